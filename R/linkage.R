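#' Consensus genotype vector of a set of SNP loci
#'
#' Collapses the genotype rows of one contig (or anchor bin) into a single
#' per-individual vector: the majority code among non-missing calls, missing
#' on ties or when every call is missing. The concordance is the majority
#' share among non-missing calls.
#'
#' @param calls Character matrix (loci x individuals) of `"P1"`/`"P2"`/`NA`.
#' @return A list with `consensus` (named character vector), `concordance`
#'   (named numeric) and `n_loci`.
#' @examples
#' m <- rbind(c("P1", NA), c("P1", "P2"), c("P2", "P2"))
#' colnames(m) <- c("i1", "i2")
#' consensus_vector(m)$consensus
#' @export
consensus_vector <- function(calls) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  if (nrow(calls) == 0) abort("consensus over an empty locus set")
  n1 <- colSums(calls == "P1", na.rm = TRUE)
  n2 <- colSums(calls == "P2", na.rm = TRUE)
  consensus <- dplyr::case_when(n1 > n2 ~ "P1", n2 > n1 ~ "P2",
                                TRUE ~ NA_character_)
  tot <- n1 + n2
  concordance <- ifelse(tot > 0, pmax(n1, n2) / tot, NA_real_)
  names(consensus) <- names(concordance) <- colnames(calls)
  list(consensus = consensus, concordance = concordance, n_loci = nrow(calls))
}

#' Recombination fraction between two genotype vectors
#'
#' The fraction of individuals, among those non-missing in both vectors,
#' whose parental codes differ. In a doubled-haploid population r is near 0
#' for tightly linked loci and near 0.5 for unlinked loci. Undefined (`NA`)
#' when fewer than `min_informative` individuals are informative.
#'
#' @param v1,v2 Equal-length character vectors of `"P1"`/`"P2"`/`NA` over the
#'   same individuals.
#' @param min_informative Minimum joint non-missing individuals.
#' @return A single numeric in \[0, 1\], or `NA`.
#' @examples
#' recomb_fraction(c("P1", "P1", "P2"), c("P1", "P2", "P2"), min_informative = 1)
#' @export
recomb_fraction <- function(v1, v2, min_informative = 10) {
  if (length(v1) != length(v2)) abort("genotype vectors differ in length")
  inf <- !is.na(v1) & !is.na(v2)
  n <- sum(inf)
  if (n < min_informative) {
    return(NA_real_)
  }
  sum(v1[inf] != v2[inf]) / n
}

#' Build anchor bins from the anchored genotype matrix
#'
#' Groups anchored SNP loci into fixed windows of `bin_bp` along each
#' pseudomolecule and computes a consensus genotype vector per window.
#' Windows without loci are omitted. The bin is the granularity at which
#' unplaced contigs are inserted.
#'
#' @param genotypes `nc_genotypes` of loci anchored on pseudomolecules.
#' @param bin_bp Window width (bp).
#' @param seq_lengths Optional named lengths used to validate locus
#'   positions and clip the final bin.
#' @return A tibble with `seq_id`, `start`, `end`, `mid`, `n_snps`, and a
#'   `consensus` list-column, ordered within each pseudomolecule.
#' @export
build_anchor_bins <- function(genotypes, bin_bp = 1e6, seq_lengths = NULL) {
  stopifnot(inherits(genotypes, "nc_genotypes"))
  loci <- genotypes$loci
  if (!is.null(seq_lengths)) {
    bad <- loci$pos >= seq_lengths[loci$seq_id]
    if (any(bad)) abort(sprintf("locus beyond sequence end: %s", loci$locus_id[bad][1]))
  }
  bin <- floor(loci$pos / bin_bp)
  key <- paste(loci$seq_id, bin, sep = "\r")
  idx <- split(seq_len(nrow(loci)), key)
  rows <- purrr::map(idx, function(i) {
    cv <- consensus_vector(genotypes$calls[i, , drop = FALSE])
    start <- floor(loci$pos[i][1] / bin_bp) * bin_bp
    end <- start + bin_bp
    if (!is.null(seq_lengths)) end <- min(end, seq_lengths[[loci$seq_id[i][1]]])
    tibble(seq_id = loci$seq_id[i][1], start = start, end = end,
           mid = (start + end) / 2, n_snps = length(i), consensus = list(cv$consensus))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$seq_id, .data$start)
}

#' Place one contig against the anchor bins
#'
#' Computes the recombination fraction between the contig's consensus
#' genotype vector and every anchor bin, then applies the placement rule:
#'
#' * `placed` -- the global minimum r is at most `r_max` and beats the best
#'   bin on every *other* pseudomolecule by at least `delta_conflict`;
#' * `conflict` -- a second pseudomolecule is linked nearly as well (its
#'   best r within `delta_conflict` of the minimum; this is how
#'   homeologous A/C similarity shows up);
#' * `insufficient` -- every r is undefined, or no bin reaches `r_max`
#'   (no usable linkage).
#'
#' Ties between equally good bins on the same pseudomolecule go to the bin
#' with more SNPs, then the smaller coordinate. The insertion position is
#' the midpoint of the winning bin.
#'
#' @param contig Either a consensus genotype vector or a calls matrix
#'   (collapsed with [consensus_vector()]).
#' @param bins Anchor bins from [build_anchor_bins()].
#' @param config An [nc_config()] (uses `r_max`, `delta_conflict`,
#'   `min_informative`).
#' @param contig_id Id recorded in the result.
#' @return One-row tibble: `contig_id`, `status`, `seq_id`, `position`,
#'   `r_best`, `r_second_chrom`, `n_informative`.
#' @export
place_contig <- function(contig, bins, config = nc_config(), contig_id = NA_character_) {
  if (nrow(bins) == 0) abort("no anchor bins")
  if (is.matrix(contig)) contig <- consensus_vector(contig)$consensus
  r <- purrr::map_dbl(bins$consensus, recomb_fraction, v2 = contig,
                      min_informative = config$min_informative)
  res <- tibble(contig_id = contig_id, status = NA_character_,
                seq_id = NA_character_, position = NA_real_,
                r_best = NA_real_, r_second_chrom = NA_real_,
                n_informative = NA_integer_)
  if (all(is.na(r))) {
    res$status <- "insufficient"
    return(res)
  }
  ord <- order(r, -bins$n_snps, bins$start, na.last = TRUE)
  best <- ord[1]
  r_best <- r[best]
  other <- which(bins$seq_id != bins$seq_id[best] & !is.na(r))
  r2 <- if (length(other) > 0) min(r[other]) else Inf
  inf_vec <- bins$consensus[[best]]
  res$r_best <- r_best
  res$r_second_chrom <- if (is.finite(r2)) r2 else NA_real_
  res$n_informative <- sum(!is.na(inf_vec) & !is.na(contig))
  if (r_best > config$r_max) {
    res$status <- "insufficient"
  } else if (r2 - r_best >= config$delta_conflict) {
    res$status <- "placed"
    res$seq_id <- bins$seq_id[best]
    res$position <- bins$mid[best]
  } else {
    # a second pseudomolecule is linked almost as well; never force-place
    res$status <- "conflict"
  }
  res
}

#' Place every unplaced contig
#'
#' Drives [place_contig()] over a genotype matrix whose `seq_id` column
#' names the unplaced contig each SNP locus sits on. Contigs listed in
#' `contig_ids` but carrying no SNP loci are reported as `no_snp`. When a
#' prior chromosome assignment is supplied, consistency is assessed over
#' contigs that were placed and had a prior.
#'
#' @param unplaced `nc_genotypes` of SNP loci on unplaced contigs
#'   (`loci$seq_id` = contig id).
#' @param bins Anchor bins from [build_anchor_bins()].
#' @param config An [nc_config()].
#' @param contig_ids All contig ids under consideration (default: those with
#'   loci, plus any in `prior`).
#' @param prior Optional tibble `contig_id`, `prior_seq` (`"-"` or `NA` for
#'   none).
#' @return A tibble of class `nc_placement`, one row per contig, with a
#'   summary available via [glance()]: counts of placed / no_snp / conflict /
#'   insufficient and the prior-consistency fraction.
#' @seealso [placement_agp()] to emit the improved-assembly AGP.
#' @export
place_all <- function(unplaced, bins, config = nc_config(),
                      contig_ids = NULL, prior = NULL) {
  stopifnot(inherits(unplaced, "nc_genotypes"))
  with_loci <- unique(unplaced$loci$seq_id)
  if (is.null(contig_ids)) {
    contig_ids <- union(with_loci, if (!is.null(prior)) prior$contig_id else character())
  }
  if (anyDuplicated(contig_ids)) abort("duplicate contig id")
  rows <- purrr::map(contig_ids, function(cid) {
    i <- which(unplaced$loci$seq_id == cid)
    if (length(i) == 0) {
      return(tibble(contig_id = cid, status = "no_snp", seq_id = NA_character_,
                    position = NA_real_, r_best = NA_real_,
                    r_second_chrom = NA_real_, n_informative = NA_integer_))
    }
    cv <- consensus_vector(unplaced$calls[i, , drop = FALSE])
    place_contig(cv$consensus, bins, config, contig_id = cid)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(prior)) {
    assert_cols(prior, c("contig_id", "prior_seq"), "prior")
    out <- dplyr::left_join(out, prior, by = "contig_id")
    out$prior_consistent <- dplyr::case_when(
      is.na(out$prior_seq) | out$prior_seq == "-" ~ "not-applicable",
      out$status != "placed" ~ "not-applicable",
      out$seq_id == out$prior_seq ~ "yes",
      TRUE ~ "no"
    )
  } else {
    out$prior_seq <- NA_character_
    out$prior_consistent <- "not-applicable"
  }
  class(out) <- unique(c("nc_placement", class(out)))
  out
}

#' @rdname place_all
#' @param x An `nc_placement` tibble.
#' @param ... Unused.
#' @method glance nc_placement
#' @export
glance.nc_placement <- function(x, ...) {
  applicable <- x$prior_consistent %in% c("yes", "no")
  tibble(
    n_contigs = nrow(x),
    placed = sum(x$status == "placed"),
    no_snp = sum(x$status == "no_snp"),
    conflict = sum(x$status == "conflict"),
    insufficient = sum(x$status == "insufficient"),
    prior_consistency = if (any(applicable)) {
      sum(x$prior_consistent == "yes") / sum(applicable)
    } else {
      NA_real_
    }
  )
}

#' AGP layout for linkage placements
#'
#' Emits one AGP object per pseudomolecule listing its placed contigs in
#' insertion order with 100-N scaffold gaps. Genotypes carry no orientation
#' signal, so orientation is recorded as `?`; insertion granularity is the
#' anchor bin, so the layout records order, not base-perfect coordinates.
#'
#' @param placements `nc_placement` tibble from [place_all()].
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param gap_length Gap size between consecutive placed contigs.
#' @return AGP layout tibble for [write_agp()].
#' @export
placement_agp <- function(placements, contig_lengths, gap_length = 100) {
  placed <- dplyr::arrange(
    dplyr::filter(placements, .data$status == "placed"),
    .data$seq_id, .data$position, .data$contig_id
  )
  rows <- list()
  for (sq in unique(placed$seq_id)) {
    ctgs <- placed$contig_id[placed$seq_id == sq]
    pos <- 0L
    part <- 0L
    for (j in seq_along(ctgs)) {
      if (j > 1) {
        part <- part + 1L
        rows[[length(rows) + 1]] <- tibble(
          object = sq, object_beg = pos + 1L, object_end = pos + gap_length,
          part_number = part, component_type = "N", component_id = NA_character_,
          component_beg = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_, gap_length = gap_length
        )
        pos <- pos + gap_length
      }
      len <- as.integer(contig_lengths[[ctgs[j]]])
      part <- part + 1L
      rows[[length(rows) + 1]] <- tibble(
        object = sq, object_beg = pos + 1L, object_end = pos + len,
        part_number = part, component_type = "W", component_id = ctgs[j],
        component_beg = 1L, component_end = len, orientation = "?",
        gap_length = NA_integer_
      )
      pos <- pos + len
    }
  }
  dplyr::bind_rows(rows)
}
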