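#' Call gene presence/absence from genomic-read exon coverage
#'
#' For each gene, the fraction of exonic bases reaching depth
#' `loss_min_depth` under the supplied read set is computed; a gene is
#' `absent` when that fraction falls below `loss_min_frac` (default: fewer
#' than 5% of exonic bases covered). Calling is per read set, so absence of
#' a cultivar-A gene under cultivar-B reads is the cross-cultivar
#' presence/absence signal.
#'
#' @param genes Gene tibble from [read_gff3()].
#' @param coverage `nc_coverage` tibble holding one depth track per
#'   sequence (any single mode).
#' @param config An [nc_config()].
#' @return Tibble `gene_id`, `seq_id`, `covered_frac`, `status`
#'   (`present`/`absent`).
#' @export
call_presence <- function(genes, coverage, config = nc_config()) {
  mode <- unique(coverage$mode)
  if (length(mode) != 1) abort("call_presence expects a single coverage mode")
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$seq_id %in% coverage$seq_id) {
      abort(sprintf("gene %s lies on unknown sequence %s", g$gene_id, g$seq_id))
    }
    d <- get_track(coverage, g$seq_id, mode)
    ex <- g$exons[[1]]
    idx <- unlist(purrr::map2(ex$start, ex$end, function(s, e) (s + 1L):e))
    frac <- mean(d[idx] >= config$loss_min_depth)
    tibble(gene_id = g$gene_id, seq_id = g$seq_id, covered_frac = frac,
           status = if (frac < config$loss_min_frac) "absent" else "present")
  })
  dplyr::bind_rows(rows)
}

#' Call expression presence from per-library fragment counts
#'
#' A gene is expressed in a library when at least `expr_min_fragments`
#' unique fragments map to it there (default 5); fewer are treated as
#' mismappings from expressed homeologous copies.
#'
#' @param counts Long tibble `gene_id`, `library`, `fragments`, or a wide
#'   tibble (`gene_id` plus one numeric column per library).
#' @param config An [nc_config()].
#' @return Long tibble `gene_id`, `library`, `fragments`, `expressed`.
#' @examples
#' call_expression(tibble::tibble(gene_id = "g", library = c("L1", "L2"),
#'                                fragments = c(4, 5)))
#' @export
call_expression <- function(counts, config = nc_config()) {
  counts <- as_tibble(counts)
  if (!"fragments" %in% names(counts)) {
    counts <- tidyr::pivot_longer(counts, -"gene_id", names_to = "library",
                                  values_to = "fragments")
  }
  assert_cols(counts, c("gene_id", "library", "fragments"), "counts")
  if (any(counts$fragments < 0)) abort("negative fragment count")
  dplyr::mutate(counts, expressed = .data$fragments >= config$expr_min_fragments)
}

#' Classify a cross-cultivar expression pattern
#'
#' Given per-role expressed flags for one gene -- the reference cultivar
#' carrying the gene, the query cultivar where it is predicted absent, the
#' donor parent, and the mapping-population libraries -- assigns one of:
#' `none` (no library expressed), `reference-only`,
#' `reference-and-donor-segregating` (reference and donor expressed, query
#' not, population mixed), `other-cultivars-only` (query and donor but not
#' reference), `all`, or `other` for remaining combinations.
#'
#' @param reference,query,donor Logical flags (any library of that role).
#' @param population Logical vector of per-library flags for the
#'   population; "mixed" means at least one expressed and one not.
#' @return Category string.
#' @export
classify_pattern <- function(reference, query, donor, population = logical()) {
  mixed <- length(population) > 0 && any(population) && any(!population)
  if (!reference && !query && !donor && !any(population)) {
    return("none")
  }
  if (reference && query && donor && (length(population) == 0 || all(population))) {
    return("all")
  }
  if (reference && !query && !donor && !any(population)) {
    return("reference-only")
  }
  if (reference && donor && !query && mixed) {
    return("reference-and-donor-segregating")
  }
  if (!reference && query && donor) {
    return("other-cultivars-only")
  }
  "other"
}

#' Classify expression patterns for many genes
#'
#' Applies [classify_pattern()] per gene over a long flag table.
#'
#' @param flags Tibble `gene_id`, `role` (one of `reference`, `query`,
#'   `donor`, `population`), `library`, `expressed`.
#' @return Tibble `gene_id`, `category`, plus per-category counts as the
#'   `counts` attribute.
#' @export
classify_patterns <- function(flags) {
  assert_cols(flags, c("gene_id", "role", "expressed"), "flags")
  bad <- setdiff(unique(flags$role), c("reference", "query", "donor", "population"))
  if (length(bad) > 0) abort(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  out <- dplyr::bind_rows(purrr::map(split(flags, flags$gene_id), function(ff) {
    role_any <- function(r) any(ff$expressed[ff$role == r])
    tibble(
      gene_id = ff$gene_id[1],
      category = classify_pattern(
        reference = role_any("reference"), query = role_any("query"),
        donor = role_any("donor"),
        population = ff$expressed[ff$role == "population"]
      )
    )
  }))
  attr(out, "counts") <- dplyr::count(out, .data$category)
  out
}
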