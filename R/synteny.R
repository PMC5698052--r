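#' Rank genes along their chromosome
#'
#' Collinearity is assessed on gene order, not base positions; ranks are
#' row numbers after sorting genes by start within each sequence.
#'
#' @param genes Tibble with `gene_id`, `seq_id`, `start`.
#' @return Input with a `rank` column added.
#' @export
gene_ranks <- function(genes) {
  assert_cols(genes, c("gene_id", "seq_id", "start"), "genes")
  dplyr::mutate(
    dplyr::group_by(dplyr::arrange(genes, .data$seq_id, .data$start,
                                   .data$gene_id), .data$seq_id),
    rank = dplyr::row_number()
  ) |> dplyr::ungroup()
}

#' Reciprocal-best gene pairs from a protein hit table
#'
#' Hits above `homolog_evalue` are discarded; each gene's best partner is
#' chosen by bit-score (ties by smaller e-value, then lexicographic id) and
#' a pair is kept only when the choice is mutual, so every gene appears in
#' at most one pair.
#'
#' @param hits Hit tibble from [read_hits()] with gene ids in
#'   `query`/`target`.
#' @param genes_a,genes_b Gene tibbles ([gene_ranks()] is applied) for the
#'   query and target genomes.
#' @param config An [nc_config()].
#' @return Tibble `gene_a`, `gene_b`, `score`, plus per-side `seq_`,
#'   `rank_`, `pos_` columns.
#' @export
best_pairs <- function(hits, genes_a, genes_b, config = nc_config()) {
  h <- dplyr::filter(hits, .data$evalue <= config$homolog_evalue)
  if (nrow(h) == 0) {
    return(tibble(gene_a = character(), gene_b = character(), score = numeric(),
                  seq_a = character(), rank_a = integer(), pos_a = numeric(),
                  seq_b = character(), rank_b = integer(), pos_b = numeric()))
  }
  best_of <- function(df, by, partner) {
    df <- dplyr::arrange(df, .data[[by]], -.data$bitscore, .data$evalue,
                         .data[[partner]])
    df[!duplicated(df[[by]]), c(by, partner, "bitscore")]
  }
  ab <- best_of(h, "query", "target")
  ba <- best_of(h, "target", "query")
  pairs <- dplyr::inner_join(ab, ba, by = c("query", "target"),
                             suffix = c("", ".r"))
  ra <- gene_ranks(genes_a)
  rb <- gene_ranks(genes_b)
  out <- tibble(gene_a = pairs$query, gene_b = pairs$target,
                score = pairs$bitscore)
  out <- dplyr::left_join(
    out,
    dplyr::select(ra, gene_a = "gene_id", seq_a = "seq_id", rank_a = "rank",
                  pos_a = "start"),
    by = "gene_a"
  )
  out <- dplyr::left_join(
    out,
    dplyr::select(rb, gene_b = "gene_id", seq_b = "seq_id", rank_b = "rank",
                  pos_b = "start"),
    by = "gene_b"
  )
  if (anyNA(out$rank_a) || anyNA(out$rank_b)) abort("hit references unknown gene")
  dplyr::arrange(out, .data$seq_a, .data$rank_a)
}

# Longest gap-bounded monotone chain among pairs sorted by rank_a.
# Returns indices of the best chain (ties: leftmost start, then ascending
# orientation preferred), or integer(0).
chain_dp <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- integer(0)
  for (dir in c(1L, -1L)) {
    len <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        da <- ra[i] - ra[j]
        db <- dir * (rb[i] - rb[j])
        if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap &&
            len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    end <- which.max(len)
    chain <- integer(0)
    k <- end
    while (!is.na(k)) {
      chain <- c(k, chain)
      k <- prev[k]
    }
    better <- length(chain) > length(best) ||
      (length(chain) == length(best) && length(best) > 0 &&
         ra[chain[1]] < ra[best[1]])
    if (better) best <- chain
  }
  best
}

#' Find collinear blocks of gene pairs
#'
#' Within each chromosome pair, pairs are chained into blocks: consecutive
#' members may skip at most `max_rank_gap` gene ranks on either genome and
#' ranks on the second genome must be strictly monotone (increasing =
#' `same` orientation, decreasing = `inverted`). Chains are extracted
#' greedily, longest first (ties to the leftmost start); chains shorter
#' than `min_block_genes` are dropped, and each pair belongs to at most one
#' block.
#'
#' @param pairs Pair tibble from [best_pairs()].
#' @param config An [nc_config()] (uses `min_block_genes`, `max_rank_gap`).
#' @return Tibble `block_id`, `seq_a`, `seq_b`, `orientation`, `n_genes`,
#'   `members` (list-column of member pair rows, ordered by `rank_a`).
#' @export
find_blocks <- function(pairs, config = nc_config()) {
  groups <- split(pairs, paste(pairs$seq_a, pairs$seq_b, sep = "\r"))
  blocks <- list()
  for (grp in groups) {
    grp <- dplyr::arrange(grp, .data$rank_a, .data$rank_b)
    repeat {
      idx <- chain_dp(grp$rank_a, grp$rank_b, config$max_rank_gap)
      if (length(idx) < config$min_block_genes) break
      members <- grp[idx, ]
      blocks[[length(blocks) + 1]] <- tibble(
        seq_a = members$seq_a[1], seq_b = members$seq_b[1],
        orientation = if (members$rank_b[nrow(members)] > members$rank_b[1]) "same" else "inverted",
        n_genes = nrow(members), members = list(members)
      )
      grp <- grp[-idx, ]
      if (nrow(grp) == 0) break
    }
  }
  if (length(blocks) == 0) {
    return(tibble(block_id = integer(), seq_a = character(), seq_b = character(),
                  orientation = character(), n_genes = integer(),
                  members = list()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(blocks), .data$seq_a, .data$seq_b,
                        purrr::map_dbl(.data$members, function(m) m$rank_a[1]))
  dplyr::mutate(out, block_id = dplyr::row_number(), .before = 1)
}

#' Classify genes outside collinear blocks
#'
#' Paired genes that did not make it into any block are classified by where
#' their partner lies: `expected-chromosome` when the partner is on the
#' expected (homologous) chromosome; additionally `expected-region` when it
#' falls within `expected_region_bp` of the position interpolated from
#' flanking collinear blocks; otherwise `elsewhere`. Expected-region genes
#' are a subset of expected-chromosome genes.
#'
#' @param pairs Pair tibble from [best_pairs()].
#' @param blocks Blocks from [find_blocks()]; members are excluded from
#'   classification and used as interpolation anchors.
#' @param homeology Named character vector mapping each query chromosome to
#'   its expected partner chromosome; `NULL` means same-name chromosomes
#'   (two assemblies of one species). See [napus_homeology_map()] for the
#'   A/C subgenome pairs.
#' @param config An [nc_config()].
#' @return Tibble of out-of-block genes: `gene_a`, `seq_a`, `pos_a`,
#'   `seq_b`, `pos_b`, `expected_seq`, `interp_pos`, `class`.
#' @export
classify_outside <- function(pairs, blocks, homeology = NULL,
                             config = nc_config()) {
  in_block <- if (nrow(blocks) > 0) {
    unlist(purrr::map(blocks$members, function(m) m$gene_a))
  } else {
    character()
  }
  outside <- dplyr::filter(pairs, !.data$gene_a %in% in_block)
  expected_of <- function(sq) {
    if (is.null(homeology)) sq else unname(homeology[sq])
  }
  anchors <- if (nrow(blocks) > 0) {
    dplyr::bind_rows(blocks$members)
  } else {
    pairs[0, ]
  }
  rows <- purrr::map(seq_len(nrow(outside)), function(i) {
    g <- outside[i, ]
    exp_seq <- expected_of(g$seq_a)
    interp <- NA_real_
    cls <- "elsewhere"
    if (!is.na(exp_seq) && identical(g$seq_b, exp_seq)) {
      cls <- "expected-chromosome"
      anc <- dplyr::filter(anchors, .data$seq_a == g$seq_a,
                           .data$seq_b == exp_seq)
      if (nrow(anc) >= 2) {
        interp <- stats::approx(anc$pos_a, anc$pos_b, xout = g$pos_a,
                                rule = 2, ties = mean)$y
      } else if (nrow(anc) == 1) {
        interp <- anc$pos_b[1]
      }
      if (!is.na(interp) && abs(g$pos_b - interp) <= config$expected_region_bp) {
        cls <- "expected-region"
      }
    }
    tibble(gene_a = g$gene_a, seq_a = g$seq_a, pos_a = g$pos_a,
           seq_b = g$seq_b, pos_b = g$pos_b, expected_seq = exp_seq,
           interp_pos = interp, class = cls)
  })
  dplyr::bind_rows(rows)
}

#' Homeologous chromosome pairs of the B. napus A and C subgenomes
#'
#' The canonical A/C correspondences (A1-C1 through A9-C9, with A10's
#' homeologous segments on C9).
#'
#' @param prefix_a,prefix_c Chromosome-name prefixes.
#' @return Named character vector mapping each chromosome to its homeolog.
#' @export
napus_homeology_map <- function(prefix_a = "chrA", prefix_c = "chrC") {
  a <- sprintf("%s%02d", prefix_a, 1:10)
  c_ <- sprintf("%s%02d", prefix_c, 1:9)
  stats::setNames(
    c(sprintf("%s%02d", prefix_c, c(1:9, 9)), sprintf("%s%02d", prefix_a, 1:9)),
    c(a, c_)
  )
}
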