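#' Estimate the single-copy read depth of a track
#'
#' The reference depth D that one assembly copy of single-copy sequence
#' attracts. Computed as the mode of the positive-depth histogram after
#' discarding the top 1% of depths (which removes organelle/collapsed
#' spikes); modal ties resolve to the smaller depth.
#'
#' @param depth Integer depth vector, or an `nc_coverage` tibble whose
#'   tracks are pooled.
#' @return Positive numeric D.
#' @examples
#' estimate_single_copy_depth(c(rep(10, 90), rep(20, 9), rep(500, 1)))
#' @export
estimate_single_copy_depth <- function(depth) {
  if (inherits(depth, "nc_coverage") || is.data.frame(depth)) {
    depth <- unlist(depth$depth, use.names = FALSE)
  }
  pos <- depth[depth > 0]
  if (length(pos) == 0) abort("all-zero coverage track")
  cap <- stats::quantile(pos, 0.99, names = FALSE)
  kept <- pos[pos <= cap]
  if (length(kept) == 0) kept <- pos
  tab <- table(kept)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

# Maximal runs of TRUE positions, as 0-based half-open intervals, keeping
# only runs of at least min_len. max_gap > 0 joins runs separated by short
# FALSE gaps before applying the length filter.
runs_true <- function(pred, min_len, max_gap = 0) {
  r <- rle(pred)
  if (max_gap > 0 && length(r$lengths) > 2) {
    inner <- seq_along(r$values)[-c(1, length(r$values))]
    joinable <- inner[!r$values[inner] & r$lengths[inner] <= max_gap]
    if (length(joinable) > 0) {
      r$values[joinable] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep])
}

region_tbl <- function(seq_id, runs, class, depth, support) {
  if (nrow(runs) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  length = integer(), class = character(), mean_depth = numeric(),
                  support = character()))
  }
  tibble(
    seq_id = seq_id, start = runs$start, end = runs$end,
    length = runs$end - runs$start, class = class,
    mean_depth = purrr::map2_dbl(runs$start, runs$end,
                                 function(s, e) mean(depth[(s + 1):e])),
    support = support
  )
}

#' Call collapsed assembly regions from unique-mapping depth
#'
#' A position is collapsed-supported when its unique-mapping depth is at
#' least `collapse_multiplier * D`: sequence present in several genome
#' copies but assembled once attracts the reads of all copies, all mapping
#' uniquely. Maximal runs of supported positions of at least `min_block_bp`
#' are emitted; by default no gap joining is applied.
#'
#' @param unique_track Integer depth vector of the unique-placement mapping
#'   for one sequence.
#' @param D Single-copy depth from [estimate_single_copy_depth()].
#' @param config An [nc_config()].
#' @param seq_id Sequence id recorded in the calls.
#' @param max_gap Join supported runs separated by gaps up to this size.
#' @return Region tibble: `seq_id`, `start`, `end`, `length`, `class`,
#'   `mean_depth`, `support`.
#' @export
call_collapsed <- function(unique_track, D, config = nc_config(),
                           seq_id = NA_character_, max_gap = 0) {
  stopifnot(D > 0)
  pred <- unique_track >= config$collapse_multiplier * D
  region_tbl(seq_id, runs_true(pred, config$min_block_bp, max_gap),
             "collapsed", unique_track, "unique")
}

#' Call repetitive assembly regions from unique vs all-placement depth
#'
#' A position is repeat-supported when unique-mapping depth collapses to at
#' most `rep_unique_frac * D` *while* all-placement depth remains at least
#' `rep_all_frac * D`. The second predicate distinguishes assembly repeats
#' (reads exist but cannot map uniquely) from plain coverage dropout (no
#' reads at all).
#'
#' @param unique_track,all_track Equal-length depth vectors for one
#'   sequence under the two mapping modes.
#' @inheritParams call_collapsed
#' @return Region tibble as in [call_collapsed()], class `repetitive`.
#' @export
call_repetitive <- function(unique_track, all_track, D, config = nc_config(),
                            seq_id = NA_character_, max_gap = 0) {
  stopifnot(D > 0)
  if (length(unique_track) != length(all_track)) {
    abort("unique and all tracks differ in length")
  }
  pred <- unique_track <= config$rep_unique_frac * D &
    all_track >= config$rep_all_frac * D
  region_tbl(seq_id, runs_true(pred, config$min_block_bp, max_gap),
             "repetitive", all_track, "unique+all")
}

#' Call collapsed and repetitive regions genome-wide
#'
#' Convenience driver: estimates the single-copy depth D (from the `random`
#' track when present, otherwise `unique`, pooled across sequences) and
#' calls both region classes on every sequence.
#'
#' @param coverage `nc_coverage` tibble with `unique` and `all` tracks per
#'   sequence (optionally `random`).
#' @param config An [nc_config()].
#' @param max_gap Run-joining gap, see [call_collapsed()].
#' @return Region tibble with both classes, plus attribute `D`.
#' @export
find_core_regions <- function(coverage, config = nc_config(), max_gap = 0) {
  d_mode <- if ("random" %in% coverage$mode) "random" else "unique"
  D <- estimate_single_copy_depth(coverage[coverage$mode == d_mode, ])
  seqs <- unique(coverage$seq_id)
  out <- purrr::map(seqs, function(sq) {
    u <- get_track(coverage, sq, "unique")
    a <- get_track(coverage, sq, "all")
    dplyr::bind_rows(
      call_collapsed(u, D, config, seq_id = sq, max_gap = max_gap),
      call_repetitive(u, a, D, config, seq_id = sq, max_gap = max_gap)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "D") <- D
  out
}

#' Locate genes in collapsed/repetitive regions
#'
#' A gene is located in a region class when at least `region_overlap_frac`
#' of its exonic bases fall inside that class's regions. Genes passing for
#' both classes are `both`; the rest `neither`.
#'
#' @param regions Region tibble (both classes together is fine).
#' @param genes Gene tibble from [read_gff3()].
#' @param config An [nc_config()].
#' @return A list with `genes` (per-gene tibble: `gene_id`, `seq_id`,
#'   `collapsed_frac`, `repetitive_frac`, `class`) and `counts` (per
#'   sequence and class gene counts with percentages).
#' @export
annotate_genes <- function(regions, genes, config = nc_config()) {
  overlap_frac <- function(g, cls) {
    ex <- g$exons[[1]]
    reg <- regions[regions$class == cls & regions$seq_id == g$seq_id, ]
    if (nrow(reg) == 0 || nrow(ex) == 0) {
      return(0)
    }
    ir_e <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    ir_r <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    ov <- sum(IRanges::width(IRanges::intersect(ir_e, ir_r)))
    ov / sum(ex$end - ex$start)
  }
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cf <- overlap_frac(g, "collapsed")
    rf <- overlap_frac(g, "repetitive")
    in_c <- cf >= config$region_overlap_frac
    in_r <- rf >= config$region_overlap_frac
    cls <- if (in_c && in_r) "both" else if (in_c) "collapsed" else if (in_r) "repetitive" else "neither"
    tibble(gene_id = g$gene_id, seq_id = g$seq_id,
           collapsed_frac = cf, repetitive_frac = rf, class = cls)
  })
  per_gene <- dplyr::bind_rows(rows)
  counts <- dplyr::mutate(
    dplyr::count(per_gene, .data$seq_id, .data$class),
    pct = 100 * .data$n / nrow(per_gene)
  )
  list(genes = per_gene, counts = counts)
}

#' Summarize region calls
#'
#' Per-sequence and per-class counts, total lengths and mean lengths, plus
#' genome-wide totals per class.
#'
#' @param regions Region tibble.
#' @return List with `by_sequence` and `overall` tibbles.
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0) {
    empty <- tibble(seq_id = character(), class = character(), n = integer(),
                    total_bp = numeric(), mean_bp = numeric())
    return(list(by_sequence = empty, overall = empty[, -1]))
  }
  by_seq <- dplyr::summarise(
    dplyr::group_by(regions, .data$seq_id, .data$class),
    n = dplyr::n(), total_bp = sum(.data$length), mean_bp = mean(.data$length),
    .groups = "drop"
  )
  overall <- dplyr::summarise(
    dplyr::group_by(regions, .data$class),
    n = dplyr::n(), total_bp = sum(.data$length), mean_bp = mean(.data$length),
    .groups = "drop"
  )
  list(by_sequence = by_seq, overall = overall)
}

#' Count items in fixed genomic windows
#'
#' Bins items (regions, genes -- anything with `seq_id` and `start`) into
#' fixed windows from coordinate 0 and counts per window.
#'
#' @param items Tibble with `seq_id` and `start`.
#' @param window_bp Window width (default 10 Mbp).
#' @return Tibble `seq_id`, `window`, `start`, `end`, `n`.
#' @export
window_counts <- function(items, window_bp = 1e7) {
  assert_cols(items, c("seq_id", "start"), "items")
  out <- dplyr::count(
    dplyr::mutate(items, window = floor(.data$start / window_bp)),
    .data$seq_id, .data$window
  )
  dplyr::mutate(out, start = .data$window * window_bp,
                end = (.data$window + 1) * window_bp)[,
    c("seq_id", "window", "start", "end", "n")]
}
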