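#' Sort one contig by homology evidence
#'
#' Applies the alignment-based sorting rule: hits above the e-value cut-off
#' are discarded; contigs shorter than `min_contig_bp` are `too_short`;
#' with no surviving hits, `no_hit`. Otherwise, if the best bit-scores on
#' two *different* pseudomolecules are within `ambiguity_window` of each
#' other (runner-up >= 99% of best at the default, boundary inclusive) the
#' contig is `ambiguous`; multiple strong hits inside one pseudomolecule
#' (tandem or internal repeats) never trigger ambiguity. Placed contigs get
#' the best hit's target start as their position.
#'
#' @param contig_id Contig id.
#' @param contig_length Contig length in bp.
#' @param hits Hit tibble from [read_hits()], restricted or not (rows with
#'   `query != contig_id` are ignored).
#' @param config An [nc_config()] (uses `sort_evalue`, `min_contig_bp`,
#'   `ambiguity_window`).
#' @return One-row tibble: `contig_id`, `status` (`placed` / `ambiguous` /
#'   `no_hit` / `too_short`), `seq_id`, `position`, `best_score`,
#'   `runner_up`.
#' @export
sort_contig <- function(contig_id, contig_length, hits, config = nc_config()) {
  res <- tibble(contig_id = contig_id, status = NA_character_,
                seq_id = NA_character_, position = NA_real_,
                best_score = NA_real_, runner_up = NA_real_)
  if (contig_length < config$min_contig_bp) {
    res$status <- "too_short"
    return(res)
  }
  h <- dplyr::filter(hits, .data$query == contig_id,
                     .data$evalue <= config$sort_evalue)
  if (nrow(h) == 0) {
    res$status <- "no_hit"
    return(res)
  }
  if (any(h$bitscore <= 0)) abort("non-positive bit-score")
  # best hit per pseudomolecule, then rank pseudomolecules
  h <- h[order(h$target, -h$bitscore, h$evalue, h$t_start), ]
  per_target <- h[!duplicated(h$target), ]
  per_target <- per_target[order(-per_target$bitscore, per_target$evalue,
                                 per_target$target), ]
  s1 <- per_target$bitscore[1]
  res$best_score <- s1
  res$seq_id <- per_target$target[1]
  res$position <- per_target$t_start[1]
  if (nrow(per_target) > 1) {
    s2 <- per_target$bitscore[2]
    res$runner_up <- s2
    if (s2 >= (1 - config$ambiguity_window) * s1) {
      res$status <- "ambiguous"
      res$seq_id <- NA_character_
      res$position <- NA_real_
      return(res)
    }
  }
  res$status <- "placed"
  res
}

#' Sort all contigs and build ordered pseudomolecule scaffolds
#'
#' Runs [sort_contig()] over an assembly of contigs, then concatenates the
#' placed contigs of each pseudomolecule in order of their target position
#' (ties broken lexicographically by contig id) with N-gaps in between.
#'
#' @param assembly Contig assembly from [read_fasta()]/[as_assembly()].
#' @param hits Hit tibble from [read_hits()]; queries must be assembly ids.
#' @param config An [nc_config()].
#' @param gap_length Number of N between consecutive contigs (cosmetic;
#'   recorded in the AGP so the scaffolds are reversible).
#' @return A list with `decisions` (tibble, one row per contig), `scaffolds`
#'   (`nc_assembly` of the concatenated pseudomolecules) and `agp` (layout
#'   tibble for [write_agp()]).
#' @export
sort_all <- function(assembly, hits, config = nc_config(), gap_length = 100) {
  assembly <- as_assembly(assembly)
  stray <- setdiff(unique(hits$query), assembly$seq_id)
  if (length(stray) > 0) {
    abort(sprintf("hit table references unknown contig(s): %s",
                  paste(utils::head(stray, 3), collapse = ", ")))
  }
  decisions <- dplyr::bind_rows(purrr::map2(
    assembly$seq_id, assembly$length,
    function(cid, len) sort_contig(cid, len, hits, config)
  ))
  sc <- build_scaffolds(assembly, decisions, gap_length = gap_length)
  list(decisions = decisions, scaffolds = sc$scaffolds, agp = sc$agp)
}

#' @rdname sort_all
#' @param decisions Decision tibble from [sort_all()]/[sort_contig()].
#' @export
build_scaffolds <- function(assembly, decisions, gap_length = 100) {
  assembly <- as_assembly(assembly)
  placed <- dplyr::arrange(
    dplyr::filter(decisions, .data$status == "placed"),
    .data$seq_id, .data$position, .data$contig_id
  )
  seqs <- stats::setNames(assembly$seq, assembly$seq_id)
  gap <- strrep("N", gap_length)
  agp <- list()
  out <- character()
  for (sq in unique(placed$seq_id)) {
    ctgs <- placed$contig_id[placed$seq_id == sq]
    pieces <- unname(seqs[ctgs])
    out[[sq]] <- paste(pieces, collapse = gap)
    pos <- 0L
    part <- 0L
    for (j in seq_along(ctgs)) {
      if (j > 1) {
        part <- part + 1L
        agp[[length(agp) + 1]] <- tibble(
          object = sq, object_beg = pos + 1L, object_end = pos + gap_length,
          part_number = part, component_type = "N", component_id = NA_character_,
          component_beg = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_, gap_length = as.integer(gap_length)
        )
        pos <- pos + gap_length
      }
      len <- nchar(pieces[j])
      part <- part + 1L
      agp[[length(agp) + 1]] <- tibble(
        object = sq, object_beg = pos + 1L, object_end = pos + len,
        part_number = part, component_type = "W", component_id = ctgs[j],
        component_beg = 1L, component_end = len, orientation = "+",
        gap_length = NA_integer_
      )
      pos <- pos + len
    }
  }
  list(
    scaffolds = if (length(out) > 0) as_assembly(out) else NULL,
    agp = dplyr::bind_rows(agp)
  )
}
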