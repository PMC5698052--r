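#' Analysis configuration
#'
#' All tunable thresholds used across the toolkit, with defaults. Values with
#' a direct published origin: `min_block_bp` (minimum collapsed/repetitive
#' block length), `min_contig_bp` (minimum contig length for homology
#' sorting), `sort_evalue` (blastn e-value cut-off for contig sorting),
#' `ambiguity_window` (two top-scoring alignments "within 1%" are left
#' unplaced), `min_block_genes` (collinear blocks need at least five genes),
#' `min_gene_bp` (genes shorter than 100 bp are filtered),
#' `expr_min_fragments` (fewer than five unique fragments in a library means
#' not expressed), `homolog_evalue` (blastp e-value cut-off for gene
#' pairing). The remainder are this package's own calibration, documented in
#' the methods vignette.
#'
#' @param min_block_bp Minimum length (bp) of a collapsed/repetitive region.
#' @param min_contig_bp Contigs shorter than this are not homology-sorted.
#' @param sort_evalue E-value cut-off for contig-sorting homology hits.
#' @param homolog_evalue E-value cut-off for gene-to-gene protein hits.
#' @param ambiguity_window Fraction: runner-up scores within this fraction of
#'   the best score (on a different pseudomolecule) make a contig ambiguous.
#' @param min_block_genes Minimum genes per collinear block.
#' @param min_gene_bp Minimum total exon length (bp) for a gene to be kept.
#' @param expr_min_fragments Minimum fragments in a library to call a gene
#'   expressed there.
#' @param r_max Maximum recombination fraction for linkage placement; in a
#'   doubled-haploid population unlinked loci sit near r = 0.5, so 0.25
#'   excludes them decisively.
#' @param delta_conflict Required margin (in r) between the best and the best
#'   other-pseudomolecule bin; smaller margins are reported as conflicts.
#' @param min_informative Minimum individuals informative for both vectors
#'   for a recombination fraction to be defined.
#' @param collapse_multiplier Unique-mapping depth above `collapse_multiplier
#'   * D` (D = single-copy depth) marks a position collapsed; 1.75 sits below
#'   the doubled-coverage expectation of 2 to tolerate Poisson noise.
#' @param rep_unique_frac,rep_all_frac A position is repetitive when unique
#'   depth is at most `rep_unique_frac * D` while all-placement depth is at
#'   least `rep_all_frac * D` (separates assembly repeats from plain
#'   coverage dropout).
#' @param loss_min_frac,loss_min_depth A gene is absent when fewer than
#'   `loss_min_frac` of its exonic bases reach depth `loss_min_depth`.
#' @param bin_bp Anchor-bin width (bp) for linkage placement.
#' @param region_overlap_frac Fraction of a gene's exonic bases that must
#'   fall inside a region class for the gene to be located in it.
#' @param max_rank_gap Maximum gene-rank gap between consecutive members of a
#'   collinear chain, on both genomes.
#' @param expected_region_bp Distance window around the position interpolated
#'   from flanking collinear blocks that counts as the "expected region".
#'
#' @return A named list of class `nc_config`.
#' @examples
#' cfg <- nc_config(r_max = 0.2)
#' cfg$r_max
#' @export
nc_config <- function(min_block_bp = 50,
                      min_contig_bp = 1000,
                      sort_evalue = 1e-6,
                      homolog_evalue = 1e-10,
                      ambiguity_window = 0.01,
                      min_block_genes = 5,
                      min_gene_bp = 100,
                      expr_min_fragments = 5,
                      r_max = 0.25,
                      delta_conflict = 0.05,
                      min_informative = 10,
                      collapse_multiplier = 1.75,
                      rep_unique_frac = 0.1,
                      rep_all_frac = 0.5,
                      loss_min_frac = 0.05,
                      loss_min_depth = 1,
                      bin_bp = 1e6,
                      region_overlap_frac = 0.5,
                      max_rank_gap = 5,
                      expected_region_bp = 1e6) {
  cfg <- list(
    min_block_bp = min_block_bp, min_contig_bp = min_contig_bp,
    sort_evalue = sort_evalue, homolog_evalue = homolog_evalue,
    ambiguity_window = ambiguity_window, min_block_genes = min_block_genes,
    min_gene_bp = min_gene_bp, expr_min_fragments = expr_min_fragments,
    r_max = r_max, delta_conflict = delta_conflict,
    min_informative = min_informative,
    collapse_multiplier = collapse_multiplier,
    rep_unique_frac = rep_unique_frac, rep_all_frac = rep_all_frac,
    loss_min_frac = loss_min_frac, loss_min_depth = loss_min_depth,
    bin_bp = bin_bp, region_overlap_frac = region_overlap_frac,
    max_rank_gap = max_rank_gap, expected_region_bp = expected_region_bp
  )
  validate_config(cfg)
  structure(cfg, class = "nc_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_block_bp >= 1, cfg$min_contig_bp >= 0,
    cfg$sort_evalue > 0, cfg$homolog_evalue > 0,
    cfg$ambiguity_window >= 0, cfg$ambiguity_window < 1,
    cfg$min_block_genes >= 1, cfg$min_gene_bp >= 0,
    cfg$expr_min_fragments >= 0,
    cfg$r_max > 0, cfg$r_max <= 0.5,
    cfg$delta_conflict >= 0, cfg$min_informative >= 1,
    cfg$collapse_multiplier > 1,
    cfg$rep_unique_frac >= 0, cfg$rep_unique_frac < 1,
    cfg$rep_all_frac > 0,
    cfg$loss_min_frac > 0, cfg$loss_min_frac <= 1,
    cfg$loss_min_depth >= 1,
    cfg$bin_bp >= 1, cfg$region_overlap_frac > 0, cfg$region_overlap_frac <= 1,
    cfg$max_rank_gap >= 1, cfg$expected_region_bp > 0
  )
  invisible(cfg)
}

#' @export
print.nc_config <- function(x, ...) {
  cat("<nc_config>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a configuration file
#'
#' The on-disk format is flat TOML: one `key = value` per line, `#` comments
#' allowed. Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path File path.
#' @param config An [nc_config()] object.
#' @return `read_config()` returns an `nc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  known <- names(formals(nc_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(nc_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nc_config"))
  lines <- sprintf("%s = %s", names(config),
                   vapply(config, format, "", scientific = FALSE))
  write_lines_atomic(lines, path)
  invisible(path)
}
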