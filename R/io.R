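#' Build an assembly table
#'
#' An assembly is a tibble with one row per sequence: `seq_id`, `seq`
#' (uppercase nucleotide string over A/C/G/T/N) and `length`. All toolkit
#' coordinates are 0-based half-open; conversions from 1-based formats
#' (FASTA headers carry no coordinates, GFF3 and blast tables do) happen at
#' the I/O boundary only.
#'
#' @param x Named character vector of sequences, or a data frame with
#'   `seq_id` and `seq` columns.
#' @return A tibble of class `nc_assembly`.
#' @examples
#' as_assembly(c(chrA01 = "ACGTACGT", chrC01 = "GGGTTTAA"))
#' @export
as_assembly <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("sequences must be named")
    x <- tibble(seq_id = names(x), seq = unname(x))
  }
  x <- as_tibble(x)
  assert_cols(x, c("seq_id", "seq"), "assembly")
  if (anyDuplicated(x$seq_id)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(x$seq_id[duplicated(x$seq_id)]), collapse = ", ")))
  }
  if (any(!nzchar(x$seq))) abort("empty sequence record")
  x$seq <- toupper(x$seq)
  if (any(grepl("[^ACGTN]", x$seq))) abort("sequence alphabet must be A/C/G/T/N")
  x$length <- nchar(x$seq)
  out <- x[, c("seq_id", "seq", "length")]
  class(out) <- c("nc_assembly", class(out))
  out
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings that return/accept the tibble assembly
#' representation. Reading folds case and takes the first whitespace-
#' delimited token of each header as the sequence id.
#'
#' @param path File path.
#' @param assembly An [as_assembly()] tibble.
#' @param width Line-wrap width on output.
#' @return `read_fasta()` returns an `nc_assembly` tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(Biostrings::width(ss) == 0)) abort("empty FASTA record")
  as_assembly(stats::setNames(as.character(ss), ids))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(assembly, path, width = 70) {
  assembly <- as_assembly(assembly)
  ss <- Biostrings::DNAStringSet(stats::setNames(assembly$seq, assembly$seq_id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon features. For multi-isoform genes the exon set is
#' the union of all mRNA exons (interval-merged), so coverage-based presence
#' does not depend on isoform choice. Two optional attributes on the gene
#' line are picked up: `aed` (annotation edit distance, in \[0,1\]) and
#' `domains` (comma-separated protein-domain accessions). Coordinates are
#' converted from 1-based inclusive to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `seq_id`, `strand`,
#'   `start`, `end`, `aed`, `domains` (list-column), `exons` (list-column of
#'   `start`/`end` tibbles, sorted, non-overlapping) and `exon_bp`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else {
    rep(NA_character_, length(gr))
  }
  gi <- which(typ == "gene")
  if (length(gi) == 0) abort("no gene features in GFF3")
  strands <- as.character(GenomicRanges::strand(gr))
  mrna_parent <- stats::setNames(parents[typ == "mRNA"], ids[typ == "mRNA"])

  rows <- purrr::map(gi, function(i) {
    gid <- ids[i]
    if (is.na(gid)) abort("gene feature without ID attribute")
    strand <- strands[i]
    if (!strand %in% c("+", "-")) abort(sprintf("unknown strand for gene %s", gid))
    g_start <- GenomicRanges::start(gr)[i] - 1L
    g_end <- GenomicRanges::end(gr)[i]
    own_mrnas <- names(mrna_parent)[mrna_parent == gid]
    ei <- which(typ == "exon" & (parents %in% own_mrnas | parents == gid))
    if (length(ei) == 0) abort(sprintf("gene %s has no exons", gid))
    es <- GenomicRanges::start(gr)[ei] - 1L
    ee <- GenomicRanges::end(gr)[ei]
    if (any(es < g_start) || any(ee > g_end)) {
      abort(sprintf("exon outside gene span for %s", gid))
    }
    merged <- IRanges::reduce(IRanges::IRanges(start = es + 1L, end = ee))
    exons <- tibble(start = IRanges::start(merged) - 1L, end = IRanges::end(merged))
    # attributes may come back as plain vectors or CharacterLists
    attr_chr <- function(col, i) {
      if (!col %in% names(mc)) {
        return(character())
      }
      v <- unlist(as.list(mc[[col]][i]), use.names = FALSE)
      v[!is.na(v)]
    }
    aed_raw <- attr_chr("aed", i)
    aed <- if (length(aed_raw)) suppressWarnings(as.numeric(aed_raw[1])) else NA_real_
    doms <- unlist(strsplit(attr_chr("domains", i), ",", fixed = TRUE))
    if (is.null(doms)) doms <- character()
    exon_bp <- sum(exons$end - exons$start)
    tibble(
      gene_id = gid, seq_id = as.character(GenomicRanges::seqnames(gr))[i],
      strand = strand, start = g_start, end = g_end, aed = aed,
      domains = list(doms), exons = list(exons), exon_bp = exon_bp
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene ids in GFF3")
  out
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()] for the toolkit's gene table (one mRNA per gene;
#' `aed`/`domains` emitted as gene attributes).
#'
#' @param genes Gene tibble as returned by [read_gff3()].
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  assert_cols(genes, c("gene_id", "seq_id", "strand", "exons"), "genes")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    gs <- min(ex$start)
    ge <- max(ex$end)
    aed <- if (!is.null(g$aed) && !is.na(g$aed)) sprintf(";aed=%g", g$aed) else ""
    doms <- if (!is.null(g$domains[[1]]) && length(g$domains[[1]]) > 0) {
      sprintf(";domains=%s", paste(g$domains[[1]], collapse = ","))
    } else {
      ""
    }
    lines <- c(
      lines,
      sprintf("%s\tnapcomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s%s",
              g$seq_id, gs + 1L, ge, g$strand, g$gene_id, aed, doms),
      sprintf("%s\tnapcomp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$seq_id, gs + 1L, ge, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tnapcomp\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
              g$seq_id, ex$start + 1L, ex$end, g$strand, g$gene_id,
              seq_len(nrow(ex)), g$gene_id)
    )
  }
  write_lines_atomic(lines, path)
  invisible(path)
}

#' Read and write doubled-haploid genotype matrices
#'
#' TSV dialect: a header row `locus_id seq_id pos allele1 allele2` followed
#' by one column per individual; one row per SNP locus with codes `a`
#' (parent 1), `b` (parent 2) or `-` (missing). Positions are 0-based. A
#' doubled-haploid population is fully homozygous, so any other code
#' (residual heterozygosity) is coerced to missing with a warning.
#'
#' @param path File path.
#' @param genotypes An `nc_genotypes` object.
#' @return `read_genotypes()` returns an `nc_genotypes` object: a list with
#'   `loci` (tibble `locus_id`, `seq_id`, `pos`, `allele1`, `allele2`),
#'   `individuals` (character) and `calls` (loci x individuals character
#'   matrix of `"P1"`/`"P2"`/`NA`).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("genotype TSV not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  meta_cols <- c("locus_id", "seq_id", "pos", "allele1", "allele2")
  assert_cols(df, meta_cols, "genotype TSV")
  inds <- setdiff(names(df), meta_cols)
  if (length(inds) == 0) abort("genotype TSV has no individual columns")
  loci <- tibble(
    locus_id = df$locus_id, seq_id = df$seq_id, pos = as.integer(df$pos),
    allele1 = df$allele1, allele2 = df$allele2
  )
  if (any(loci$allele1 == loci$allele2)) abort("SNP locus with identical alleles")
  raw <- as.matrix(df[, inds, drop = FALSE])
  calls <- matrix(NA_character_, nrow(raw), ncol(raw),
                  dimnames = list(loci$locus_id, inds))
  calls[raw == "a"] <- "P1"
  calls[raw == "b"] <- "P2"
  het <- !(raw %in% c("a", "b", "-"))
  if (any(het)) {
    warn(sprintf("%d non-homozygous genotype code(s) coerced to missing", sum(het)))
  }
  new_genotypes(loci, inds, calls)
}

new_genotypes <- function(loci, individuals, calls) {
  stopifnot(nrow(calls) == nrow(loci), ncol(calls) == length(individuals))
  structure(list(loci = loci, individuals = individuals, calls = calls),
            class = "nc_genotypes")
}

#' @export
print.nc_genotypes <- function(x, ...) {
  cat(sprintf("<nc_genotypes> %d loci x %d individuals on %d sequence(s)\n",
              nrow(x$loci), length(x$individuals), dplyr::n_distinct(x$loci$seq_id)))
  invisible(x)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "nc_genotypes"))
  codes <- genotypes$calls
  out <- matrix("-", nrow(codes), ncol(codes))
  out[codes == "P1"] <- "a"
  out[codes == "P2"] <- "b"
  df <- dplyr::bind_cols(genotypes$loci,
                         as_tibble(stats::setNames(as.data.frame(out),
                                                   genotypes$individuals)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Per-base coverage tracks
#'
#' A coverage object is a tibble with one row per (sequence, mapping mode):
#' `seq_id`, `mode` (`"unique"`, `"all"` or `"random"`) and `depth`, a
#' list-column of per-base integer depth vectors whose length equals the
#' sequence length.
#'
#' @param seq_id,mode,depth Track fields; `depth` a non-negative integer
#'   vector.
#' @return A tibble of class `nc_coverage`.
#' @export
coverage_track <- function(seq_id, mode, depth) {
  if (!mode %in% c("unique", "all", "random")) abort("unknown coverage mode")
  if (any(depth < 0)) abort("negative depth")
  out <- tibble(seq_id = seq_id, mode = mode, depth = list(as.integer(depth)))
  class(out) <- c("nc_coverage", class(out))
  out
}

bind_coverage <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("nc_coverage", class(out)))
  out
}

get_track <- function(coverage, seq, mode) {
  i <- which(coverage$seq_id == seq & coverage$mode == mode)
  if (length(i) != 1) abort(sprintf("no unique %s track for %s", mode, seq))
  coverage$depth[[i]]
}

#' Read per-base depth from bedGraph
#'
#' Positions absent from the file default to depth 0; every assembly
#' sequence gets a track. Intervals beyond the sequence end are an error.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param assembly An [as_assembly()] tibble, or a named vector of sequence
#'   lengths.
#' @param mode Mapping mode of this track.
#' @return An `nc_coverage` tibble.
#' @export
read_depth <- function(path, assembly, mode = "unique") {
  if (!file.exists(path)) abort(sprintf("bedGraph not found: %s", path))
  lens <- if (inherits(assembly, "nc_assembly") || is.data.frame(assembly)) {
    stats::setNames(assembly$length, assembly$seq_id)
  } else {
    assembly
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  depths <- lapply(lens, function(L) integer(L))
  sq <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  sc <- as.integer(S4Vectors::mcols(gr)$score)
  for (i in seq_along(gr)) {
    if (!sq[i] %in% names(depths)) abort(sprintf("unknown sequence in bedGraph: %s", sq[i]))
    if (e0[i] > lens[[sq[i]]]) abort(sprintf("bedGraph interval beyond end of %s", sq[i]))
    depths[[sq[i]]][(s0[i] + 1L):e0[i]] <- sc[i]
  }
  bind_coverage(purrr::map2(names(depths), depths,
                            function(s, d) coverage_track(s, mode, d)))
}

#' Write per-base depth as bedGraph
#'
#' Runs of equal depth are emitted as single intervals; zero-depth runs are
#' omitted (readers default them back to 0).
#'
#' @param coverage An `nc_coverage` tibble (one mode).
#' @param path Output file.
#' @export
write_depth <- function(coverage, path) {
  lines <- character()
  for (i in seq_len(nrow(coverage))) {
    d <- coverage$depth[[i]]
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    if (any(keep)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", coverage$seq_id[i],
                                starts[keep], ends[keep], r$values[keep]))
    }
  }
  write_lines_atomic(lines, path)
  invisible(path)
}

#' Read a 12-column homology hit table
#'
#' Standard tabular blast output: query, target, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, tstart, tend, e-value,
#' bit-score. Input intervals are 1-based inclusive; `tstart > tend` encodes
#' a minus-strand hit. Internally intervals become ordered 0-based half-open
#' with a `t_strand` column.
#'
#' @param path File path.
#' @return A tibble with columns `query`, `target`, `pident`, `aln_len`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `t_strand`, `evalue`,
#'   `bitscore`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort(sprintf("hit table not found: %s", path))
  df <- readr::read_tsv(
    path,
    col_names = c("query", "target", "pident", "aln_len", "mismatches",
                  "gaps", "qstart", "qend", "tstart", "tend", "evalue",
                  "bitscore"),
    col_types = "ccdiiiiiiidd", progress = FALSE
  )
  if (any(df$bitscore <= 0)) abort("non-positive bit-score in hit table")
  if (any(df$evalue < 0)) abort("negative e-value in hit table")
  tibble(
    query = df$query, target = df$target, pident = df$pident,
    aln_len = df$aln_len,
    q_start = df$qstart - 1L, q_end = df$qend,
    t_start = pmin(df$tstart, df$tend) - 1L, t_end = pmax(df$tstart, df$tend),
    t_strand = ifelse(df$tstart <= df$tend, "+", "-"),
    evalue = df$evalue, bitscore = df$bitscore
  )
}

#' Read and write k-mer multiplicity histograms
#'
#' Two-column TSV: multiplicity m (>= 1) and the number of distinct k-mers
#' observed m times.
#'
#' @param path File path.
#' @param k K-mer length the histogram was computed with (metadata only).
#' @param histogram An `nc_kmer_hist` tibble.
#' @return `read_kmer_histogram()` returns a tibble of class `nc_kmer_hist`
#'   with columns `multiplicity` and `count`, sorted by multiplicity, and a
#'   `k` attribute.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  if (!file.exists(path)) abort(sprintf("histogram not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("multiplicity", "count"),
                        col_types = "dd", progress = FALSE)
  as_kmer_histogram(df, k = k)
}

#' @rdname read_kmer_histogram
#' @export
as_kmer_histogram <- function(histogram, k = NA_integer_) {
  histogram <- as_tibble(histogram)
  assert_cols(histogram, c("multiplicity", "count"), "histogram")
  if (nrow(histogram) == 0) abort("empty k-mer histogram")
  if (any(histogram$multiplicity < 1) ||
      any(histogram$multiplicity != floor(histogram$multiplicity))) {
    abort("multiplicities must be integers >= 1")
  }
  if (any(histogram$count < 0)) abort("negative k-mer counts")
  if (anyDuplicated(histogram$multiplicity)) abort("duplicated multiplicity bin")
  out <- dplyr::arrange(histogram, .data$multiplicity)
  attr(out, "k") <- k
  class(out) <- unique(c("nc_kmer_hist", class(out)))
  out
}

#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(histogram, path) {
  write_lines_atomic(sprintf("%d\t%d", as.integer(histogram$multiplicity),
                             as.integer(histogram$count)), path)
  invisible(path)
}

#' Write region calls as BED
#'
#' Name field carries the region class, score the mean depth.
#'
#' @param regions Region tibble from [call_collapsed()]/[call_repetitive()].
#' @param path Output file.
#' @export
write_bed <- function(regions, path) {
  write_lines_atomic(
    sprintf("%s\t%d\t%d\t%s\t%s", regions$seq_id, regions$start, regions$end,
            regions$class, format(round(regions$mean_depth, 2), trim = TRUE)),
    path
  )
  invisible(path)
}

#' Write an AGP v2.1 component layout
#'
#' @param layout AGP layout tibble as produced by [build_scaffolds()] or
#'   [placement_agp()].
#' @param path Output file.
#' @export
write_agp <- function(layout, path) {
  rows <- vapply(seq_len(nrow(layout)), function(i) {
    r <- layout[i, ]
    if (r$component_type == "N") {
      sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\tmap", r$object,
              r$object_beg, r$object_end, r$part_number, r$gap_length)
    } else {
      sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s", r$object, r$object_beg,
              r$object_end, r$part_number, r$component_id, r$component_beg,
              r$component_end, r$orientation)
    }
  }, "")
  write_lines_atomic(c("##agp-version\t2.1", rows), path)
  invisible(path)
}
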