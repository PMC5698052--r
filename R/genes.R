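#' Default transposase-related domain blocklist
#'
#' Pfam-style accessions of transposase / transposable-element domains used
#' to drop TE-derived gene models during gene-set filtering. Shipped as a
#' plain-text file (`extdata/transposase_domains.txt`) so it can be swapped
#' for a custom list.
#'
#' @param path Optional path to an alternative one-accession-per-line file.
#' @return Character vector of domain accessions.
#' @export
nc_transposase_domains <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "transposase_domains.txt", package = "napcomp")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Filter a predicted gene set
#'
#' Removes gene models that are too short (total exon length below
#' `min_gene_bp`), have no evidence support (AED score of 1), or carry a
#' transposase-related protein domain. The first matching reason (in that
#' order) is recorded per removed gene.
#'
#' @param genes Gene tibble from [read_gff3()] (needs `exon_bp`, `aed`,
#'   `domains`).
#' @param config An [nc_config()].
#' @param blocklist Character vector of domain accessions; defaults to
#'   [nc_transposase_domains()].
#' @return A list with `kept` (gene tibble) and `removed` (tibble of
#'   `gene_id`, `reason` in `short` / `no-evidence` / `transposase`).
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2"), seq_id = "chrA01", strand = "+",
#'   exons = list(tibble::tibble(start = 0, end = 90),
#'                tibble::tibble(start = 0, end = 500)),
#'   exon_bp = c(90, 500), aed = c(0.2, 0.2), domains = list(character(), character())
#' )
#' filter_gene_set(genes, nc_config())$removed
#' @export
filter_gene_set <- function(genes, config = nc_config(),
                            blocklist = nc_transposase_domains()) {
  if (nrow(genes) == 0) {
    return(list(kept = genes, removed = tibble(gene_id = character(),
                                               reason = character())))
  }
  assert_cols(genes, c("gene_id", "exon_bp", "aed", "domains"), "genes")
  aed <- ifelse(is.na(genes$aed), 0, genes$aed)
  te <- purrr::map_lgl(genes$domains, function(d) any(d %in% blocklist))
  reason <- dplyr::case_when(
    genes$exon_bp < config$min_gene_bp ~ "short",
    aed >= 1 ~ "no-evidence",
    te ~ "transposase",
    TRUE ~ NA_character_
  )
  list(
    kept = genes[is.na(reason), , drop = FALSE],
    removed = tibble(gene_id = genes$gene_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  )
}
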