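#' Per-chromosome SNP density and totals
#'
#' Builds the comparison-report arithmetic: SNPs per Mbp rounded half-up to
#' the nearest integer (the convention of printed per-chromosome density
#' tables) and per-subgenome plus genome-wide totals of every count column.
#'
#' @param chromosomes Tibble with at least `name`, `snps` and `length_mbp`;
#'   any further numeric columns (gene counts, absent-gene counts) are
#'   summed into the totals.
#' @return List with `chromosomes` (input plus `snps_per_mbp`) and `totals`
#'   (one row per subgenome prefix and one `Total` row).
#' @examples
#' chromosome_report(tibble::tibble(name = "chrA01", snps = 45870,
#'                                  length_mbp = 31.16))$chromosomes
#' @export
chromosome_report <- function(chromosomes) {
  assert_cols(chromosomes, c("name", "snps", "length_mbp"), "chromosomes")
  chrom <- dplyr::mutate(
    as_tibble(chromosomes),
    snps_per_mbp = snp_density(.data$snps, .data$length_mbp)
  )
  num_cols <- names(chrom)[vapply(chrom, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, "snps_per_mbp")
  subgenome <- stringr::str_match(chrom$name, "^chr([A-Z])")[, 2]
  sub_tot <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tibble(subgenome = subgenome, chrom[num_cols]),
                    !is.na(subgenome)),
      .data$subgenome
    ),
    dplyr::across(dplyr::everything(), sum), .groups = "drop"
  )
  sub_tot <- dplyr::mutate(sub_tot, name = paste("Total", .data$subgenome),
                           .keep = "unused", .before = 1)
  grand <- dplyr::summarise(chrom[num_cols], dplyr::across(dplyr::everything(), sum))
  totals <- dplyr::bind_rows(sub_tot, dplyr::mutate(grand, name = "Total",
                                                    .before = 1))
  list(chromosomes = chrom, totals = totals)
}

#' @rdname chromosome_report
#' @param snps,length_mbp SNP count and length in Mbp.
#' @export
snp_density <- function(snps, length_mbp) {
  as.integer(round_half_up(snps / length_mbp))
}

#' Published per-chromosome comparison of the two B. napus assemblies
#'
#' The printed per-chromosome summary of the Darmor-bzh / Tapidor
#' comparison (SNP counts, pseudomolecule lengths, printed SNP densities,
#' filtered gene counts and cross-cultivar absent-gene counts), shipped as
#' plain text. These published values serve as worked-example inputs for
#' [chromosome_report()]; the density and total columns can be recomputed
#' from the count columns and checked against the printed ones.
#'
#' @return Tibble with one row per pseudomolecule plus the unplaced-contig
#'   collection.
#' @export
published_comparison_table <- function() {
  readr::read_tsv(
    system.file("extdata", "darmor_tapidor_table.tsv", package = "napcomp"),
    col_types = readr::cols(name = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}
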