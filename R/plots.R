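#' Plot per-chromosome region counts
#'
#' Bar chart of collapsed/repetitive region counts by chromosome, the usual
#' way two assemblies' region landscapes are compared.
#'
#' @param regions Region tibble (optionally from several assemblies bound
#'   together with an `assembly` column, mapped to fill).
#' @return A ggplot object.
#' @export
plot_region_counts <- function(regions) {
  counts <- if ("assembly" %in% names(regions)) {
    dplyr::count(regions, .data$seq_id, .data$class, .data$assembly)
  } else {
    dplyr::count(regions, .data$seq_id, .data$class)
  }
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$seq_id, y = .data$n)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if ("assembly" %in% names(counts)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$assembly),
                          position = "dodge")
  } else {
    p + ggplot2::geom_col()
  }
}

#' @rdname fit_kmer_sizes
#' @param object An `nc_kmer_fit`.
#' @method autoplot nc_kmer_fit
#' @export
autoplot.nc_kmer_fit <- function(object, ...) {
  h <- as_tibble(object$histogram)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$multiplicity, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$valley, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$peak, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = sprintf("genome %.1f Mbp / assembly %.1f Mbp",
                                  object$genome_size / 1e6,
                                  object$assembly_size / 1e6)) +
    ggplot2::theme_minimal()
}

#' @rdname place_all
#' @param object An `nc_placement`.
#' @method autoplot nc_placement
#' @export
autoplot.nc_placement <- function(object, ...) {
  counts <- dplyr::count(object, .data$status)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contigs") +
    ggplot2::theme_minimal()
}
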