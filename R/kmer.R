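#' Locate the error valley and coverage peak of a k-mer histogram
#'
#' Sequencing errors concentrate distinct k-mers at multiplicity 1-2; the
#' true single-copy coverage shows as a peak at higher multiplicity. The
#' valley v is the first local minimum scanning the (sparse, ordered)
#' multiplicities upward from 1; with no local minimum v = 0. The peak p is
#' the count-maximizing multiplicity above v (modal ties resolve to the
#' smaller multiplicity). A histogram that only decays monotonically -- an
#' error-only curve with no coverage peak -- is an error.
#'
#' @param histogram `nc_kmer_hist` tibble from [read_kmer_histogram()].
#' @param smooth Apply a width-3 moving average to the counts before peak
#'   detection (for noisy histograms).
#' @return List with `valley` and `peak` multiplicities.
#' @examples
#' h <- as_kmer_histogram(tibble::tibble(
#'   multiplicity = c(1, 2, 3, 10, 20, 30),
#'   count = c(5e6, 1e5, 1e3, 8e5, 1e6, 7e5)
#' ))
#' find_error_valley_and_peak(h)
#' @export
find_error_valley_and_peak <- function(histogram, smooth = FALSE) {
  m <- histogram$multiplicity
  cnt <- histogram$count
  if (smooth && length(cnt) >= 3) {
    cnt <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
    cnt[is.na(cnt)] <- histogram$count[is.na(cnt)]
    cnt <- as.numeric(cnt)
  }
  n <- length(m)
  valley <- 0
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (cnt[i - 1] > cnt[i] && cnt[i] <= cnt[i + 1]) {
        valley <- m[i]
        break
      }
    }
  }
  cand <- which(m > valley)
  if (length(cand) == 0) abort("no multiplicities beyond the valley")
  peak <- m[cand][which.max(cnt[cand])]
  if (valley == 0 && n >= 2 && peak == m[1] && all(diff(cnt) <= 0)) {
    abort("no coverage peak: histogram decays monotonically (error-only)")
  }
  list(valley = valley, peak = peak)
}

#' Genome and assembly size from a k-mer histogram
#'
#' Solid k-mers are those with multiplicity above the error valley v. The
#' genome size estimate `sum(m * count[m]) / p` (m > v) accounts for
#' coverage and copy number: every genomic copy of a k-mer contributes its
#' coverage to the numerator. The expected assembly size is simply the
#' number of *distinct* solid k-mers, since an assembler represents each
#' distinct sequence once however many times it occurs. The gap between the
#' two is the repeat content an assembly is expected to collapse, hence
#' genome size >= assembly size always.
#'
#' With `refine_peak = TRUE` (default) the divisor is a sub-integer peak
#' refinement: the count-weighted mean multiplicity over the solid bins
#' whose counts reach half the peak count (restricted to within p/2 of p so
#' higher-copy peaks stay out). At integer coverage c a Poisson histogram
#' has an exact modal tie at c-1/c, so the raw argmax alone would inject a
#' ~1/c relative error; the half-max centroid is insensitive to which side
#' of the tie the argmax lands on.
#'
#' @param histogram `nc_kmer_hist` tibble.
#' @param valley,peak From [find_error_valley_and_peak()].
#' @param refine_peak Use the local-centroid divisor.
#' @return List with `genome_size`, `assembly_size` (bp) and `peak_used`.
#' @examples
#' h <- as_kmer_histogram(tibble::tibble(multiplicity = c(20, 40),
#'                                       count = c(9e5, 5e4)))
#' estimate_sizes(h, valley = 0, peak = 20)
#' @export
estimate_sizes <- function(histogram, valley, peak, refine_peak = TRUE) {
  if (peak <= valley) abort("peak must exceed valley")
  m <- histogram$multiplicity
  cnt <- histogram$count
  solid <- m > valley
  p_used <- peak
  if (refine_peak) {
    cmax <- cnt[m == peak]
    w <- solid & cnt >= cmax / 2 & abs(m - peak) <= peak / 2
    p_used <- sum(m[w] * cnt[w]) / sum(cnt[w])
  }
  list(
    genome_size = sum(m[solid] * cnt[solid]) / p_used,
    assembly_size = sum(cnt[solid]),
    peak_used = p_used
  )
}

#' Fit a k-mer histogram: valley, peak, genome and assembly size
#'
#' One-stop wrapper combining [find_error_valley_and_peak()] and
#' [estimate_sizes()]. Returns a fitted object with [tidy()], [glance()]
#' and [ggplot2::autoplot()] methods.
#'
#' @inheritParams find_error_valley_and_peak
#' @inheritParams estimate_sizes
#' @return An object of class `nc_kmer_fit`.
#' @export
fit_kmer_sizes <- function(histogram, smooth = FALSE, refine_peak = TRUE) {
  vp <- find_error_valley_and_peak(histogram, smooth = smooth)
  sz <- estimate_sizes(histogram, vp$valley, vp$peak, refine_peak = refine_peak)
  structure(
    list(histogram = histogram, k = attr(histogram, "k"),
         valley = vp$valley, peak = vp$peak, peak_used = sz$peak_used,
         genome_size = sz$genome_size, assembly_size = sz$assembly_size),
    class = "nc_kmer_fit"
  )
}

#' @export
print.nc_kmer_fit <- function(x, ...) {
  cat(sprintf(
    "<nc_kmer_fit> valley %g, peak %g (divisor %.2f)\n  genome size %.0f bp, expected assembly size %.0f bp\n",
    x$valley, x$peak, x$peak_used, x$genome_size, x$assembly_size
  ))
  invisible(x)
}

#' @rdname fit_kmer_sizes
#' @param x An `nc_kmer_fit` object.
#' @param ... Unused.
#' @method tidy nc_kmer_fit
#' @export
tidy.nc_kmer_fit <- function(x, ...) {
  tibble(
    term = c("valley", "peak", "peak_used", "genome_size", "assembly_size"),
    value = c(x$valley, x$peak, x$peak_used, x$genome_size, x$assembly_size)
  )
}

#' @rdname fit_kmer_sizes
#' @method glance nc_kmer_fit
#' @export
glance.nc_kmer_fit <- function(x, ...) {
  tibble(genome_size = x$genome_size, assembly_size = x$assembly_size,
         valley = x$valley, peak = x$peak)
}

#' Write a k-mer sizing report as JSON
#'
#' @param fit An `nc_kmer_fit`.
#' @param path Output path.
#' @export
write_kmer_report <- function(fit, path) {
  jsonlite::write_json(
    list(k = fit$k, valley = fit$valley, peak = fit$peak,
         genome_size = fit$genome_size, assembly_size = fit$assembly_size),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
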