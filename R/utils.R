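#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Genotype codes used throughout: "P1", "P2", NA (missing).
GT_CODES <- c("P1", "P2")

round_half_up <- function(x, digits = 0) {
  # base round() is banker's rounding; printed SNP densities use half-up
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the previous RNG
#' state afterwards, so simulation helpers do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Write `lines` to `path` atomically (tempfile in the same directory, then
# rename), so an interrupted run never leaves a partial output behind.
write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
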