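# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `code` with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Trimmed mean over the central fraction of values
#'
#' Removes `ceiling(trim * n)` values from each tail (after sorting) and
#' averages the remainder, i.e. the mean over the central `1 - 2 * trim`
#' fraction of cells. Falls back to the plain mean when trimming would leave
#' nothing.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed from each tail, in `[0, 0.5)`.
#' @return a single numeric value.
#' @export
trimmed_mean <- function(x, trim = 0.1) {
  n <- length(x)
  if (n == 0L) return(NaN)
  if (trim < 0 || trim >= 0.5) stop("`trim` must be in [0, 0.5)")
  # guard against FP noise in trim * n (e.g. 0.1 * 30)
  k <- as.integer(ceiling(trim * n - 1e-9))
  if (2L * k >= n) return(mean(x))
  xs <- sort(x)
  mean(xs[(k + 1L):(n - k)])
}

# dense column means/vars that also work on Matrix sparse classes
col_means <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colMeans(x) else colMeans(x)
}

col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  m <- col_means(x)
  m2 <- if (inherits(x, "Matrix")) Matrix::colMeans(x^2) else colMeans(x^2)
  (m2 - m^2) * n / (n - 1)
}

row_sums <- function(x) {
  if (inherits(x, "Matrix")) Matrix::rowSums(x) else rowSums(x)
}
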