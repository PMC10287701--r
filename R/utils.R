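#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded analyses do not perturb the global
#' random stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# stop() with sprintf-style formatting, without call noise
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# equal spacing check used before any FFT (tolerance in ms)
is_equally_spaced <- function(x, tol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1L])) <= tol
}

# finite-sample permutation p-value with plus-one smoothing: always in (0, 1]
perm_pvalue <- function(n_exceed, n_iter) (1 + n_exceed) / (1 + n_iter)
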