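# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. seed = NULL leaves the RNG untouched.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` child seeds from one master seed, so that
# independent stochastic stages never share a stream.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Permutation p-value with the +1 convention (observed counted once).
#' @keywords internal
#' @noRd
perm_pvalue <- function(stat_obs, stat_perm, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  if (tail == "two.sided") {
    stat_obs <- abs(stat_obs)
    stat_perm <- abs(stat_perm)
  }
  tol <- 1e-8 * max(1, abs(stat_obs))
  (sum(stat_perm >= stat_obs - tol) + 1) / (length(stat_perm) + 1)
}
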