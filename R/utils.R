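#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched. All stochastic operations in the package go
# through this so that no generator leaks global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index, staying within
# the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647L)
}

# AIC for weighted least squares with known per-point variances:
# -2 log L = chi2 + const, so AIC = chi2 + 2k up to a model-independent
# constant (the constant cancels in comparisons on the same data).
# With a finite n_obs the small-sample (AICc) penalty is added, which
# matters when the point count per parameter is low (e.g. 40 histogram
# bins vs 6 mixture parameters).
aic_wls <- function(chi2, n_par, n_obs = Inf) {
  corr <- if (is.finite(n_obs) && n_obs > n_par + 1)
    2 * n_par * (n_par + 1) / (n_obs - n_par - 1) else 0
  chi2 + 2 * n_par + corr
}

# Parsimony rule: the smallest model within `delta` AIC units of the
# minimum wins (substantial-support threshold).
pick_by_aic <- function(aics, delta = 2) {
  best <- min(aics)
  which(aics <= best + delta)[1L]
}

stop_if_not_sorted <- function(x, what = "timestamps") {
  if (is.unsorted(x)) stop(what, " must be sorted in ascending order")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
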