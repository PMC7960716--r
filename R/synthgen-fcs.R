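#' Simulate a noisy FCS correlation curve
#'
#' Evaluates the PET-FCS model on the supplied lag grid and adds
#' zero-mean Gaussian noise with standard deviation `noise_sd` times the
#' model amplitude at the first lag (uniform absolute noise). The `sem`
#' column carries that standard deviation so fits can weight points.
#'
#' @param params an [fcs_params()] ground truth.
#' @param lags strictly increasing positive lag grid, us.
#' @param noise_sd fractional noise level relative to G at the first lag;
#'   0 returns the closed-form model exactly.
#' @param seed integer seed.
#' @param condition_label optional label attached to the curve.
#' @return A data.frame of class `fcs_curve` with `lag_us`, `G`, `sem`.
#' @export
simulate_fcs_curve <- function(params, lags, noise_sd = 0.002, seed = 1L,
                               condition_label = "synthetic") {
  stopifnot(inherits(params, "fcs_params"))
  if (any(lags <= 0)) stop("lags must be strictly positive")
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be strictly increasing")
  g <- fcs_model(params, lags)
  sd_abs <- noise_sd * g[1]
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(lags), 0, sd_abs)) else 0
  out <- data.frame(lag_us = lags, G = g + noise,
                    sem = rep(max(sd_abs, .Machine$double.eps), length(lags)))
  attr(out, "condition_label") <- condition_label
  class(out) <- c("fcs_curve", "data.frame")
  out
}

#' Quasi-logarithmic lag grid
#'
#' @param from,to grid limits, us.
#' @param n number of lags.
#' @return numeric vector of log-spaced lags.
#' @export
log_lag_grid <- function(from = 0.01, to = 1e6, n = 200) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}
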