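#' Fit a Gaussian mixture to a FRET efficiency histogram
#'
#' Efficiencies are binned on `n_bins` equal bins over `range` (the
#' default overshoots \[0, 1\] slightly to accommodate corrected values)
#' and the histogram is fitted by weighted least squares to a sum of
#' `n_components` Gaussians with Poisson weights 1/max(count, 1).
#' Component weights are area fractions; the mixture mean and the FWHM of
#' the fitted curve are reported alongside.
#'
#' @param e_values FRET efficiencies (fractions in roughly \[0, 1\]).
#' @param n_components number of Gaussian components.
#' @param n_bins,range histogram binning (40 bins over \[-0.1, 1.1\]).
#' @param init optional list with `centers`, `sigmas`, `heights` starting
#'   values (used by the bootstrap to seed replicate fits).
#' @return An object of class `mixture_fit`: `components` (data.frame
#'   with `center`, `sigma`, `weight`, sorted by center), `mean_E`,
#'   `fwhm_E`, `chi2`, `chi2_red`, `aic`, `converged`, `collapsed`
#'   (`TRUE` when two components are indistinguishable) and the fitted
#'   histogram.
#' @export
fit_fret_mixture <- function(e_values, n_components = 2, n_bins = 40,
                             range = c(-0.1, 1.1), init = NULL) {
  e_values <- e_values[is.finite(e_values)]
  if (length(e_values) < 50) stop("need at least 50 efficiency values")
  if (stats::sd(e_values) < 1e-12)
    stop("degenerate data: all efficiencies identical, refusing to fit")
  stopifnot(n_components >= 1)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  h <- graphics::hist(pmin(pmax(e_values, range[1]), range[2]),
                      breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  w <- 1 / pmax(y, 1)
  k <- n_components

  model_fun <- function(par) {
    mu <- par[seq_len(k)]
    sig <- exp(par[k + seq_len(k)])
    hh <- exp(par[2 * k + seq_len(k)])
    rowSums(sapply(seq_len(k), function(i)
      hh[i] * exp(-(x - mu[i])^2 / (2 * sig[i]^2))))
  }
  resid_fun <- function(par) sqrt(w) * (y - model_fun(par))

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- c(init$centers, log(init$sigmas), log(pmax(init$heights, 1e-6)))
  } else {
    qs <- stats::quantile(e_values, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    s0 <- max(stats::sd(e_values) / sqrt(k), 0.02)
    h0 <- max(y) / k
    starts[[1]] <- c(qs, rep(log(s0), k), rep(log(h0), k))
    if (k > 1) {
      sp <- seq(stats::quantile(e_values, 0.1), stats::quantile(e_values, 0.9),
                length.out = k)
      starts[[2]] <- c(sp, rep(log(s0), k), rep(log(h0), k))
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2_val) {
      best <- fit
      best$chi2_val <- chi2
    }
  }
  if (is.null(best)) stop("mixture fit failed to converge from all starts")

  par <- best$par
  mu <- par[seq_len(k)]
  sig <- exp(par[k + seq_len(k)])
  hh <- exp(par[2 * k + seq_len(k)])
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; hh <- hh[ord]
  area <- hh * sig
  wts <- area / sum(area)
  collapsed <- k > 1 && any(diff(mu) < 1e-3 + pmin(sig[-k], sig[-1]) / 10)

  dense_x <- seq(range[1], range[2], length.out = 2000)
  dense_y <- rowSums(sapply(seq_len(k), function(i)
    hh[i] * exp(-(dense_x - mu[i])^2 / (2 * sig[i]^2))))
  half <- max(dense_y) / 2
  above <- which(dense_y >= half)
  fwhm <- dense_x[max(above)] - dense_x[min(above)]

  n_par <- 3 * k
  chi2 <- best$chi2_val
  structure(list(
    components = data.frame(center = mu, sigma = sig, weight = wts,
                            height = hh),
    n_components = k,
    mean_E = sum(wts * mu),
    fwhm_E = fwhm,
    chi2 = chi2,
    chi2_red = chi2 / (length(y) - n_par),
    aic = aic_wls(chi2, n_par, length(y)),
    converged = best$info %in% 1:4,
    collapsed = collapsed,
    histogram = data.frame(mid = x, counts = y,
                           fitted = model_fun(best$par)),
    n_values = length(e_values),
    range = range, n_bins = n_bins),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d component(s), n = %d bursts\n",
              x$n_components, x$n_values))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  E_%d = %.1f%%  sigma = %.1f%%  weight = %.2f\n",
                i, 100 * comp$center[i], 100 * comp$sigma[i], comp$weight[i]))
  cat(sprintf("  <E> = %.1f%%  dE_FWHM = %.1f%%  chi2_red = %.2f  AIC = %.1f\n",
              100 * x$mean_E, 100 * x$fwhm_E, x$chi2_red, x$aic))
  invisible(x)
}

#' Choose the number of FRET states by AIC
#'
#' Fits 1..`max_components` Gaussians and returns the most parsimonious
#' fit whose AIC is within `delta_aic` of the minimum.
#'
#' @param e_values FRET efficiencies.
#' @param max_components largest mixture size tried.
#' @param delta_aic parsimony margin (AIC units).
#' @param ... passed to [fit_fret_mixture()].
#' @return The selected `mixture_fit`.
#' @export
select_fret_model <- function(e_values, max_components = 2, delta_aic = 2, ...) {
  fits <- lapply(seq_len(max_components), function(kc)
    tryCatch(fit_fret_mixture(e_values, n_components = kc, ...),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no mixture size converged")
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  fits[[pick_by_aic(aics, delta_aic)]]
}

#' Bootstrap standard errors for a mixture fit
#'
#' Resamples the efficiency values with replacement, refits the chosen
#' mixture (seeded from the full-data solution) and reports the standard
#' deviation of every parameter across replicates. Non-convergent
#' replicates are dropped and counted.
#'
#' @param e_values FRET efficiencies used for the original fit.
#' @param fit the `mixture_fit` whose parameters are to be bootstrapped.
#' @param n_reps replicate count (2000 by default).
#' @param seed master seed; replicate seeds are derived from it.
#' @return A list with `se` (data.frame of `center`, `sigma`, `weight`
#'   SEs per component), `se_mean_E`, `se_fwhm_E`, `n_used`, `n_dropped`.
#' @export
bootstrap_mixture <- function(e_values, fit, n_reps = 2000, seed = 1L) {
  stopifnot(inherits(fit, "mixture_fit"))
  e_values <- e_values[is.finite(e_values)]
  k <- fit$n_components
  init <- list(centers = fit$components$center,
               sigmas = fit$components$sigma,
               heights = fit$components$height)
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    samp <- with_seed(derive_seed(seed, r),
                      sample(e_values, length(e_values), replace = TRUE))
    f <- tryCatch(
      fit_fret_mixture(samp, n_components = k, n_bins = fit$n_bins,
                       range = fit$range, init = init),
      error = function(e) NULL)
    if (!is.null(f) && f$converged)
      res[[r]] <- c(f$components$center, f$components$sigma,
                    f$components$weight, f$mean_E, f$fwhm_E)
  }
  keep <- !vapply(res, is.null, logical(1))
  n_drop <- sum(!keep)
  if (n_drop > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_drop, n_reps))
  mat <- do.call(rbind, res[keep])
  sds <- apply(mat, 2, stats::sd)
  list(se = data.frame(center = sds[seq_len(k)],
                       sigma = sds[k + seq_len(k)],
                       weight = sds[2 * k + seq_len(k)]),
       se_mean_E = sds[3 * k + 1],
       se_fwhm_E = sds[3 * k + 2],
       n_used = sum(keep), n_dropped = n_drop)
}
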