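# --- parameter packing -------------------------------------------------
# Free parameters live on unconstrained scales: log for positive
# quantities, log(s - 1) for the ellipticity. Quench lifetimes are
# constrained below tau_d/2 through a logistic map — an exponential as
# slow as the diffusion time is not identifiable as blinking and would
# otherwise be free to reshape the diffusion shoulder. Lifetimes are
# kept ordered by sorting at unpack time.

pack_fcs <- function(p) {
  c(log(p$n_mean), log(p$tau_d), log(p$s - 1), log(max(p$k_trip, 1e-6)),
    log(p$t_trip),
    if (length(p$quench_amps))
      as.numeric(rbind(
        log(pmax(p$quench_amps, 1e-6)),
        stats::qlogis(pmin(p$quench_taus / (p$tau_d / 2), 0.999)))))
}

unpack_fcs <- function(par, n_quench) {
  tau_d <- exp(par[2])
  qa <- qt <- numeric(0)
  if (n_quench > 0) {
    rest <- par[-(1:5)]
    qa <- exp(rest[seq(1, 2 * n_quench, by = 2)])
    qt <- (tau_d / 2) * stats::plogis(rest[seq(2, 2 * n_quench, by = 2)])
    ord <- order(qt)
    qa <- qa[ord]; qt <- qt[ord]
  }
  fcs_params(n_mean = exp(par[1]), tau_d = tau_d, s = 1 + exp(par[3]),
             k_trip = exp(par[4]), t_trip = exp(par[5]),
             quench_amps = qa, quench_taus = qt)
}

# Data-driven starting values: diffusion from the curve tail (2-parameter
# fit with the ellipticity pinned; the tail alone cannot separate all
# three diffusion parameters), blinking amplitudes/lifetimes from the
# ratio of the data to the tail fit.
fcs_start_values <- function(curve, n_quench, t_trip0 = 5, s0 = 4) {
  lag <- curve$lag_us
  g <- curve$G
  half_idx <- which(g < g[1] / 2)[1] %||% length(lag)
  tau_half <- lag[half_idx]
  tail_idx <- which(lag >= tau_half)
  if (length(tail_idx) < 8)
    tail_idx <- seq(max(1, length(lag) - 8), length(lag))
  resid_tail <- function(par) {
    p <- fcs_params(n_mean = exp(par[1]), tau_d = exp(par[2]), s = s0)
    g[tail_idx] - fcs_model(p, lag[tail_idx])
  }
  t0 <- c(log(1 / max(g[1] / 2, 1e-4)), log(tau_half))
  tf <- tryCatch(minpack.lm::nls.lm(par = t0, fn = resid_tail),
                 error = function(e) NULL)
  par_diff <- if (!is.null(tf)) tf$par else t0
  # discard a runaway tail fit
  if (!is.finite(par_diff[1]) || !is.finite(par_diff[2]) ||
      exp(par_diff[2]) < min(lag) || exp(par_diff[2]) > 100 * max(lag) ||
      exp(par_diff[1]) < 1e-6 || exp(par_diff[1]) > 1e6)
    par_diff <- t0
  p_diff <- fcs_params(n_mean = exp(par_diff[1]), tau_d = exp(par_diff[2]),
                       s = s0)
  # blinking ratio (clipped away from 0)
  ratio <- pmax(g / fcs_model(p_diff, lag) - 1, 1e-4)
  if (n_quench > 0) {
    qt0 <- exp(seq(log(lag[2] * 5), log(p_diff$tau_d / 2),
                   length.out = n_quench + 1))[seq_len(n_quench)]
    # enforce >= x2 separation between starting lifetimes
    for (i in seq_len(n_quench)[-1])
      qt0[i] <- max(qt0[i], 2 * qt0[i - 1])
    amp0 <- rep(max(ratio[1], 0.05) / (n_quench + 1), n_quench)
  } else {
    qt0 <- numeric(0); amp0 <- numeric(0)
  }
  fcs_params(n_mean = p_diff$n_mean, tau_d = p_diff$tau_d, s = p_diff$s,
             k_trip = max(ratio[1], 0.05) / (n_quench + 1), t_trip = t_trip0,
             quench_amps = amp0, quench_taus = qt0)
}

# The triplet and quenching exponentials of the blinking factor are
# mathematically exchangeable; after a fit, give the triplet label to
# the component whose lifetime is nearest (in log space) to the triplet
# prior carried by the initialization (the free-dye benchmark scale).
relabel_triplet <- function(params, t_trip_prior) {
  if (!length(params$quench_taus)) return(params)
  taus <- c(params$t_trip, params$quench_taus)
  amps <- c(params$k_trip, params$quench_amps)
  pick <- which.min(abs(log(taus) - log(t_trip_prior)))
  ord <- order(taus[-pick])
  fcs_params(n_mean = params$n_mean, tau_d = params$tau_d, s = params$s,
             k_trip = amps[pick], t_trip = taus[pick],
             quench_amps = amps[-pick][ord], quench_taus = taus[-pick][ord])
}

#' Fit the PET-FCS model to one correlation curve
#'
#' Weighted least squares (weights 1/sem when available, else uniform)
#' of the diffusion x triplet x quenching model with `n_quench` quenching
#' exponentials. Starting values are derived from the curve (diffusion
#' from the tail, blinking from the short-lag excess) and the
#' Levenberg-Marquardt fit is repeated from `n_starts` jittered starting
#' points to avoid local minima of the ill-conditioned multi-component
#' model; the lowest-chi2 solution is returned.
#'
#' @param curve data.frame with `lag_us`, `G` and optionally `sem`.
#' @param n_quench number of quenching components (0-3).
#' @param n_starts number of seeded multi-start restarts.
#' @param seed seed for the start jitter.
#' @param init optional [fcs_params()] starting point.
#' @return list of class `fcs_fit`: `params` ([fcs_params()]), `chi2`,
#'   `chi2_red`, `aic`, `converged`, `at_bound`, `fitted`.
#' @export
fcs_fit <- function(curve, n_quench = 3, n_starts = 5, seed = 1L,
                    init = NULL) {
  stopifnot(all(c("lag_us", "G") %in% names(curve)), n_quench %in% 0:3)
  lag <- curve$lag_us
  if (log10(max(lag) / min(lag)) < 4)
    warning("curve spans fewer than 4 decades of lag; fit may be unstable")
  w <- if ("sem" %in% names(curve) && all(curve$sem > 0))
    1 / curve$sem^2 else rep(1, length(lag))
  resid_fun <- function(par) {
    p <- unpack_fcs(par, n_quench)
    sqrt(w) * (curve$G - fcs_model(p, lag))
  }
  p0 <- init %||% fcs_start_values(curve, n_quench)
  base <- pack_fcs(p0)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) base else
      base + with_seed(derive_seed(seed, s),
                       stats::rnorm(length(base), 0, 0.3))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2_val) {
      best <- fit; best$chi2_val <- chi2
    }
  }
  if (is.null(best)) stop("FCS fit failed to converge from all starts")
  params <- unpack_fcs(best$par, n_quench)
  params <- relabel_triplet(params, t_trip_prior = p0$t_trip)
  n_par <- length(best$par)
  at_bound <- any(abs(best$par) > 20)
  structure(list(params = params, chi2 = best$chi2_val,
                 chi2_red = best$chi2_val / (length(lag) - n_par),
                 aic = aic_wls(best$chi2_val, n_par, length(lag)),
                 converged = best$info %in% 1:4, at_bound = at_bound,
                 fitted = data.frame(lag_us = lag,
                                     G = fcs_model(params, lag))),
            class = "fcs_fit")
}

#' Select the number of quenching components by AIC
#'
#' Fits 0 to `max_quench` quenching terms and returns the most
#' parsimonious fit within `delta_aic` of the minimum AIC.
#'
#' @param curve correlation curve.
#' @param max_quench largest number of quenching terms tried.
#' @param delta_aic parsimony margin.
#' @param ... passed to [fcs_fit()].
#' @return the selected `fcs_fit` (element `n_quench` gives the count).
#' @export
fcs_select_quench_terms <- function(curve, max_quench = 3, delta_aic = 2, ...) {
  fits <- vector("list", max_quench + 1)
  for (nq in 0:max_quench) {
    f <- tryCatch(fcs_fit(curve, n_quench = nq, ...), error = function(e) NULL)
    # nested refinement: grow the previous solution by one small term so
    # the larger model always starts from (at least) the smaller model's
    # optimum; guards against under-converged comparisons
    prev <- if (nq > 0) fits[[nq]] else NULL
    if (!is.null(prev)) {
      p <- prev$params
      new_tau <- if (length(p$quench_taus))
        sqrt(max(p$quench_taus) * p$tau_d) else sqrt(p$t_trip * p$tau_d)
      grown <- fcs_params(n_mean = p$n_mean, tau_d = p$tau_d, s = p$s,
                          k_trip = p$k_trip, t_trip = p$t_trip,
                          quench_amps = c(p$quench_amps, 0.01),
                          quench_taus = c(p$quench_taus, new_tau))
      f2 <- tryCatch(fcs_fit(curve, n_quench = nq, init = grown, ...),
                     error = function(e) NULL)
      if (!is.null(f2) && (is.null(f) || f2$chi2 < f$chi2)) f <- f2
    }
    fits[[nq + 1]] <- f
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no quench-term count converged")
  idx <- which(ok)
  aics <- vapply(fits[idx], function(f) f$aic, numeric(1))
  pick <- idx[pick_by_aic(aics, delta_aic)]
  sel <- fits[[pick]]
  sel$n_quench <- pick - 1L
  sel
}

#' Global PET-FCS fit with shared parameters
#'
#' Jointly fits several correlation curves measured under different
#' conditions, with the triplet lifetime (and optionally other
#' parameters) shared across curves and everything else per-curve.
#'
#' @param curves list of correlation curves (each `lag_us`, `G`, `sem`).
#' @param n_quench quenching components per curve.
#' @param shared character vector of shared parameter names (currently
#'   `"t_trip"` supported).
#' @param seed seed for multi-start jitter of the per-curve
#'   initializations.
#' @return list of class `fcs_global_fit`: `fits` (per-curve
#'   [fcs_params()]), `shared` (named list of shared values), `chi2`
#'   (joint), `chi2_per_curve`, `aic`.
#' @export
fcs_fit_global <- function(curves, n_quench = 3, shared = "t_trip",
                           seed = 1L) {
  stopifnot(length(curves) >= 2, identical(shared, "t_trip"))
  singles <- lapply(seq_along(curves), function(i)
    fcs_fit(curves[[i]], n_quench = n_quench, seed = derive_seed(seed, i)))
  t_trip0 <- mean(vapply(singles, function(f) f$params$t_trip, numeric(1)))
  # per-curve packed parameters without t_trip (position 5)
  per_curve0 <- lapply(singles, function(f) pack_fcs(f$params)[-5])
  n_pc <- length(per_curve0[[1]])
  par0 <- c(log(t_trip0), unlist(per_curve0))
  wts <- lapply(curves, function(cv)
    if ("sem" %in% names(cv) && all(cv$sem > 0)) 1 / cv$sem^2
    else rep(1, nrow(cv)))
  resid_fun <- function(par) {
    tt <- exp(par[1])
    unlist(lapply(seq_along(curves), function(i) {
      pc <- par[1 + (i - 1) * n_pc + seq_len(n_pc)]
      full <- append(pc, log(tt), after = 4)
      p <- unpack_fcs(full, n_quench)
      sqrt(wts[[i]]) * (curves[[i]]$G - fcs_model(p, curves[[i]]$lag_us))
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  tt <- exp(fit$par[1])
  fits <- lapply(seq_along(curves), function(i) {
    pc <- fit$par[1 + (i - 1) * n_pc + seq_len(n_pc)]
    unpack_fcs(append(pc, log(tt), after = 4), n_quench)
  })
  res_per <- lapply(seq_along(curves), function(i) {
    p <- fits[[i]]
    sum(wts[[i]] * (curves[[i]]$G - fcs_model(p, curves[[i]]$lag_us))^2)
  })
  chi2 <- sum(fit$fvec^2)
  structure(list(fits = fits, shared = list(t_trip = tt), chi2 = chi2,
                 chi2_per_curve = unlist(res_per),
                 aic = aic_wls(chi2, length(par0)),
                 converged = fit$info %in% 1:4,
                 singles = singles),
            class = "fcs_global_fit")
}

#' Remove the diffusion component from an FCS curve
#'
#' Subtracts the pure-diffusion term (blinking factor set to 1) of the
#' fitted model from both the data and the fitted curve, leaving only the
#' triplet and quenching decays for display.
#'
#' @param curve correlation curve (`lag_us`, `G`).
#' @param params fitted [fcs_params()].
#' @return data.frame with `lag_us`, `G_sub` (data minus diffusion) and
#'   `fitted_sub` (fit minus diffusion).
#' @export
subtract_diffusion <- function(curve, params) {
  stopifnot(inherits(params, "fcs_params"))
  g_diff <- fcs_model(params, curve$lag_us, blinking = FALSE)
  data.frame(lag_us = curve$lag_us,
             G_sub = curve$G - g_diff,
             fitted_sub = fcs_model(params, curve$lag_us) - g_diff)
}
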