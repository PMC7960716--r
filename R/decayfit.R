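#' Isotropic (rotation-free) decay from polarized channels
#'
#' F(t) = I_par(t) + 2 G I_perp(t), the denominator of the anisotropy
#' estimator; its shape is independent of rotational depolarization.
#'
#' @param pd data.frame with `bin_ns`, `counts_par`, `counts_perp`.
#' @param g_factor polarization sensitivity correction G.
#' @return data.frame with `bin_ns` and `counts`.
#' @export
isotropic_decay <- function(pd, g_factor = 1) {
  stopifnot(all(c("bin_ns", "counts_par", "counts_perp") %in% names(pd)),
            g_factor > 0)
  data.frame(bin_ns = pd$bin_ns,
             counts = pd$counts_par + 2 * g_factor * pd$counts_perp)
}

#' Time-resolved anisotropy from polarized channels
#'
#' r(t) = (I_par - G I_perp) / (I_par + 2 G I_perp). Bins whose total
#' count falls below `floor_counts` are masked (dropped); the per-bin
#' uncertainty is propagated from Poisson counting statistics.
#'
#' @param pd data.frame with `bin_ns`, `counts_par`, `counts_perp`.
#' @param g_factor polarization sensitivity correction G.
#' @param floor_counts minimal `counts_par + counts_perp` per retained bin.
#' @return data.frame with `bin_ns`, `r` and `sigma_r`.
#' @export
anisotropy_curve <- function(pd, g_factor = 1, floor_counts = 100) {
  stopifnot(all(c("bin_ns", "counts_par", "counts_perp") %in% names(pd)),
            g_factor > 0)
  p <- pd$counts_par
  q <- pd$counts_perp
  keep <- (p + q) >= floor_counts
  if (!any(keep)) stop("all bins fall below the count floor; no anisotropy curve")
  p <- p[keep]; q <- q[keep]
  g <- g_factor
  den <- p + 2 * g * q
  r <- (p - g * q) / den
  # delta-method Poisson propagation: var = 9 g^2 p q (p + q) / den^4
  var_r <- 9 * g^2 * p * q * (p + q) / den^4
  data.frame(bin_ns = pd$bin_ns[keep], r = r,
             sigma_r = sqrt(pmax(var_r, 1e-12)))
}

# Shared LM driver for sums of exponentials fitted to (x, y, w). With
# poisson = TRUE the weights are iteratively refreshed from the model
# (1/max(fitted, 1)), approximating Poisson maximum likelihood and
# removing the small downward bias of observed-count weighting.
fit_exp_sum <- function(x, y, w, k, tau_starts, c_starts, poisson = FALSE) {
  model_fun <- function(par) {
    tau <- exp(par[seq_len(k)])
    cc <- exp(par[k + seq_len(k)])
    rowSums(sapply(seq_len(k), function(i) cc[i] * exp(-x / tau[i])))
  }
  par <- c(log(tau_starts), log(c_starts))
  n_pass <- if (poisson) 3 else 1
  for (pass in seq_len(n_pass)) {
    resid_fun <- local({
      wp <- w
      function(par) sqrt(wp) * (y - model_fun(par))
    })
    fit <- minpack.lm::nls.lm(par = par, fn = resid_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    par <- fit$par
    if (poisson) w <- 1 / pmax(model_fun(par), 1)
  }
  tau <- exp(par[seq_len(k)])
  cc <- exp(par[k + seq_len(k)])
  list(tau = tau, coef = cc, chi2 = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

#' Fit a multi-exponential fluorescence decay
#'
#' Fits the histogram to F(t) = sum_i c_i exp(-t / tau_i) by weighted
#' least squares with Poisson weights 1/max(count, 1); the number of
#' components (up to `max_components`) is selected by AIC with a
#' parsimony margin of `delta_aic`. Amplitude fractions B_i = c_i /
#' sum(c) and lifetimes are reported sorted by descending lifetime.
#' Fitting starts `tail_offset` ns after the histogram peak (no
#' instrument response deconvolution is attempted).
#'
#' @param decay data.frame with `bin_ns` and `counts`.
#' @param max_components largest number of exponentials tried.
#' @param n_components fix the component count instead of selecting.
#' @param tail_offset ns after the peak at which the fit window starts.
#' @param delta_aic parsimony margin for model selection.
#' @param poisson use iteratively reweighted (model-based) weights, an
#'   approximation to Poisson maximum likelihood; the default keeps the
#'   plain observed-count weighting.
#' @return An object of class `lifetime_fit`: `lifetimes` (ns,
#'   descending), `amplitudes` (fractions summing to 1), `coefficients`,
#'   `n_total`, `chi2`, `chi2_red`, `aic`, `collapsed`, plus the fit
#'   window (`bin_ns`, `counts`, `fitted`).
#' @export
fit_lifetimes <- function(decay, max_components = 3, n_components = NULL,
                          tail_offset = 0.5, delta_aic = 2, poisson = FALSE) {
  stopifnot(all(c("bin_ns", "counts") %in% names(decay)))
  if (sum(decay$counts > 0) < 100)
    stop("need at least 100 nonzero bins for a lifetime fit")
  peak_t <- decay$bin_ns[which.max(decay$counts)]
  sel <- decay$bin_ns >= peak_t + tail_offset
  x <- decay$bin_ns[sel] - (peak_t + tail_offset)
  y <- decay$counts[sel]
  w <- 1 / pmax(y, 1)
  tau0 <- sum(x * y) / sum(y)     # crude mean decay time
  tau0 <- max(tau0, min(diff(decay$bin_ns)))

  one_fit <- function(k) {
    spread <- if (k == 1) 1 else exp(seq(-1.2, 1.2, length.out = k))
    f <- tryCatch(
      fit_exp_sum(x, y, w, k, tau_starts = tau0 * spread,
                  c_starts = rep(max(y) / k, k), poisson = poisson),
      error = function(e) NULL)
    if (is.null(f)) return(NULL)
    f$aic <- aic_wls(f$chi2, 2 * k, length(y))
    f$k <- k
    f
  }
  ks <- if (is.null(n_components)) seq_len(max_components) else n_components
  fits <- Filter(Negate(is.null), lapply(ks, one_fit))
  if (!length(fits)) stop("lifetime fit did not converge for any component count")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  f <- fits[[pick_by_aic(aics, delta_aic)]]

  ord <- order(f$tau, decreasing = TRUE)
  tau <- f$tau[ord]; cc <- f$coef[ord]
  collapsed <- f$k > 1 && any(tau[-f$k] / tau[-1] < 1.05)
  yhat <- rowSums(sapply(seq_len(f$k), function(i) cc[i] * exp(-x / tau[i])))
  structure(list(
    lifetimes = tau,
    amplitudes = cc / sum(cc),
    coefficients = cc,
    n_components = f$k,
    n_total = sum(decay$counts),
    chi2 = f$chi2,
    chi2_red = f$chi2 / (length(y) - 2 * f$k),
    aic = f$aic,
    collapsed = collapsed,
    converged = f$converged,
    window = data.frame(bin_ns = x, counts = y, fitted = yhat),
    offset_ns = peak_t + tail_offset),
    class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential lifetime fit: %d component(s)\n",
              x$n_components))
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  tau_%d = %.3f ns  B_%d = %.3f\n",
                i, x$lifetimes[i], i, x$amplitudes[i]))
  cat(sprintf("  chi2_red = %.2f  AIC = %.1f\n", x$chi2_red, x$aic))
  invisible(x)
}

#' Fit a multi-exponential anisotropy decay
#'
#' Fits r(t) = r0 * sum_i A_i exp(-t / rho_i), with sum(A_i) = 1
#' enforced by construction. `r0` is either free within (0, `r0_max`\]
#' or fixed.
#'
#' @param rc anisotropy curve from [anisotropy_curve()] (`bin_ns`, `r`,
#'   `sigma_r`).
#' @param n_components number of rotational components.
#' @param r0 fixed fundamental anisotropy, or `NULL` to fit it.
#' @param r0_max upper bound for a free `r0` (theoretical limit 0.4).
#' @return An object of class `aniso_fit`: `r0`, `rhos` (ns, descending),
#'   `fractions` (sum to 1), `chi2`, `chi2_red`, `aic`, fitted curve.
#' @export
fit_anisotropy <- function(rc, n_components = 2, r0 = NULL, r0_max = 0.4) {
  stopifnot(all(c("bin_ns", "r", "sigma_r") %in% names(rc)))
  if (nrow(rc) < 50) stop("need at least 50 valid bins for an anisotropy fit")
  x <- rc$bin_ns
  y <- rc$r
  w <- 1 / rc$sigma_r^2
  k <- n_components
  r0_fixed <- !is.null(r0)

  unpack <- function(par) {
    i <- 0
    r0v <- if (r0_fixed) r0 else {
      i <- 1
      r0_max * stats::plogis(par[1])
    }
    rho <- exp(par[i + seq_len(k)])
    av <- if (k == 1) 1 else {
      z <- c(par[i + k + seq_len(k - 1)], 0)
      exp(z) / sum(exp(z))
    }
    list(r0 = r0v, rho = rho, a = av)
  }
  resid_fun <- function(par) {
    p <- unpack(par)
    yhat <- p$r0 * rowSums(sapply(seq_len(k), function(i)
      p$a[i] * exp(-x / p$rho[i])))
    sqrt(w) * (y - yhat)
  }
  span <- max(x) - min(x)
  rho0 <- if (k == 1) span / 3 else exp(seq(log(max(min(x), 0.1)),
                                            log(span), length.out = k))
  par0 <- c(if (!r0_fixed) stats::qlogis(min(max(y[1] / r0_max, 0.05), 0.95)),
            log(rho0), if (k > 1) rep(0, k - 1))
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- unpack(fit$par)
  ord <- order(p$rho, decreasing = TRUE)
  rho <- p$rho[ord]; av <- p$a[ord]
  chi2 <- sum(fit$fvec^2)
  n_par <- length(par0)
  longest <- rho[1]
  if (span < longest / 5)
    warning("fit window spans less than rho_slow/5; slow component poorly constrained")
  yhat <- p$r0 * rowSums(sapply(seq_len(k), function(i)
    av[i] * exp(-x / rho[i])))
  structure(list(r0 = p$r0, rhos = rho, fractions = av, n_components = k,
                 r0_fixed = r0_fixed, chi2 = chi2,
                 chi2_red = chi2 / (length(y) - n_par),
                 aic = aic_wls(chi2, n_par, length(y)),
                 converged = fit$info %in% 1:4,
                 curve = data.frame(bin_ns = x, r = y, fitted = yhat)),
            class = "aniso_fit")
}

#' @export
print.aniso_fit <- function(x, ...) {
  cat(sprintf("Anisotropy decay fit: %d component(s), r0 = %.3f%s\n",
              x$n_components, x$r0, if (x$r0_fixed) " (fixed)" else ""))
  for (i in seq_along(x$rhos))
    cat(sprintf("  rho_%d = %.2f ns  A_%d = %.3f\n",
                i, x$rhos[i], i, x$fractions[i]))
  invisible(x)
}

#' Parametric bootstrap standard errors for decay fits
#'
#' Generates `n_reps` synthetic datasets by adding Poisson noise to the
#' idealized (fitted) decay expectation, refits each, and returns the
#' standard deviation of every parameter across replicates.
#'
#' @param fit a `lifetime_fit` or `aniso_fit`.
#' @param n_reps replicate count (100 by default).
#' @param seed master seed.
#' @param ... method-specific arguments; for `aniso_fit` supply `pd`
#'   (the polarized decay the curve came from) and optionally `g_factor`
#'   and `floor_counts`.
#' @return list with `se` (named vector of parameter SEs), `n_used`,
#'   `n_dropped`.
#' @export
parametric_bootstrap <- function(fit, n_reps = 100, seed = 1L, ...) {
  UseMethod("parametric_bootstrap")
}

#' @export
parametric_bootstrap.lifetime_fit <- function(fit, n_reps = 100, seed = 1L, ...) {
  mu <- fit$window$fitted
  if (sum(mu > 0) < 2) stop("degenerate expectation; bootstrap refused")
  x <- fit$window$bin_ns
  k <- fit$n_components
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    y <- with_seed(derive_seed(seed, r), stats::rpois(length(mu), mu))
    f <- tryCatch(
      fit_exp_sum(x, y, 1 / pmax(y, 1), k,
                  tau_starts = fit$lifetimes, c_starts = fit$coefficients),
      error = function(e) NULL)
    if (!is.null(f)) {
      ord <- order(f$tau, decreasing = TRUE)
      res[[r]] <- c(f$tau[ord], f$coef[ord] / sum(f$coef))
    }
  }
  keep <- !vapply(res, is.null, logical(1))
  if (sum(!keep) > 0.1 * n_reps)
    warning("more than 10% of bootstrap replicates failed to converge")
  mat <- do.call(rbind, res[keep])
  sds <- apply(mat, 2, stats::sd)
  names(sds) <- c(paste0("tau_", seq_len(k)), paste0("B_", seq_len(k)))
  list(se = sds, n_used = sum(keep), n_dropped = sum(!keep))
}

#' @export
parametric_bootstrap.aniso_fit <- function(fit, n_reps = 100, seed = 1L,
                                           pd = NULL, g_factor = 1,
                                           floor_counts = 100, ...) {
  if (is.null(pd))
    stop("supply pd = the polarized decay data.frame used for the fit")
  iso <- isotropic_decay(pd, g_factor)
  lt <- fit_lifetimes(iso, max_components = 3)
  t_all <- pd$bin_ns
  f_ideal <- rowSums(sapply(seq_along(lt$lifetimes), function(i)
    lt$coefficients[i] * exp(-pmax(t_all - lt$offset_ns, 0) / lt$lifetimes[i])))
  f_ideal[t_all < lt$offset_ns] <- NA
  r_ideal <- fit$r0 * rowSums(sapply(seq_len(fit$n_components), function(i)
    fit$fractions[i] * exp(-t_all / fit$rhos[i])))
  mu_par <- f_ideal * (1 + 2 * r_ideal) / 3
  mu_perp <- f_ideal * (1 - r_ideal) / (3 * g_factor)
  ok <- is.finite(mu_par) & is.finite(mu_perp)
  k <- fit$n_components
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- with_seed(derive_seed(seed, r), data.frame(
      bin_ns = t_all[ok],
      counts_par = stats::rpois(sum(ok), mu_par[ok]),
      counts_perp = stats::rpois(sum(ok), mu_perp[ok])))
    f <- tryCatch({
      rc <- anisotropy_curve(sim, g_factor, floor_counts)
      fit_anisotropy(rc, n_components = k,
                     r0 = if (fit$r0_fixed) fit$r0 else NULL)
    }, error = function(e) NULL)
    if (!is.null(f)) res[[r]] <- c(f$r0, f$rhos, f$fractions)
  }
  keep <- !vapply(res, is.null, logical(1))
  if (sum(!keep) > 0.1 * n_reps)
    warning("more than 10% of bootstrap replicates failed to converge")
  mat <- do.call(rbind, res[keep])
  sds <- apply(mat, 2, stats::sd)
  names(sds) <- c("r0", paste0("rho_", seq_len(k)), paste0("A_", seq_len(k)))
  list(se = sds, n_used = sum(keep), n_dropped = sum(!keep))
}
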