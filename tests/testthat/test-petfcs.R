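test_that("the FCS model obeys its closed-form limits", {
  p <- fcs_params(1, 1000, 5, 0.2, 5, c(0.3), c(1))
  expect_equal(fcs_model(p, 1e-9), 1.5, tolerance = 1e-6)
  expect_lt(fcs_model(p, 1e9), 1e-3)
  # hand evaluation at tau = tau_d with no blinking
  p2 <- fcs_params(1, 1000, 5)
  expect_equal(fcs_model(p2, 1000), 0.5 * (1 + 1 / 25)^-0.5,
               tolerance = 1e-12)
  # monotone decreasing for nonnegative amplitudes
  lg <- log_lag_grid(1e-3, 1e6, 200)
  expect_true(all(diff(fcs_model(p, lg)) < 0))
})

test_that("a noiseless curve is recovered to high accuracy", {
  truth <- fcs_params(2, 800, 4, 0.15, 5, c(0.25), c(2))
  lg <- log_lag_grid(1e-3, 1e6, 150)
  cv <- simulate_fcs_curve(truth, lg, noise_sd = 0)
  fit <- fcs_fit(cv, n_quench = 1, n_starts = 3)
  expect_equal(fit$params$n_mean, 2, tolerance = 1e-5)
  expect_equal(fit$params$tau_d, 800, tolerance = 1e-4)
  expect_equal(fit$params$quench_taus, 2, tolerance = 1e-4)
  expect_equal(fit$params$t_trip, 5, tolerance = 1e-4)
})

test_that("quench-term count is selected by AIC", {
  # free-dye-like: diffusion + one triplet only
  truth <- fcs_params(1, 200, 5, 0.2, 3)
  cv <- simulate_fcs_curve(truth, log_lag_grid(1e-2, 1e5, 120),
                           noise_sd = 0.002, seed = 41L)
  sel <- fcs_select_quench_terms(cv, max_quench = 2, n_starts = 2)
  expect_equal(sel$n_quench, 0L)
})

test_that("receptor-like three-component curves are recovered", {
  truth <- fcs_condition_truths()$apo
  amp_errs <- vapply(c(42L, 7L, 99L), function(seed) {
    cv <- simulate_fcs_curve(truth, log_lag_grid(), noise_sd = 0.002,
                             seed = seed)
    p <- fcs_fit(cv, n_quench = 3, seed = 1L)$params
    expect_lt(abs(min(p$quench_taus) - 0.34) / 0.34, 0.10)
    expect_lt(max(abs(p$quench_taus - c(0.34, 52, 264)) / c(0.34, 52, 264)),
              0.15)
    # amplitude identity: G(0+) <N> - 1 = K_t + sum K_i
    g0 <- fcs_model(p, 1e-9)
    expect_equal(g0 * p$n_mean - 1, p$k_trip + sum(p$quench_amps),
                 tolerance = 1e-6)
    max(abs(p$quench_amps - c(0.38, 0.24, 0.31)))
  }, numeric(1))
  expect_lt(mean(amp_errs), 0.05)
})

test_that("global fits share the triplet lifetime across conditions", {
  truths <- fcs_condition_truths()
  curves <- lapply(seq_along(truths), function(i)
    simulate_fcs_curve(truths[[i]], log_lag_grid(), noise_sd = 0.002,
                       seed = 100 + i))
  gf <- fcs_fit_global(curves, n_quench = 3)
  expect_lt(abs(gf$shared$t_trip - 5) / 5, 0.10)
  # per-curve fast lifetimes track their own ground truths
  t_fast_hat <- vapply(gf$fits, function(p) min(p$quench_taus), numeric(1))
  t_fast_true <- vapply(truths, function(p) min(p$quench_taus), numeric(1))
  expect_lt(max(abs(t_fast_hat - t_fast_true) / t_fast_true), 0.15)
  # sharing a correctly specified parameter costs essentially nothing
  chi2_singles <- sum(vapply(gf$singles, function(f) f$chi2, numeric(1)))
  expect_lt(gf$chi2, chi2_singles * 1.02)
})

test_that("two identical curves give identical per-curve parameters", {
  truth <- fcs_params(1, 500, 5, 0.2, 5, c(0.3), c(1))
  cv <- simulate_fcs_curve(truth, log_lag_grid(1e-2, 1e5, 120),
                           noise_sd = 0.001, seed = 43L)
  gf <- fcs_fit_global(list(cv, cv), n_quench = 1)
  expect_equal(gf$fits[[1]]$tau_d, gf$fits[[2]]$tau_d, tolerance = 1e-6)
  expect_equal(gf$fits[[1]]$quench_taus, gf$fits[[2]]$quench_taus,
               tolerance = 1e-6)
})

test_that("diffusion subtraction isolates the blinking decays", {
  truth <- fcs_params(1, 1000, 5, 0.19, 5, c(0.38, 0.24, 0.31),
                      c(0.34, 52, 264))
  lg <- log_lag_grid(1e-2, 1e6, 150)
  cv <- simulate_fcs_curve(truth, lg, noise_sd = 0)
  sub <- subtract_diffusion(cv, truth)
  # reconstruction identity
  g_diff <- fcs_model(truth, lg, blinking = FALSE)
  expect_equal(sub$fitted_sub + g_diff, fcs_model(truth, lg),
               tolerance = 1e-12)
  # residual at the shortest lag: (1/N) sum of blinking terms at that lag
  blink1 <- 0.19 * exp(-lg[1] / 5) + 0.38 * exp(-lg[1] / 0.34) +
    0.24 * exp(-lg[1] / 52) + 0.31 * exp(-lg[1] / 264)
  expect_equal(sub$G_sub[1], g_diff[1] * blink1, tolerance = 1e-10)
  # a curve with no blinking terms subtracts to ~0
  p0 <- fcs_params(1, 1000, 5)
  cv0 <- simulate_fcs_curve(p0, lg, noise_sd = 0)
  expect_lt(max(abs(subtract_diffusion(cv0, p0)$G_sub)), 1e-12)
})

test_that("Stokes-Einstein conversion behaves as expected", {
  expect_equal(hydrodynamic_radius(2000) / hydrodynamic_radius(1000), 2,
               tolerance = 1e-12)
  # round trip: pick tau_d so R_H = 0.5 nm, recover it
  kb <- 1.380649e-23
  d_coef <- kb * 298 / (6 * pi * 1e-3 * 0.5e-9)
  tau_d_us <- (250e-9)^2 / (4 * d_coef) * 1e6
  expect_equal(hydrodynamic_radius(tau_d_us), 0.5, tolerance = 1e-9)
  # receptor/free-dye diffusion-time ratio equals the R_H ratio
  expect_equal(hydrodynamic_radius(12 * tau_d_us) /
                 hydrodynamic_radius(tau_d_us), 12, tolerance = 1e-9)
})

test_that("quenching lifetimes convert to the printed collision rates", {
  expect_equal(quench_rate(40, "us", "per_ms"), 25)
  expect_equal(round(quench_rate(270, "ns", "per_us"), 1), 3.7)
  expect_equal(quench_rate(1, "ms", "per_ms"), 1)
})

test_that("the multi-tau correlator matches a brute-force correlator", {
  ts <- withr::with_seed(44, sort(runif(5000, 0, 1e8)))
  cv <- multitau_correlate(ts, bin_width_ns = 1e4, n_blocks = 4)
  n_bins <- floor((ts[length(ts)] - ts[1]) / 1e4) + 1
  counts <- tabulate(floor((ts - ts[1]) / 1e4) + 1L, nbins = n_bins)
  bf <- brute_force_correlation(counts, 1:16)
  expect_lt(max(abs(cv$G[1:16] - bf)), 1e-10)
  expect_error(multitau_correlate(ts[1:500]), "1000 photons")
})

test_that("an uncorrelated stream correlates to zero", {
  ts <- withr::with_seed(45, sort(runif(30000, 0, 5e9)))
  cv <- multitau_correlate(ts, bin_width_ns = 1e4)
  ok <- is.finite(cv$sem)
  expect_gt(mean(abs(cv$G[ok]) < 3 * cv$sem[ok]), 0.93)
  expect_lt(max(abs(cv$G)), 0.1)
})

test_that("a periodic comb stream shows peaks at multiples of the period", {
  # photons at exact multiples of 5 us; check the base-resolution lags
  # (coarser levels alias the comb and are verified against brute force)
  ts <- seq(0, 2e7, by = 5e3)
  cv <- multitau_correlate(ts, bin_width_ns = 1e3, n_blocks = 4)
  lev0 <- cv[seq_len(16), ]
  on_peak <- lev0$G[lev0$lag_us %in% c(5, 10, 15)]
  off_peak <- lev0$G[!(lev0$lag_us %in% c(5, 10, 15))]
  expect_true(all(on_peak > 3))
  expect_true(all(abs(off_peak + 1) < 0.01))  # anticorrelated between peaks
})

test_that("telegraph blinking yields the analytic correlation lifetime", {
  ts <- blinking_photon_stream(k_on = 0.02, k_off = 0.02, bright_rate = 20,
                               total_ns = 5e8, seed = 46)
  cv <- multitau_correlate(ts, bin_width_ns = 1000, max_lag_us = 2000,
                           n_blocks = 4)
  sel <- cv$lag_us < 300
  fit <- minpack.lm::nls.lm(par = c(log(1), log(10)), fn = function(p)
    cv$G[sel] - exp(p[1]) * exp(-cv$lag_us[sel] / exp(p[2])))
  t_hat <- exp(fit$par[2])
  t_true <- 1 / (0.02 + 0.02)   # 25 us
  expect_lt(abs(t_hat - t_true) / t_true, 0.15)
})
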