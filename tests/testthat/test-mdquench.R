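test_that("running average follows the shrunken-edge rule", {
  s <- data.frame(t_ns = 0:4, d_nm = 0:4)
  expect_equal(running_average(s, 3)$d_nm, c(0.5, 1, 2, 3, 3.5))
  # constant series unchanged; window = dt is the identity
  cs <- data.frame(t_ns = 0:9, d_nm = rep(2, 10))
  expect_equal(running_average(cs, 5)$d_nm, rep(2, 10))
  expect_equal(running_average(s, 1)$d_nm, s$d_nm)
  expect_warning(out <- running_average(s, 0.1), "window")
  expect_equal(out$d_nm, s$d_nm)
})

test_that("state assignment counts crossings of the cutoff", {
  flat <- data.frame(t_ns = 0:99, d_nm = rep(2.5, 100))
  qt <- assign_states(flat, 1.8)
  expect_equal(qt$n_transitions, 0)
  expect_equal(qt$quenched_fraction, 0)
  # square wave crossing the cutoff 10 times
  sq <- data.frame(t_ns = 0:109, d_nm = rep(rep(c(1.0, 2.0), 5), each = 11))
  expect_equal(assign_states(sq, 1.5)$n_transitions, 9)
  sq2 <- data.frame(t_ns = 0:10, d_nm = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1))
  expect_equal(assign_states(sq2, 1.5)$n_transitions, 10)
})

test_that("telegraph transition frequency matches the Markov oracle", {
  tc <- telegraph_config(rate_to_quenched = 0.5, rate_to_unquenched = 0.5,
                         jitter_sd = 0, dt = 1, duration = 400, seed = 51L)
  tr <- simulate_distance_trajectory(tc)
  f_true <- telegraph_switch_frequency(0.5, 0.5)
  qt <- assign_states(tr, (1.5 + 2.1) / 2)
  expect_lt(abs(qt$freq_per_us - f_true) / f_true, 0.15)
  # with jitter and 20-ns smoothing the count still tracks the truth
  tc2 <- telegraph_config(jitter_sd = 0.1, duration = 500, seed = 52L)
  tr2 <- simulate_distance_trajectory(tc2)
  sm <- running_average(tr2, 20)
  f_sm <- assign_states(sm, 1.8)$freq_per_us
  expect_lt(abs(f_sm - f_true) / f_true, 0.20)
})

test_that("smoothing never increases the transition count", {
  for (seed in 1:8) {
    tc <- telegraph_config(jitter_sd = 0.08, duration = 100, seed = seed)
    tr <- simulate_distance_trajectory(tc)
    for (cf in c(1.6, 1.8, 2.0)) {
      raw <- assign_states(tr, cf)$n_transitions
      sm <- assign_states(running_average(tr, 20), cf)$n_transitions
      expect_lte(sm, raw)
    }
  }
})

test_that("transition counts are shift-invariant", {
  tc <- telegraph_config(jitter_sd = 0.05, duration = 100, seed = 53L)
  tr <- simulate_distance_trajectory(tc)
  shifted <- tr
  shifted$d_nm <- shifted$d_nm + 0.7
  expect_equal(assign_states(tr, 1.8)$n_transitions,
               assign_states(shifted, 2.5)$n_transitions)
})

test_that("quenched fraction is monotone non-decreasing in the cutoff", {
  tc <- telegraph_config(jitter_sd = 0.1, duration = 100, seed = 54L)
  tr <- simulate_distance_trajectory(tc)
  fr <- vapply(seq(1, 2.6, by = 0.1),
               function(cf) assign_states(tr, cf)$quenched_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("the cutoff scan peaks between the telegraph levels", {
  # jitter-free case: the frequency is flat and maximal strictly between
  # the levels and exactly zero outside them
  tcs <- lapply(1:3, function(i)
    simulate_distance_trajectory(
      telegraph_config(level_quenched = 1.5, level_unquenched = 2.1,
                       jitter_sd = 0, duration = 200, seed = 60 + i)))
  sc <- scan_cutoffs(tcs, cutoffs = seq(1, 2.6, by = 0.05), window = 20)
  inside <- sc$cutoff_nm > 1.55 & sc$cutoff_nm < 2.05
  outside <- sc$cutoff_nm < 1.45 | sc$cutoff_nm > 2.15
  expect_equal(max(sc$freq_per_us_mean[outside]), 0)
  expect_gt(min(sc$freq_per_us_mean[inside]), 0)
  # the maximum lies strictly between the two levels
  cut_at_max <- sc$cutoff_nm[which.max(sc$freq_per_us_mean)]
  expect_gt(cut_at_max, 1.5)
  expect_lt(cut_at_max, 2.1)
  expect_true(all(sc$freq_per_us_sd >= 0))
  # with jitter, a cutoff placed on a level toggles on noise; interior
  # cutoffs still report the true switching frequency
  trj <- simulate_distance_trajectory(
    telegraph_config(jitter_sd = 0.05, duration = 200, seed = 64L))
  scj <- scan_cutoffs(list(trj), cutoffs = c(1.2, 1.8, 2.4), window = 20)
  expect_equal(scj$freq_per_us_mean[c(1, 3)], c(0, 0))
  expect_lt(abs(scj$freq_per_us_mean[2] - telegraph_switch_frequency(0.5, 0.5)) /
              telegraph_switch_frequency(0.5, 0.5), 0.2)
})

test_that("dye-cloud geometry reduces to hand-computable cases", {
  # single frame: centroid distance is the mean extension
  fr <- matrix(c(0.81, 0, 0), ncol = 3)
  st <- dye_extension(c(0, 0, 0), list(fr))
  expect_equal(st$l_mean, 0.81)
  # anchor at the centroid
  fr2 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(dye_extension(c(0, 0, 0), list(fr2))$l_mean, 0)
  # two atoms at unit axes: centroid at (0.5, 0.5, 0)
  fr3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(dye_extension(c(0, 0, 0), list(fr3))$l_mean, sqrt(0.5),
               tolerance = 1e-12)
  expect_error(dye_extension(c(0, 0, 0), list(matrix(numeric(0), ncol = 3))),
               "empty")
})

test_that("dye-cloud autocorrelation lifetime is recovered from AR(1) samples", {
  tau <- 4   # ns, with dt = 1 ns
  a <- exp(-1 / tau)
  r <- withr::with_seed(55, {
    as.numeric(stats::filter(rnorm(20000, 0, sqrt(1 - a^2)), a,
                             method = "recursive"))
  })
  frames <- lapply(2 + 0.2 * r, function(d) matrix(c(d, 0, 0), ncol = 3))
  st <- dye_extension(c(0, 0, 0), frames, dt_ns = 1)
  expect_lt(abs(st$acor_lifetime_ns - tau) / tau, 0.3)
})

test_that("the quenching cutoff adds the dye extension to the quench range", {
  expect_equal(quench_cutoff(0.81), 1.81)
  expect_equal(quench_cutoff(0), 1.0)
  expect_equal(quench_cutoff(0.81, 0.9), 1.71)
})

test_that("ionic-lock occupancy and segments follow the threshold rule", {
  all_in <- ionic_lock_fraction(rep(3, 50), t_ns = 0:49)
  expect_equal(all_in$fraction_intact, 1)
  expect_equal(nrow(all_in$segments), 1)
  expect_equal(ionic_lock_fraction(rep(8, 50))$fraction_intact, 0)
  alt <- ionic_lock_fraction(rep(c(3, 8), 25))
  expect_equal(alt$fraction_intact, 0.5)
  expect_equal(nrow(alt$segments), 50)
  # 2-D histogram normalizes to 1
  h <- ionic_lock_fraction(runif(500, 2, 10), companion = runif(500),
                           nbins = 10)$hist2d
  expect_equal(sum(h), 1, tolerance = 1e-12)
})

test_that("distance histograms are normalized and split at the cutoff", {
  tc <- telegraph_config(rate_to_quenched = 0.3, rate_to_unquenched = 0.7,
                         jitter_sd = 0.02, duration = 400, seed = 56L)
  tr <- simulate_distance_trajectory(tc)
  h <- distance_histogram(tr, breaks = 60, d_q = 1.8)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  # occupancy of the quenched level: k_q / (k_q + k_u) = 0.3
  below <- sum(h$prob[h$mid_nm < 1.8])
  expect_lt(abs(below - 0.3), 0.02)
  # near-constant trace occupies a single bin
  flat <- data.frame(t_ns = 1:200, d_nm = rep(1.5, 200))
  hf <- distance_histogram(flat, breaks = c(0, 1, 1.4999, 1.5001, 2, 3))
  expect_equal(max(hf$prob), 1)
})
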