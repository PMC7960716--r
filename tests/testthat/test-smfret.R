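test_that("burst search finds a planted cluster and nothing in noise", {
  expect_equal(nrow(detect_bursts(data.frame(timestamp_ns = numeric(0),
                                             excitation = character(0),
                                             emission = character(0)))),
               0)
  # one 100-photon cluster inside 1 photon/ms background
  pl <- planted_photon_stream(n_bursts = 1, burst_photons = 100,
                              burst_span_ns = 1e6, gap_ns = 5e7,
                              bg_rate_per_ms = 1, seed = 11)
  params <- burst_search_params(window_photons = 10, max_window_span = 500,
                                min_burst_photons = 30)
  bs <- detect_bursts(pl$stream, params)
  expect_equal(nrow(bs), 1)
  in_window <- pl$stream$timestamp_ns >= pl$windows$start_ns[1] &
    pl$stream$timestamp_ns <= pl$windows$end_ns[1]
  # the burst contains at least 90 of the 100 planted photons
  covered <- sum(which(in_window) >= bs$first_idx & which(in_window) <= bs$last_idx)
  expect_gte(covered, 90)
})

test_that("burst search recall on 50 planted bursts is high with no false positives", {
  pl <- planted_photon_stream(n_bursts = 50, seed = 12)
  bs <- detect_bursts(pl$stream,
                      burst_search_params(10, 500, 30, merge_gap = 100))
  # match each planted window to a detected burst by overlap
  hit <- vapply(seq_len(50), function(i) {
    any(bs$start_ms * 1e6 < pl$windows$end_ns[i] &
          (bs$start_ms + bs$duration_ms) * 1e6 > pl$windows$start_ns[i])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # no burst should start inside a burst-free stretch (2 ms after each window)
  gaps_ok <- !vapply(seq_len(nrow(bs)), function(j) {
    s <- bs$start_ms[j] * 1e6
    any(s > pl$windows$end_ns + 2e6 & s < pl$windows$start_ns + 1.8e7)
  }, logical(1))
  expect_true(all(gaps_ok))
  expect_error(detect_bursts(data.frame(timestamp_ns = c(2, 1),
                                        excitation = "D", emission = "D")),
               "sorted")
})

test_that("corrections follow the stated arithmetic", {
  mk <- function(i_d, i_a, i_aa, dur = 1) {
    data.frame(n_DexDem = i_d, n_DexAem = i_a, n_AexAem = i_aa,
               duration_ms = dur)
  }
  # zero background / leakage: identity
  b <- apply_corrections(mk(100, 60, 50), correction_set(gamma = 1))
  expect_equal(b$I_D, 100)
  expect_equal(b$I_A, 60)
  # leakage removes a fraction of donor counts from the acceptor channel
  b <- apply_corrections(mk(100, 60, 50),
                         correction_set(gamma = 1, leakage = 0.1))
  expect_equal(b$I_A, 50)
  # background subtraction: 2 counts/ms over 2 ms
  b <- apply_corrections(mk(50, 60, 50, dur = 2),
                         correction_set(gamma = 1,
                                        background_rates = c(DexDem = 2,
                                                             DexAem = 0,
                                                             AexAem = 0)))
  expect_equal(b$I_D, 46)
  # gamma consistency check on the optional efficiency fields
  expect_error(correction_set(gamma = 0.5, eta_Dem = 1, eta_Aem = 1,
                              Phi_D = 1, Phi_A = 1),
               "inconsistent")
})

test_that("efficiency and stoichiometry follow their definitions", {
  expect_equal(fret_efficiency(50, 50, 1), 0.5)
  expect_equal(fret_efficiency(0, 70, 0.56), 0)
  expect_equal(fret_efficiency(30, 70, 0.56), 30 / 69.2)
  expect_true(is.na(fret_efficiency(0, 0, 1)))
  expect_equal(stoichiometry(30, 30), 0.5)
  expect_equal(stoichiometry(50, 0), 1)
  expect_equal(stoichiometry(30, 70), 0.3)
  # bounded in [0, 1] for any nonnegative inputs
  ia <- runif(100, 0, 50); id <- runif(100, 0, 50)
  e <- fret_efficiency(ia, id, 0.56)
  s <- stoichiometry(ia, id)
  expect_true(all(e >= 0 & e <= 1, na.rm = TRUE))
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
})

test_that("stoichiometry filter keeps dual-labelled bursts", {
  b <- data.frame(I_DD = c(1, 5, 9), I_AA = c(9, 5, 1))
  kept <- filter_stoichiometry(b)
  expect_equal(kept$S, 0.5)
  # planted 30% donor-only contamination is rejected
  model <- fret_state_model(0.4, 0.05, 1)
  cfg <- burst_sim_config(n_bursts = 3000, frac_donor_only = 0.3, seed = 13L)
  bb <- simulate_fret_bursts(model, cfg)
  corr <- correction_set(gamma = cfg$gamma_true,
                         background_rates = cfg$background_rates,
                         leakage = cfg$leakage)
  bb <- apply_corrections(bb, corr)
  # the usual minimum-size filter removes near-empty bursts whose
  # stoichiometry is dominated by background
  bb <- bb[bb$I_D + bb$I_A + bb$I_AA >= 30, ]
  n_before <- nrow(bb)
  bb <- filter_stoichiometry(bb)
  retained <- nrow(bb) / n_before
  expect_lt(abs(retained - 0.7), 0.03)
  expect_true(all(bb$true_state == 1))
})

test_that("shot-noise width follows the binomial variance", {
  expect_equal(shot_noise_fwhm(0.5, 100), 2 * sqrt(2 * log(2)) * 0.05 * 100,
               tolerance = 1e-12)
  expect_equal(round(shot_noise_fwhm(0.5, 100), 2), 11.77)
  expect_equal(shot_noise_fwhm(0, 50), 0)
  expect_equal(shot_noise_fwhm(0.3, 50, percent = FALSE) / (2 * sqrt(2 * log(2))),
               sqrt(0.21 / 50), tolerance = 1e-12)
  expect_error(broadening_benchmark(0.5, 100, 5), "narrower")
})

test_that("Foerster inversion reproduces the printed distances", {
  expect_equal(forster_distance(0.5, 50.1), 50.1)
  r_low <- forster_distance(0.24, 50.1)
  r_high <- forster_distance(0.52, 50.1)
  expect_lt(abs(r_low - 60.6) / 60.6, 0.005)
  expect_lt(abs(r_high - 49.3) / 49.3, 0.005)
  expect_error(forster_distance(0), "strictly inside")
  expect_error(forster_distance(1), "strictly inside")
})

test_that("observed histogram width is never below the shot-noise floor", {
  model <- fret_state_model(0.4, 0.05, 1)
  cfg <- burst_sim_config(n_bursts = 3000, seed = 14L)
  b <- simulate_fret_bursts(model, cfg)
  corr <- correction_set(gamma = cfg$gamma_true,
                         background_rates = cfg$background_rates,
                         leakage = cfg$leakage)
  b <- apply_corrections(b, corr)
  b <- b[b$I_D + b$I_A >= 30, ]
  e <- fret_efficiency(b$I_A, b$I_D, cfg$gamma_true)
  obs_fwhm <- 100 * 2 * sqrt(2 * log(2)) * sd(e)
  sn <- shot_noise_fwhm(mean(e), mean(b$I_D + b$I_A))
  expect_gte(obs_fwhm, sn)
})
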