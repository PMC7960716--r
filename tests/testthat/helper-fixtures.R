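# Shared fixtures built in code at test time.

# Table-1-style apo two-state FRET model used for recovery tests; the
# per-component widths keep the low-FRET tail clear of the E = 0
# boundary (see the methods vignette).
apo_burst_model <- function() {
  fret_state_model(centers = c(0.24, 0.52), widths = c(0.08, 0.08),
                   weights = c(0.69, 0.31))
}

# Standard burst analysis pipeline: corrections -> size filter ->
# stoichiometry filter -> corrected efficiencies.
burst_pipeline_e <- function(bursts, cfg, min_photons = 50) {
  corr <- correction_set(gamma = cfg$gamma_true,
                         background_rates = cfg$background_rates,
                         leakage = cfg$leakage)
  b <- apply_corrections(bursts, corr)
  b <- b[b$I_D + b$I_A >= min_photons, ]
  b <- filter_stoichiometry(b)
  fret_efficiency(b$I_A, b$I_D, cfg$gamma_true)
}

# Receptor-like FCS ground truths (triplet + three quenching terms,
# amplitudes/lifetimes in us) for five ligand conditions.
fcs_condition_truths <- function() {
  list(
    apo      = fcs_params(1, 1000, 5, 0.19, 5, c(0.38, 0.24, 0.31), c(0.34, 52, 264)),
    inverse  = fcs_params(1, 1000, 5, 0.19, 5, c(0.29, 0.20, 0.24), c(0.27, 55, 225)),
    partial  = fcs_params(1, 1000, 5, 0.19, 5, c(0.34, 0.24, 0.26), c(0.32, 55, 247)),
    full     = fcs_params(1, 1000, 5, 0.19, 5, c(0.54, 0.22, 0.23), c(0.18, 60, 246)),
    mini_g   = fcs_params(1, 1000, 5, 0.19, 5, c(0.64, 0.13, 0.24), c(0.16, 51, 247)))
}

# Photon stream with bursts planted at known times inside uniform
# background; returns the stream plus the planted burst windows.
planted_photon_stream <- function(n_bursts = 50, burst_photons = 100,
                                  burst_span_ns = 1e6, gap_ns = 2e7,
                                  bg_rate_per_ms = 1, seed = 1) {
  withr::with_seed(seed, {
    starts <- (seq_len(n_bursts) - 1) * gap_ns + 5e6
    burst_ts <- unlist(lapply(starts, function(s)
      sort(s + runif(burst_photons, 0, burst_span_ns))))
    total_ns <- max(starts) + gap_ns
    n_bg <- rpois(1, bg_rate_per_ms * total_ns / 1e6)
    ts <- sort(c(burst_ts, runif(n_bg, 0, total_ns)))
    n <- length(ts)
    data.frame(timestamp_ns = ts,
               excitation = sample(c("D", "A"), n, TRUE),
               emission = sample(c("D", "A"), n, TRUE)) ->
      stream
    list(stream = stream,
         windows = data.frame(start_ns = starts,
                              end_ns = starts + burst_span_ns))
  })
}

# Vectorized telegraph-blinking photon stream for correlator tests:
# photons emitted at `bright_rate` (per us) during "on" dwells of a
# symmetric two-state process with rates k_on/k_off per us.
blinking_photon_stream <- function(k_on = 0.02, k_off = 0.02,
                                   bright_rate = 20, total_ns = 5e8,
                                   seed = 1) {
  withr::with_seed(seed, {
    n_dw <- ceiling(total_ns * (k_on + k_off) / 1e3) + 100
    dw_on <- rexp(n_dw, k_off / 1e3)
    dw_off <- rexp(n_dw, k_on / 1e3)
    on_starts <- cumsum(dw_on + dw_off) - dw_on
    keep <- on_starts < total_ns
    n_ph <- rpois(sum(keep), dw_on[keep] * bright_rate / 1e3)
    sort(rep(on_starts[keep], n_ph) +
           stats::runif(sum(n_ph)) * rep(dw_on[keep], n_ph))
  })
}

# Brute-force direct correlator on a binned signal (independent oracle
# for the multi-tau implementation).
brute_force_correlation <- function(counts, lags_bins) {
  vapply(lags_bins, function(k) {
    n <- length(counts)
    head <- counts[1:(n - k)]
    tail <- counts[(1 + k):n]
    mean(head * tail) / (mean(head) * mean(tail)) - 1
  }, numeric(1))
}
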