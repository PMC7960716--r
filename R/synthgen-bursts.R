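#' Define a FRET state mixture
#'
#' A conformational ensemble is described as a mixture of Gaussian FRET
#' states: each component has a peak efficiency (`center`), an efficiency
#' standard deviation (`width`, conformational broadening beyond shot
#' noise) and an occupancy `weight`. All efficiencies are fractions in
#' \[0, 1\].
#'
#' @param centers numeric vector of peak FRET efficiencies in \[0, 1\].
#' @param widths numeric vector of per-state efficiency standard
#'   deviations (same length as `centers`).
#' @param weights numeric vector of state occupancies; must sum to 1.
#' @return An object of class `fret_state_model`.
#' @examples
#' # two-state ensemble: open/active (low FRET) and closed/inactive (high FRET)
#' fret_state_model(centers = c(0.24, 0.52), widths = c(0.11, 0.10),
#'                  weights = c(0.69, 0.31))
#' @export
fret_state_model <- function(centers, widths, weights) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(weights),
            length(centers) >= 1)
  if (any(centers < 0 | centers > 1)) stop("centers must lie in [0, 1]")
  if (any(widths < 0)) stop("widths must be nonnegative")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(centers = as.numeric(centers),
                 widths = as.numeric(widths),
                 weights = as.numeric(weights)),
            class = "fret_state_model")
}

#' Burst simulation configuration
#'
#' Parameters of the synthetic ALEX burst generator. Burst sizes (photons
#' detected during donor-excitation periods) are drawn from a negative
#' binomial with mean `mean_photons` and dispersion `size_dispersion`
#' (variance = mean + mean^2/dispersion), emulating the heavy-tailed
#' brightness of freely diffusing molecules. Burst durations are gamma
#' distributed around `mean_duration`.
#'
#' @param n_bursts number of bursts to generate.
#' @param mean_photons mean donor-excitation photons per burst (260 by
#'   default: a 2.6 ms transit at ~10 us inter-photon time).
#' @param size_dispersion negative-binomial dispersion (larger = closer
#'   to Poisson).
#' @param background_rates named numeric vector, counts per ms, for the
#'   `DexDem`, `DexAem` and `AexAem` channels.
#' @param gamma_true detection-efficiency/quantum-yield correction factor
#'   used to distort apparent efficiencies.
#' @param leakage donor-to-acceptor spectral crossover fraction.
#' @param direct_excitation fraction of `AexAem` brightness that leaks
#'   into the donor-excitation acceptor channel.
#' @param mean_duration mean burst duration, ms.
#' @param frac_donor_only,frac_acceptor_only contaminant fractions of
#'   single-labelled bursts.
#' @param seed integer seed; the generator is deterministic given it.
#' @return An object of class `burst_sim_config`.
#' @export
burst_sim_config <- function(n_bursts = 5000,
                             mean_photons = 260,
                             size_dispersion = 2,
                             background_rates = c(DexDem = 1, DexAem = 1, AexAem = 1),
                             gamma_true = 0.56,
                             leakage = 0.05,
                             direct_excitation = 0,
                             mean_duration = 2.6,
                             frac_donor_only = 0,
                             frac_acceptor_only = 0,
                             seed = 1L) {
  stopifnot(n_bursts >= 0, mean_photons > 0, size_dispersion > 0,
            mean_duration > 0)
  if (any(background_rates < 0)) stop("background rates must be nonnegative")
  frac <- c(leakage, direct_excitation, frac_donor_only, frac_acceptor_only)
  if (any(frac < 0 | frac >= 1)) stop("fractions must lie in [0, 1)")
  if (gamma_true <= 0) stop("gamma_true must be positive")
  bg <- background_rates
  if (is.null(names(bg))) names(bg) <- c("DexDem", "DexAem", "AexAem")
  structure(list(n_bursts = as.integer(n_bursts), mean_photons = mean_photons,
                 size_dispersion = size_dispersion, background_rates = bg,
                 gamma_true = gamma_true, leakage = leakage,
                 direct_excitation = direct_excitation,
                 mean_duration = mean_duration,
                 frac_donor_only = frac_donor_only,
                 frac_acceptor_only = frac_acceptor_only,
                 seed = as.integer(seed)),
            class = "burst_sim_config")
}

#' Simulate ALEX smFRET bursts from a state mixture
#'
#' Generates per-burst photon counts in the three ALEX channels. For each
#' dual-labelled burst a state is drawn from the mixture, a per-burst
#' efficiency from the state's Gaussian (truncated to \[0, 1\]), and the
#' donor-excitation photons are split binomially between donor and
#' acceptor channels at the apparent (gamma-distorted) acceptor
#' probability p = gamma*E / (1 - E + gamma*E). Spectral leakage adds
#' Poisson counts with mean `leakage * I_D` to the acceptor channel,
#' direct excitation adds `direct_excitation * I_AA`, and each channel
#' receives Poisson background at its rate times the burst duration.
#' Donor-only contaminants carry background-only `AexAem` counts;
#' acceptor-only contaminants carry background-only donor-excitation
#' counts.
#'
#' @param model a [fret_state_model()].
#' @param cfg a [burst_sim_config()].
#' @return A data.frame with columns `burst_id`, `start_ms`,
#'   `duration_ms`, `n_DexDem`, `n_DexAem`, `n_AexAem`, `true_state`
#'   (component index; 0 = donor-only, -1 = acceptor-only) and `true_E`.
#' @export
simulate_fret_bursts <- function(model, cfg) {
  stopifnot(inherits(model, "fret_state_model"),
            inherits(cfg, "burst_sim_config"))
  cols <- c("burst_id", "start_ms", "duration_ms", "n_DexDem", "n_DexAem",
            "n_AexAem", "true_state", "true_E")
  if (cfg$n_bursts == 0) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  with_seed(cfg$seed, {
    n <- cfg$n_bursts
    kind <- sample(c("da", "donly", "aonly"), n, replace = TRUE,
                   prob = c(1 - cfg$frac_donor_only - cfg$frac_acceptor_only,
                            cfg$frac_donor_only, cfg$frac_acceptor_only))
    dur <- stats::rgamma(n, shape = 4, scale = cfg$mean_duration / 4)
    start <- cumsum(dur + stats::rexp(n, rate = 1 / (10 * cfg$mean_duration)))
    size_dex <- stats::rnbinom(n, size = cfg$size_dispersion,
                               mu = cfg$mean_photons)
    # acceptor-excitation photons ride the same transit: proportional to
    # the per-burst brightness, not an independent draw
    size_aex <- stats::rpois(n, size_dex)
    state <- sample.int(length(model$weights), n, replace = TRUE,
                        prob = model$weights)
    # truncated-Gaussian efficiencies: resample draws outside [0, 1]
    e_true <- stats::rnorm(n, model$centers[state], model$widths[state])
    bad <- which(e_true < 0 | e_true > 1)
    while (length(bad)) {
      e_true[bad] <- stats::rnorm(length(bad), model$centers[state[bad]],
                                  model$widths[state[bad]])
      bad <- bad[e_true[bad] < 0 | e_true[bad] > 1]
    }
    g <- cfg$gamma_true
    p_acc <- g * e_true / (1 - e_true + g * e_true)

    n_a_sig <- stats::rbinom(n, size_dex, p_acc)
    n_d_sig <- size_dex - n_a_sig
    n_aa_sig <- size_aex
    # single-labelled contaminants: missing dye -> no signal in its channels
    n_a_sig[kind == "donly"] <- 0L
    n_d_sig[kind == "aonly"] <- 0L
    n_a_sig[kind == "aonly"] <- 0L
    n_aa_sig[kind == "donly"] <- 0L
    e_true[kind != "da"] <- NA_real_

    leak <- stats::rpois(n, cfg$leakage * n_d_sig)
    dirx <- stats::rpois(n, cfg$direct_excitation * n_aa_sig)
    bg <- cfg$background_rates
    n_dd <- n_d_sig + stats::rpois(n, bg[["DexDem"]] * dur)
    n_da <- n_a_sig + leak + dirx + stats::rpois(n, bg[["DexAem"]] * dur)
    n_aa <- n_aa_sig + stats::rpois(n, bg[["AexAem"]] * dur)

    st <- state
    st[kind == "donly"] <- 0L
    st[kind == "aonly"] <- -1L
    data.frame(burst_id = seq_len(n), start_ms = start, duration_ms = dur,
               n_DexDem = n_dd, n_DexAem = n_da, n_AexAem = n_aa,
               true_state = st, true_E = e_true)
  })
}
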