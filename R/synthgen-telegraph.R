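#' Telegraph distance-trajectory configuration
#'
#' A two-state continuous-time Markov (telegraph) process standing in for
#' an inter-residue distance trace: the distance jumps between a quenched
#' (short) and an unquenched (long) level, sampled on a regular grid with
#' additive Gaussian jitter.
#'
#' @param rate_to_quenched,rate_to_unquenched switching rates, per us.
#' @param level_quenched,level_unquenched distance levels, nm
#'   (`level_quenched < level_unquenched`).
#' @param jitter_sd per-sample Gaussian jitter, nm.
#' @param dt sampling interval, ns.
#' @param duration trace length, us.
#' @param ou_jitter if `TRUE`, jitter is an Ornstein-Uhlenbeck process
#'   with correlation time `ou_tau` (ns) instead of i.i.d. noise.
#' @param ou_tau OU correlation time, ns.
#' @param seed integer seed.
#' @return An object of class `telegraph_config`.
#' @export
telegraph_config <- function(rate_to_quenched = 0.5, rate_to_unquenched = 0.5,
                             level_quenched = 1.5, level_unquenched = 2.1,
                             jitter_sd = 0.05, dt = 1, duration = 200,
                             ou_jitter = FALSE, ou_tau = 5, seed = 1L) {
  stopifnot(rate_to_quenched >= 0, rate_to_unquenched >= 0, dt > 0,
            duration >= dt / 1e3, jitter_sd >= 0, ou_tau > 0)
  if (level_quenched >= level_unquenched)
    stop("level_quenched must be below level_unquenched")
  n <- floor(duration * 1e3 / dt)
  if (n < 10) stop("duration must cover at least 10 samples")
  structure(list(rate_to_quenched = rate_to_quenched,
                 rate_to_unquenched = rate_to_unquenched,
                 level_quenched = level_quenched,
                 level_unquenched = level_unquenched,
                 jitter_sd = jitter_sd, dt = dt, duration = duration,
                 ou_jitter = ou_jitter, ou_tau = ou_tau,
                 seed = as.integer(seed)),
            class = "telegraph_config")
}

#' Simulate a two-state telegraph distance trajectory
#'
#' Draws exponential dwell times, samples the state on the regular grid
#' and adds jitter. True switch times are attached as attribute
#' `switch_times_ns` (ground truth for transition counting).
#'
#' @param cfg a [telegraph_config()].
#' @return A data.frame with `t_ns`, `d_nm` and `true_state` (1 =
#'   quenched level, 0 = unquenched); attributes `switch_times_ns`,
#'   `dt_ns`.
#' @export
simulate_distance_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "telegraph_config"))
  total_ns <- cfg$duration * 1e3
  with_seed(cfg$seed, {
    # alternate exponential dwells; rates are per us -> dwell in ns
    k_q <- cfg$rate_to_quenched / 1e3     # unquenched -> quenched, per ns
    k_u <- cfg$rate_to_unquenched / 1e3   # quenched -> unquenched, per ns
    p_start_q <- if (k_q + k_u > 0) k_q / (k_q + k_u) else 0
    state0 <- stats::rbinom(1, 1, p_start_q)  # 1 = quenched
    switches <- numeric(0)
    t_cur <- 0
    s_cur <- state0
    while (t_cur < total_ns) {
      rate <- if (s_cur == 1) k_u else k_q
      if (rate <= 0) break
      t_cur <- t_cur + stats::rexp(1, rate)
      if (t_cur < total_ns) switches <- c(switches, t_cur)
      s_cur <- 1 - s_cur
    }
    t_grid <- seq(0, total_ns - cfg$dt, by = cfg$dt)
    state <- (state0 + findInterval(t_grid, switches)) %% 2
    d <- ifelse(state == 1, cfg$level_quenched, cfg$level_unquenched)
    if (cfg$jitter_sd > 0) {
      if (cfg$ou_jitter) {
        a <- exp(-cfg$dt / cfg$ou_tau)
        innov <- stats::rnorm(length(t_grid), 0, cfg$jitter_sd * sqrt(1 - a^2))
        j <- stats::filter(innov, a, method = "recursive")
        d <- d + as.numeric(j)
      } else {
        d <- d + stats::rnorm(length(t_grid), 0, cfg$jitter_sd)
      }
    }
    out <- data.frame(t_ns = t_grid, d_nm = pmax(d, 0), true_state = state)
    attr(out, "switch_times_ns") <- switches
    attr(out, "dt_ns") <- cfg$dt
    out
  })
}

#' Analytic switching frequency of a telegraph process
#'
#' Expected number of level transitions per us for a two-state Markov
#' process: 2 k1 k2 / (k1 + k2).
#'
#' @param rate_to_quenched,rate_to_unquenched rates, per us.
#' @return transitions per us.
#' @export
telegraph_switch_frequency <- function(rate_to_quenched, rate_to_unquenched) {
  2 * rate_to_quenched * rate_to_unquenched /
    (rate_to_quenched + rate_to_unquenched)
}
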