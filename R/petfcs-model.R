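#' PET-FCS model parameters
#'
#' Parameters of the correlation model: 3-D diffusion through a Gaussian
#' detection volume of axial ellipticity `s`, multiplied by a blinking
#' factor with one triplet term and up to three quenching exponentials,
#'
#' G(tau) = (1/N) (1 + tau/tau_d)^-1 (1 + tau/(s^2 tau_d))^-1/2 *
#'          (1 + K_t e^(-tau/t_trip) + sum K_i e^(-tau/t_q_i)).
#'
#' All times are in microseconds.
#'
#' @param n_mean average occupancy of the detection volume.
#' @param tau_d diffusion time, us.
#' @param s axial-to-lateral ellipticity (> 1).
#' @param k_trip,t_trip triplet amplitude and lifetime (us).
#' @param quench_amps,quench_taus amplitudes and lifetimes (us) of 0-3
#'   quenching components.
#' @return An object of class `fcs_params`.
#' @examples
#' # receptor-like ground truth: triplet + three quenching components
#' fcs_params(n_mean = 1, tau_d = 1000, s = 5, k_trip = 0.19, t_trip = 5,
#'            quench_amps = c(0.38, 0.24, 0.31),
#'            quench_taus = c(0.34, 52, 264))
#' @export
fcs_params <- function(n_mean = 1, tau_d = 1000, s = 5,
                       k_trip = 0, t_trip = 5,
                       quench_amps = numeric(0), quench_taus = numeric(0)) {
  stopifnot(n_mean > 0, tau_d > 0, s > 1, k_trip >= 0, t_trip > 0,
            length(quench_amps) == length(quench_taus),
            length(quench_amps) <= 3)
  if (length(quench_taus)) stopifnot(all(quench_amps >= 0), all(quench_taus > 0))
  structure(list(n_mean = n_mean, tau_d = tau_d, s = s, k_trip = k_trip,
                 t_trip = t_trip, quench_amps = as.numeric(quench_amps),
                 quench_taus = as.numeric(quench_taus)),
            class = "fcs_params")
}

#' Evaluate the PET-FCS correlation model
#'
#' @param params an [fcs_params()].
#' @param lags lag times, us.
#' @param blinking if `FALSE`, evaluate the pure diffusion term only
#'   (blinking factor set to 1).
#' @return numeric vector of G values.
#' @export
fcs_model <- function(params, lags, blinking = TRUE) {
  stopifnot(inherits(params, "fcs_params"), all(lags >= 0))
  p <- params
  diff_term <- (1 / p$n_mean) * (1 + lags / p$tau_d)^-1 *
    (1 + lags / (p$s^2 * p$tau_d))^-0.5
  if (!blinking) return(diff_term)
  blink <- 1 + p$k_trip * exp(-lags / p$t_trip)
  for (i in seq_along(p$quench_amps))
    blink <- blink + p$quench_amps[i] * exp(-lags / p$quench_taus[i])
  diff_term * blink
}

#' Hydrodynamic radius from a diffusion time
#'
#' Applies the Stokes-Einstein relation to an FCS diffusion time:
#' omega0^2 / (4 tau_d) = k_B T / (6 pi eta R_H), solved for R_H.
#'
#' @param tau_d diffusion time, us.
#' @param omega0 lateral 1/e^2 waist of the detection volume, nm.
#' @param temperature K.
#' @param viscosity Pa s.
#' @return Hydrodynamic radius, nm.
#' @export
hydrodynamic_radius <- function(tau_d, omega0 = 250, temperature = 298,
                                viscosity = 1e-3) {
  stopifnot(tau_d > 0, omega0 > 0, temperature > 0, viscosity > 0)
  kb <- 1.380649e-23                       # J/K
  d_coef <- (omega0 * 1e-9)^2 / (4 * tau_d * 1e-6)   # m^2/s
  rh <- kb * temperature / (6 * pi * viscosity * d_coef)
  rh * 1e9
}

#' Convert a quenching lifetime to a collision frequency
#'
#' @param t_q lifetime value.
#' @param unit_in unit of `t_q` ("us", "ns" or "ms").
#' @param unit_out unit of the returned rate ("per_us" or "per_ms").
#' @return rate 1/t_q in the requested unit.
#' @examples
#' quench_rate(40, "us", "per_ms")   # 25 events per ms
#' quench_rate(270, "ns", "per_us")  # ~3.7 events per us
#' @export
quench_rate <- function(t_q, unit_in = c("us", "ns", "ms"),
                        unit_out = c("per_us", "per_ms")) {
  unit_in <- match.arg(unit_in)
  unit_out <- match.arg(unit_out)
  stopifnot(t_q > 0)
  t_us <- switch(unit_in, us = t_q, ns = t_q / 1e3, ms = t_q * 1e3)
  rate_per_us <- 1 / t_us
  switch(unit_out, per_us = rate_per_us, per_ms = rate_per_us * 1e3)
}
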