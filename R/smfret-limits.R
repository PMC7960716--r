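#' Shot-noise-limited histogram width
#'
#' For a static FRET state of efficiency `mean_E` observed with `mean_photons`
#' photons per burst, the binomial variance of the per-burst estimate is
#' E(1 - E)/F; the corresponding full width at half maximum is
#' 2 sqrt(2 ln 2) * sqrt(E(1 - E)/F). Any conformational or photophysical
#' broadening adds on top of this floor.
#'
#' @param mean_E mean FRET efficiency (fraction in \[0, 1\]).
#' @param mean_photons mean total photons per burst (F).
#' @param percent return the FWHM in percent (default) or as a fraction.
#' @return shot-noise FWHM.
#' @export
shot_noise_fwhm <- function(mean_E, mean_photons, percent = TRUE) {
  stopifnot(mean_E >= 0, mean_E <= 1, mean_photons > 0)
  sigma <- sqrt(mean_E * (1 - mean_E) / mean_photons)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  if (percent) 100 * fwhm else fwhm
}

#' Broadening benchmark for a FRET histogram
#'
#' Pairs the shot-noise floor with a supplied quasi-static reference
#' width (e.g. from a rigid dsDNA scaffold). The reference must not be
#' narrower than the shot-noise floor.
#'
#' @param mean_E mean efficiency (fraction).
#' @param mean_photons mean photons per burst.
#' @param static_limit_fwhm quasi-static reference FWHM, percent.
#' @return list with `shot_noise_fwhm` and `static_limit_fwhm` (percent).
#' @export
broadening_benchmark <- function(mean_E, mean_photons, static_limit_fwhm) {
  sn <- shot_noise_fwhm(mean_E, mean_photons)
  if (static_limit_fwhm < sn)
    stop("quasi-static reference narrower than the shot-noise floor")
  list(shot_noise_fwhm = sn, static_limit_fwhm = static_limit_fwhm)
}

#' Donor-acceptor distance from a FRET efficiency
#'
#' Inverts E = 1 / (1 + (R/R0)^6): R = R0 * ((1 - E)/E)^(1/6).
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Foerster radius, Angstrom (50.1 A for the AF488-AF647 pair).
#' @return distance in Angstrom.
#' @examples
#' forster_distance(0.5, 50.1)   # E = 0.5 returns R0
#' forster_distance(0.24, 50.1)  # low-FRET state, ~60.7 A
#' @export
forster_distance <- function(E, R0 = 50.1) {
  stopifnot(R0 > 0)
  if (any(E <= 0 | E >= 1))
    stop("E must lie strictly inside (0, 1); the inversion diverges at 0 and 1")
  R0 * ((1 - E) / E)^(1 / 6)
}
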