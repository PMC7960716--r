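#' Burst-search parameters
#'
#' Sliding-window photon-density burst search: a window of
#' `window_photons` consecutive photons qualifies when it spans at most
#' `max_window_span`; photons covered by qualifying windows form
#' candidate bursts, candidates separated by less than `merge_gap` are
#' merged, and bursts with fewer than `min_burst_photons` photons are
#' discarded.
#'
#' @param window_photons photons per sliding window (m).
#' @param max_window_span maximal window span, us.
#' @param min_burst_photons minimal photons per retained burst.
#' @param merge_gap gap below which adjacent bursts merge, us.
#' @return An object of class `burst_search_params`.
#' @export
burst_search_params <- function(window_photons = 10, max_window_span = 500,
                                min_burst_photons = 30, merge_gap = 50) {
  stopifnot(window_photons > 0, max_window_span > 0, min_burst_photons > 0,
            merge_gap > 0)
  structure(list(window_photons = as.integer(window_photons),
                 max_window_span = max_window_span,
                 min_burst_photons = as.integer(min_burst_photons),
                 merge_gap = merge_gap),
            class = "burst_search_params")
}

#' Detect fluorescence bursts in a photon stream
#'
#' @param photons data.frame with `timestamp_ns` (sorted ascending),
#'   `excitation` and `emission` (each "D" or "A").
#' @param params a [burst_search_params()].
#' @return A data.frame with one row per burst: `burst_id`, `start_ms`,
#'   `duration_ms`, `n_photons`, `n_DexDem`, `n_DexAem`, `n_AexAem`,
#'   and `first_idx`/`last_idx` into the photon stream.
#' @export
detect_bursts <- function(photons, params = burst_search_params()) {
  stopifnot(is.data.frame(photons),
            all(c("timestamp_ns", "excitation", "emission") %in% names(photons)),
            inherits(params, "burst_search_params"))
  n <- nrow(photons)
  empty <- data.frame(burst_id = integer(0), start_ms = numeric(0),
                      duration_ms = numeric(0), n_photons = integer(0),
                      n_DexDem = integer(0), n_DexAem = integer(0),
                      n_AexAem = integer(0), first_idx = integer(0),
                      last_idx = integer(0))
  if (n == 0) return(empty)
  ts <- photons$timestamp_ns
  stop_if_not_sorted(ts, "photon timestamps")
  m <- params$window_photons
  span_ns <- params$max_window_span * 1e3
  if (n < m) return(empty)
  # windows starting at j: span t[j+m-1] - t[j]
  ok <- (ts[m:n] - ts[1:(n - m + 1)]) <= span_ns
  in_burst <- logical(n)
  starts <- which(ok)
  if (!length(starts)) return(empty)
  # union of [j, j+m-1] for qualifying j, via difference array
  diffa <- integer(n + 1)
  diffa[starts] <- diffa[starts] + 1L
  diffa[starts + m] <- diffa[starts + m] - 1L
  in_burst <- cumsum(diffa[1:n]) > 0
  r <- rle(in_burst)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  first <- idx_start[r$values]
  last <- idx_end[r$values]
  # merge runs whose inter-burst gap is below merge_gap
  if (length(first) > 1) {
    gap_ns <- ts[first[-1]] - ts[last[-length(last)]]
    keep_break <- gap_ns >= params$merge_gap * 1e3
    grp <- cumsum(c(TRUE, keep_break))
    first <- tapply(first, grp, min)
    last <- tapply(last, grp, max)
  }
  n_phot <- last - first + 1L
  sel <- n_phot >= params$min_burst_photons
  first <- first[sel]; last <- last[sel]; n_phot <- n_phot[sel]
  if (!length(first)) return(empty)
  tally <- function(f, l, exc, emi) {
    idx <- seq.int(f, l)
    sum(photons$excitation[idx] == exc & photons$emission[idx] == emi)
  }
  data.frame(
    burst_id = seq_along(first),
    start_ms = ts[first] / 1e6,
    duration_ms = (ts[last] - ts[first]) / 1e6,
    n_photons = as.integer(n_phot),
    n_DexDem = mapply(tally, first, last, MoreArgs = list(exc = "D", emi = "D")),
    n_DexAem = mapply(tally, first, last, MoreArgs = list(exc = "D", emi = "A")),
    n_AexAem = mapply(tally, first, last, MoreArgs = list(exc = "A", emi = "A")),
    first_idx = as.integer(first), last_idx = as.integer(last))
}

#' Correction factors for burst intensities
#'
#' @param gamma detection-efficiency/quantum-yield correction; if the
#'   four optional efficiency/yield arguments are given, `gamma` must
#'   equal `(eta_Aem * Phi_A) / (eta_Dem * Phi_D)`.
#' @param background_rates counts per ms for `DexDem`, `DexAem`, `AexAem`.
#' @param leakage donor-to-acceptor spectral crossover fraction.
#' @param direct_excitation fraction of `AexAem` removed from the
#'   donor-excitation acceptor channel (0 disables the correction).
#' @param eta_Dem,eta_Aem,Phi_D,Phi_A optional detection efficiencies and
#'   quantum yields consistent with `gamma`.
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(gamma = 0.56,
                           background_rates = c(DexDem = 0, DexAem = 0, AexAem = 0),
                           leakage = 0, direct_excitation = 0,
                           eta_Dem = NULL, eta_Aem = NULL,
                           Phi_D = NULL, Phi_A = NULL) {
  stopifnot(gamma > 0, leakage >= 0, leakage < 1,
            direct_excitation >= 0, direct_excitation < 1)
  if (any(background_rates < 0)) stop("background rates must be nonnegative")
  opt <- list(eta_Dem, eta_Aem, Phi_D, Phi_A)
  if (all(!vapply(opt, is.null, logical(1)))) {
    g <- (eta_Aem * Phi_A) / (eta_Dem * Phi_D)
    if (abs(g - gamma) > 1e-6)
      stop("gamma inconsistent with detection efficiencies and quantum yields")
  }
  bg <- background_rates
  if (is.null(names(bg))) names(bg) <- c("DexDem", "DexAem", "AexAem")
  structure(list(gamma = gamma, background_rates = bg, leakage = leakage,
                 direct_excitation = direct_excitation),
            class = "correction_set")
}

#' Apply background and crosstalk corrections to a burst table
#'
#' Per channel, the expected background (rate x duration) is subtracted
#' and floored at zero; a `leakage` fraction of the corrected donor
#' counts is then removed from the acceptor channel, and (when enabled) a
#' `direct_excitation` fraction of the `AexAem` counts is removed from
#' the donor-excitation acceptor channel. Adds `I_D`, `I_A` (corrected
#' donor-excitation channels), `I_DD` (gamma-weighted total
#' donor-excitation signal) and `I_AA`.
#'
#' @param bursts burst table with `n_DexDem`, `n_DexAem`, `n_AexAem`,
#'   `duration_ms`.
#' @param corr a [correction_set()].
#' @return The burst table with corrected-intensity columns appended; the
#'   number of values floored at zero is attached as attribute
#'   `n_floored`.
#' @export
apply_corrections <- function(bursts, corr = correction_set()) {
  stopifnot(is.data.frame(bursts), inherits(corr, "correction_set"),
            all(c("n_DexDem", "n_DexAem", "n_AexAem", "duration_ms") %in%
                  names(bursts)))
  bg <- corr$background_rates
  i_d <- bursts$n_DexDem - bg[["DexDem"]] * bursts$duration_ms
  i_a <- bursts$n_DexAem - bg[["DexAem"]] * bursts$duration_ms
  i_aa <- bursts$n_AexAem - bg[["AexAem"]] * bursts$duration_ms
  n_floor <- sum(i_d < 0) + sum(i_a < 0) + sum(i_aa < 0)
  i_d <- pmax(i_d, 0); i_a <- pmax(i_a, 0); i_aa <- pmax(i_aa, 0)
  i_a <- pmax(i_a - corr$leakage * i_d, 0)
  if (corr$direct_excitation > 0)
    i_a <- pmax(i_a - corr$direct_excitation * i_aa, 0)
  bursts$I_D <- i_d
  bursts$I_A <- i_a
  bursts$I_AA <- i_aa
  bursts$I_DD <- i_a + corr$gamma * i_d
  if (n_floor > 0) attr(bursts, "n_floored") <- n_floor
  bursts
}

#' Per-burst FRET efficiency
#'
#' E = I_A / (I_A + gamma * I_D). Bursts with a zero denominator return
#' `NA` (flagged, not dropped).
#'
#' @param I_A,I_D corrected acceptor and donor counts under donor
#'   excitation (vectors or a burst table via `bursts`).
#' @param gamma correction factor.
#' @return numeric vector of efficiencies in \[0, 1\] (fractions).
#' @export
fret_efficiency <- function(I_A, I_D, gamma = 0.56) {
  stopifnot(gamma > 0)
  den <- I_A + gamma * I_D
  ifelse(den > 0, I_A / den, NA_real_)
}

#' Per-burst donor-acceptor stoichiometry
#'
#' S = I_DD / (I_DD + I_AA); ~1 for donor-only and ~0 for acceptor-only
#' bursts, intermediate for dual-labelled molecules.
#'
#' @param I_DD total corrected donor-excitation signal.
#' @param I_AA corrected acceptor signal under acceptor excitation.
#' @return numeric vector of stoichiometries; `NA` where undefined.
#' @export
stoichiometry <- function(I_DD, I_AA) {
  den <- I_DD + I_AA
  ifelse(den > 0, I_DD / den, NA_real_)
}

#' Keep dual-labelled bursts by stoichiometry
#'
#' @param bursts burst table carrying `I_DD` and `I_AA` (see
#'   [apply_corrections()]).
#' @param s_min,s_max inclusive stoichiometry bounds.
#' @return The filtered burst table with an `S` column.
#' @export
filter_stoichiometry <- function(bursts, s_min = 0.2, s_max = 0.8) {
  stopifnot(all(c("I_DD", "I_AA") %in% names(bursts)))
  s <- stoichiometry(bursts$I_DD, bursts$I_AA)
  bursts$S <- s
  bursts[!is.na(s) & s >= s_min & s <= s_max, , drop = FALSE]
}
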