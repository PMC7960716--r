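#' Decay simulation configuration
#'
#' Ground truth for synthetic TCSPC histograms: a multi-exponential
#' isotropic decay (amplitude fractions `amplitudes`, lifetimes
#' `lifetimes` in ns) binned on a regular grid, with optional polarized
#' channels built from an anisotropy decay r(t) = r0 * sum(A_i *
#' exp(-t/rho_i)).
#'
#' @param lifetimes fluorescence lifetimes, ns, all positive.
#' @param amplitudes amplitude fractions; must sum to 1.
#' @param total_counts expected total photon count of the histogram.
#' @param bin_width TCSPC bin width, ns (default 16 ps).
#' @param window histogram span, ns.
#' @param anisotropy optional list with elements `r0`, `rhos` (ns) and
#'   `fractions` (sum to 1); when given, parallel/perpendicular channels
#'   are generated.
#' @param seed integer seed.
#' @return An object of class `decay_sim_config`.
#' @export
decay_sim_config <- function(lifetimes, amplitudes, total_counts = 1e6,
                             bin_width = 0.016, window = 50,
                             anisotropy = NULL, seed = 1L) {
  stopifnot(length(lifetimes) == length(amplitudes), all(lifetimes > 0),
            window > bin_width, bin_width > 0, total_counts >= 0)
  if (abs(sum(amplitudes) - 1) > 1e-9) stop("amplitudes must sum to 1")
  if (!is.null(anisotropy)) {
    stopifnot(is.list(anisotropy),
              all(c("r0", "rhos", "fractions") %in% names(anisotropy)),
              length(anisotropy$rhos) == length(anisotropy$fractions),
              all(anisotropy$rhos > 0))
    if (abs(sum(anisotropy$fractions) - 1) > 1e-9)
      stop("anisotropy fractions must sum to 1")
  }
  structure(list(lifetimes = as.numeric(lifetimes),
                 amplitudes = as.numeric(amplitudes),
                 total_counts = total_counts, bin_width = bin_width,
                 window = window, anisotropy = anisotropy,
                 seed = as.integer(seed)),
            class = "decay_sim_config")
}

# Multi-exponential decay expectation on bin centers, normalized so the
# expected histogram total equals total_counts.
decay_expectation <- function(cfg) {
  t <- seq(cfg$bin_width / 2, cfg$window, by = cfg$bin_width)
  f <- rowSums(sapply(seq_along(cfg$lifetimes), function(i)
    cfg$amplitudes[i] * exp(-t / cfg$lifetimes[i])))
  list(bin_ns = t, mean = f / sum(f) * cfg$total_counts)
}

#' Simulate a TCSPC decay histogram
#'
#' Bin counts are Poisson draws around the multi-exponential expectation.
#' When `cfg$anisotropy` is present, polarized channels are constructed
#' as I_par = F(t) (1 + 2 r(t))/3 and I_perp = F(t) (1 - r(t))/3 before
#' noise, so that the anisotropy estimator (with G = 1) returns r(t)
#' exactly in the noiseless limit.
#'
#' @param cfg a [decay_sim_config()].
#' @param noiseless if `TRUE`, return the (non-integer) expectation
#'   instead of Poisson draws.
#' @return A data.frame with `bin_ns` and `counts`, or with
#'   `counts_par`/`counts_perp` for polarized output.
#' @export
simulate_decay_histogram <- function(cfg, noiseless = FALSE) {
  stopifnot(inherits(cfg, "decay_sim_config"))
  ex <- decay_expectation(cfg)
  if (cfg$total_counts == 0) {
    warning("total_counts is 0: returning an all-zero histogram")
    ex$mean[] <- 0
  }
  if (is.null(cfg$anisotropy)) {
    counts <- if (noiseless) ex$mean else
      with_seed(cfg$seed, stats::rpois(length(ex$mean), ex$mean))
    return(data.frame(bin_ns = ex$bin_ns, counts = counts))
  }
  an <- cfg$anisotropy
  r <- an$r0 * rowSums(sapply(seq_along(an$rhos), function(i)
    an$fractions[i] * exp(-ex$bin_ns / an$rhos[i])))
  mu_par <- ex$mean * (1 + 2 * r) / 3
  mu_perp <- ex$mean * (1 - r) / 3
  if (noiseless)
    return(data.frame(bin_ns = ex$bin_ns, counts_par = mu_par,
                      counts_perp = mu_perp))
  with_seed(cfg$seed, data.frame(
    bin_ns = ex$bin_ns,
    counts_par = stats::rpois(length(mu_par), mu_par),
    counts_perp = stats::rpois(length(mu_perp), mu_perp)))
}
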