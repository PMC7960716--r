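# Direct normalized autocorrelation of a binned intensity signal at
# integer bin lags: G(k) = <n_i n_{i+k}> / (<n_head> <n_tail>) - 1 with
# symmetric normalization. Shared by the multi-tau levels and usable as
# a brute-force reference on short signals.
direct_correlate_bins <- function(n, lags_bins) {
  len <- length(n)
  vapply(lags_bins, function(k) {
    if (k >= len) return(NA_real_)
    head <- n[1:(len - k)]
    tail <- n[(1 + k):len]
    mh <- mean(head); mt <- mean(tail)
    if (mh == 0 || mt == 0) return(NA_real_)
    mean(head * tail) / (mh * mt) - 1
  }, numeric(1))
}

#' Multi-tau autocorrelation of a photon stream
#'
#' Bins the photon arrival times at `bin_width_ns` and computes the
#' normalized intensity autocorrelation g(tau) - 1 on a quasi-logarithmic
#' multi-tau grid: `n_casc` lags at the base resolution, then the signal
#' is coarsened by summing pairs of bins and another `n_casc / 2` lags
#' are added per level at the doubled spacing (8 points per octave with
#' the default `n_casc = 16`). Per-lag uncertainties are estimated by
#' splitting the stream into `n_blocks` contiguous blocks and taking the
#' standard error of the block-wise correlations.
#'
#' @param timestamps_ns sorted photon arrival times, ns.
#' @param bin_width_ns base binning of the correlator, ns.
#' @param n_casc lags per level (a power of two).
#' @param max_lag_us stop once lags exceed this value.
#' @param n_blocks blocks for the standard-error estimate.
#' @return data.frame of class `fcs_curve` with `lag_us`, `G`, `sem`.
#' @export
multitau_correlate <- function(timestamps_ns, bin_width_ns = 100,
                               n_casc = 16, max_lag_us = NULL,
                               n_blocks = 8) {
  if (length(timestamps_ns) < 1000)
    stop("need at least 1000 photons for a correlation estimate")
  stop_if_not_sorted(timestamps_ns, "photon timestamps")
  t0 <- timestamps_ns - timestamps_ns[1]
  n_bins <- floor(t0[length(t0)] / bin_width_ns) + 1
  counts <- tabulate(floor(t0 / bin_width_ns) + 1L, nbins = n_bins)
  one_pass <- function(sig) {
    dt <- bin_width_ns
    lags_ns <- numeric(0)
    g <- numeric(0)
    lag_set <- seq_len(n_casc)
    repeat {
      gv <- direct_correlate_bins(sig, lag_set)
      lags_ns <- c(lags_ns, lag_set * dt)
      g <- c(g, gv)
      if (!is.null(max_lag_us) && max(lag_set) * dt > max_lag_us * 1e3) break
      # coarsen by 2
      len2 <- floor(length(sig) / 2)
      if (len2 < 2 * n_casc) break
      sig <- sig[seq_len(2 * len2)]
      sig <- sig[c(TRUE, FALSE)] + sig[c(FALSE, TRUE)]
      dt <- dt * 2
      lag_set <- seq(n_casc / 2 + 1, n_casc)
    }
    keep <- is.finite(g)
    data.frame(lag_ns = lags_ns[keep], G = g[keep])
  }
  full <- one_pass(counts)
  # block-wise sem at the lags of the full-stream grid
  blk_len <- floor(length(counts) / n_blocks)
  sems <- rep(NA_real_, nrow(full))
  if (blk_len > 4 * n_casc) {
    blocks <- lapply(seq_len(n_blocks), function(b)
      one_pass(counts[((b - 1) * blk_len + 1):(b * blk_len)]))
    for (i in seq_len(nrow(full))) {
      vals <- vapply(blocks, function(bl) {
        j <- match(full$lag_ns[i], bl$lag_ns)
        if (is.na(j)) NA_real_ else bl$G[j]
      }, numeric(1))
      vals <- vals[is.finite(vals)]
      if (length(vals) >= 3)
        sems[i] <- stats::sd(vals) / sqrt(length(vals))
    }
  }
  out <- data.frame(lag_us = full$lag_ns / 1e3, G = full$G, sem = sems)
  class(out) <- c("fcs_curve", "data.frame")
  out
}
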