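#' Centered running average of a distance series
#'
#' Moving mean over `round(window / dt)` samples (forced odd); at the
#' edges the window shrinks symmetrically so the output length equals the
#' input length.
#'
#' @param series data.frame with `t_ns` (uniform spacing) and `d_nm`.
#' @param window averaging window, ns (20 ns by default).
#' @return The series with `d_nm` replaced by its running average.
#' @export
running_average <- function(series, window = 20) {
  stopifnot(all(c("t_ns", "d_nm") %in% names(series)), nrow(series) >= 2)
  dt <- series$t_ns[2] - series$t_ns[1]
  if (window < dt) {
    warning("window shorter than the sampling interval; returning input")
    return(series)
  }
  nw <- round(window / dt)
  if (nw %% 2 == 0) nw <- nw + 1L
  h <- (nw - 1L) %/% 2L
  n <- nrow(series)
  d <- series$d_nm
  # local window sums (stats::filter) rather than cumsum differences:
  # long-range cumsum round-off would leave constant plateaus oscillating
  # at the last bit, which a cutoff placed exactly on a level amplifies
  # into spurious transitions
  out <- as.numeric(stats::filter(d, rep(1, nw), sides = 2)) / nw
  for (i in seq_len(min(h, n))) {
    out[i] <- mean(d[1:min(i + h, n)])
    j <- n - i + 1L
    out[j] <- mean(d[max(j - h, 1):n])
  }
  series$d_nm <- out
  series
}

#' Classify a distance series into quenched/unquenched states
#'
#' Samples with distance strictly below the cutoff `d_q` are "quenched"
#' (dark); transitions are counted as state changes between consecutive
#' samples. An optional hysteresis band suppresses re-crossings within
#' +/- `hysteresis` nm of the cutoff.
#'
#' @param series data.frame with `t_ns` and `d_nm`.
#' @param d_q quenching cutoff distance, nm.
#' @param hysteresis half-width of the hysteresis band, nm (0 disables).
#' @return list of class `quench_trace`: `states` (logical, TRUE =
#'   quenched), `n_transitions`, `duration_us`, `freq_per_us`,
#'   `quenched_fraction`, `cutoff`.
#' @export
assign_states <- function(series, d_q, hysteresis = 0) {
  stopifnot(all(c("t_ns", "d_nm") %in% names(series)), d_q > 0,
            hysteresis >= 0)
  d <- series$d_nm
  if (hysteresis == 0) {
    st <- d < d_q
  } else {
    st <- logical(length(d))
    st[1] <- d[1] < d_q
    for (i in 2:length(d)) {
      st[i] <- if (st[i - 1]) d[i] < d_q + hysteresis else d[i] < d_q - hysteresis
    }
  }
  dt <- series$t_ns[2] - series$t_ns[1]
  dur_us <- (series$t_ns[length(d)] - series$t_ns[1] + dt) / 1e3
  n_tr <- sum(st[-1] != st[-length(st)])
  structure(list(states = st, n_transitions = n_tr, duration_us = dur_us,
                 freq_per_us = n_tr / dur_us,
                 quenched_fraction = mean(st), cutoff = d_q),
            class = "quench_trace")
}

#' Transition frequency versus quenching cutoff
#'
#' For each replicate series: smooth with a running average, count
#' quench/de-quench transitions at every cutoff of the grid, convert to
#' a per-microsecond frequency, then aggregate mean and standard
#' deviation across replicates (unweighted).
#'
#' @param series_list list of distance series data.frames (replicates).
#' @param cutoffs cutoff grid, nm.
#' @param window smoothing window, ns (0 disables smoothing).
#' @return data.frame with `cutoff_nm`, `freq_per_us_mean`,
#'   `freq_per_us_sd`.
#' @export
scan_cutoffs <- function(series_list, cutoffs = seq(1, 2, by = 0.05),
                         window = 20) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1, all(cutoffs > 0))
  freqs <- sapply(series_list, function(s) {
    if (window > 0) s <- running_average(s, window)
    vapply(cutoffs, function(cf) assign_states(s, cf)$freq_per_us,
           numeric(1))
  })
  freqs <- matrix(freqs, nrow = length(cutoffs))
  data.frame(cutoff_nm = cutoffs,
             freq_per_us_mean = rowMeans(freqs),
             freq_per_us_sd = apply(freqs, 1, stats::sd))
}

#' Quenching cutoff from the dye-cloud extension
#'
#' The contact-quenching range of the dye/quencher pair plus the mean
#' extension of the dye cloud from its anchor atom: d_q = quench_range +
#' l_mean.
#'
#' @param l_mean mean dye-cloud extension, nm.
#' @param quench_range contact quenching range, nm (1.0 for
#'   BODIPY-FL/tyrosine).
#' @return cutoff distance, nm.
#' @examples
#' quench_cutoff(0.81)  # 1.81 nm
#' @export
quench_cutoff <- function(l_mean, quench_range = 1.0) {
  stopifnot(l_mean >= 0, quench_range >= 0)
  quench_range + l_mean
}

#' Dye-cloud geometry from per-frame aromatic-atom coordinates
#'
#' Per frame, the distance from the anchor (C-beta of the labelled
#' residue) to the unweighted centroid of the dye's aromatic atoms is
#' computed; the mean extension and, when a frame interval is supplied,
#' the exponential lifetime of the distance autocorrelation are reported.
#'
#' @param anchor numeric length-3 anchor coordinates, nm.
#' @param frames list of per-frame atom coordinate matrices (rows =
#'   atoms, columns = x/y/z in nm).
#' @param dt_ns frame interval for the autocorrelation lifetime (NULL
#'   skips it).
#' @return list of class `dye_cloud_stats`: `samples` (per-frame
#'   distances), `l_mean`, `acor_lifetime_ns` (NA if not computed).
#' @export
dye_extension <- function(anchor, frames, dt_ns = NULL) {
  stopifnot(length(anchor) == 3, length(frames) >= 1)
  samples <- vapply(frames, function(fr) {
    fr <- as.matrix(fr)
    if (nrow(fr) == 0) stop("empty atom set in a frame")
    sqrt(sum((colMeans(fr) - anchor)^2))
  }, numeric(1))
  acor <- NA_real_
  if (!is.null(dt_ns) && length(samples) >= 20 &&
      stats::sd(samples) > 0) {
    nl <- min(length(samples) - 1, 200)
    ac <- stats::acf(samples, lag.max = nl, plot = FALSE)$acf[-1]
    pos <- which(ac > 0.05)
    if (length(pos) >= 3) {
      lags <- seq_along(ac)[pos] * dt_ns
      fit <- stats::lm(log(ac[pos]) ~ 0 + lags)
      acor <- -1 / stats::coef(fit)[[1]]
    }
  }
  structure(list(samples = samples, l_mean = mean(samples),
                 acor_lifetime_ns = acor),
            class = "dye_cloud_stats")
}

#' Ionic-lock occupancy of a minimum-distance series
#'
#' The salt bridge is "intact" in frames whose minimum donor-acceptor
#' heavy-atom distance is below `threshold` (5 Angstrom by default).
#' Contiguous intact/broken segments and, optionally, a normalized 2-D
#' histogram against a companion coordinate are returned.
#'
#' @param d_min per-frame minimum distance, Angstrom.
#' @param threshold intact/broken threshold, Angstrom.
#' @param t_ns optional frame times for segment durations.
#' @param companion optional second coordinate (same length) for a 2-D
#'   probability histogram.
#' @param nbins bins per axis of the 2-D histogram.
#' @return list: `fraction_intact`, `segments` (data.frame with `intact`,
#'   `length`, and `duration_ns` when times are given), `hist2d`
#'   (normalized matrix or NULL).
#' @export
ionic_lock_fraction <- function(d_min, threshold = 5, t_ns = NULL,
                                companion = NULL, nbins = 30) {
  stopifnot(all(d_min > 0))
  intact <- d_min < threshold
  r <- rle(intact)
  segments <- data.frame(intact = r$values, length = r$lengths)
  if (!is.null(t_ns) && length(t_ns) >= 2)
    segments$duration_ns <- r$lengths * (t_ns[2] - t_ns[1])
  h2 <- NULL
  if (!is.null(companion)) {
    stopifnot(length(companion) == length(d_min))
    bx <- seq(min(d_min), max(d_min), length.out = nbins + 1)
    by <- seq(min(companion), max(companion), length.out = nbins + 1)
    ix <- pmin(findInterval(d_min, bx, rightmost.closed = TRUE), nbins)
    iy <- pmin(findInterval(companion, by, rightmost.closed = TRUE), nbins)
    h2 <- table(factor(ix, levels = 1:nbins), factor(iy, levels = 1:nbins))
    h2 <- unclass(h2 / sum(h2))
    attr(h2, "x_breaks") <- bx
    attr(h2, "y_breaks") <- by
  }
  list(fraction_intact = mean(intact), segments = segments, hist2d = h2)
}

#' Normalized distance probability distribution
#'
#' Pools one or more distance series into a probability histogram
#' (masses sum to 1), with the quenching-cutoff position attached for
#' plotting.
#'
#' @param series_list a distance series data.frame or list of them.
#' @param breaks histogram breaks (nm) or a bin count.
#' @param d_q optional cutoff marker, nm.
#' @return data.frame with `mid_nm` and `prob`; attribute `d_q`.
#' @export
distance_histogram <- function(series_list, breaks = 50, d_q = NULL) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  d <- unlist(lapply(series_list, function(s) s$d_nm))
  if (length(d) < 100) stop("need at least 100 distance samples")
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  out <- data.frame(mid_nm = h$mids, prob = h$counts / sum(h$counts))
  attr(out, "d_q") <- d_q
  out
}
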