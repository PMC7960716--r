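#' Read a photon stream table
#'
#' Expects columns `timestamp_ns`, `excitation` and `emission` (each
#' "D" or "A"); timestamps must be sorted ascending.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [detect_bursts()].
#' @export
read_photon_stream <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ns", "excitation", "emission")
  if (!all(need %in% names(x)))
    stop("photon stream must have columns: ", paste(need, collapse = ", "))
  stop_if_not_sorted(x$timestamp_ns, "photon timestamps")
  x
}

#' Write / read a burst table
#'
#' @param bursts burst table data.frame.
#' @param path CSV file path.
#' @return `read_burst_table` returns the data.frame.
#' @export
write_burst_table <- function(bursts, path) {
  utils::write.csv(bursts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_burst_table
#' @export
read_burst_table <- function(path) utils::read.csv(path)

#' Write / read an FCS correlation curve
#'
#' Columns `lag_us`, `G`, `sem`.
#'
#' @param curve correlation curve data.frame.
#' @param path CSV file path.
#' @export
write_fcs_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fcs_curve
#' @export
read_fcs_curve <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("lag_us", "G") %in% names(x)))
    stop("FCS curve must have columns lag_us and G")
  if (any(x$lag_us <= 0) || is.unsorted(x$lag_us, strictly = TRUE))
    stop("lags must be strictly increasing and positive")
  class(x) <- c("fcs_curve", "data.frame")
  x
}

#' Write / read a decay histogram
#'
#' Two-column (`bin_ns`, `counts`) or polarized three-column
#' (`bin_ns`, `counts_par`, `counts_perp`) CSV.
#'
#' @param decay decay histogram data.frame.
#' @param path CSV file path.
#' @export
write_decay <- function(decay, path) {
  utils::write.csv(decay, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  x <- utils::read.csv(path)
  if (!("bin_ns" %in% names(x)))
    stop("decay histogram must have a bin_ns column")
  x
}

#' Write / read a distance series (TSV)
#'
#' Columns `t_ns`, `d_nm`, optionally `residue` and `replicate`.
#'
#' @param series distance series data.frame.
#' @param path TSV file path.
#' @export
write_distance_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_series
#' @export
read_distance_series <- function(path) {
  x <- utils::read.delim(path)
  if (!all(c("t_ns", "d_nm") %in% names(x)))
    stop("distance series must have columns t_ns and d_nm")
  x
}
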