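## Signal conditioning for stance-phase trials: zero-lag low-pass filtering,
## 30 N stance event detection on the vertical GRF, and time-normalization of
## every channel to 101 nodes (0-100% of stance).

#' Zero-lag low-pass Butterworth filter
#'
#' Dual-pass (forward-backward) Butterworth low-pass filter. The
#' conventional biomechanics reading of a "fourth-order, zero-lag" filter is
#' a 2nd-order design applied twice (effective 4th order, `order = 2`, the
#' default); `order = 4` gives the stricter 4th-order dual-pass (8th-order
#' effective) variant. The dual pass cancels phase lag exactly and squares
#' the single-pass magnitude response, so the gain at the cutoff frequency
#' is 1/2.
#'
#' Edges are padded by odd (point) reflection before filtering and each pass
#' starts at the DC steady state of its first sample, so a constant series
#' passes through unchanged; the pad length is `3 * order` samples or eight
#' cutoff periods, whichever is longer (capped at the series length minus
#' one), which keeps endpoint transients negligible on short stance windows.
#'
#' @param series numeric vector.
#' @param rate sampling rate, Hz.
#' @param cutoff_hz low-pass cutoff, Hz; must be below the Nyquist rate.
#' @param order single-pass filter order (2 or 4).
#' @return filtered series, same length as the input.
#' @export
butterworth_zero_lag <- function(series, rate, cutoff_hz, order = 2) {
  if (!is.numeric(series)) stop("series must be numeric", call. = FALSE)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  if (rate <= 0) stop_config("rate", "must be > 0")
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop_config("cutoff_hz", "must lie in (0, rate/2)")
  n <- length(series)
  if (n <= 3 * order) stop("series too short for the filter order", call. = FALSE)
  ## cutoff pre-warp for the dual pass is deliberately omitted: the stated
  ## contract is gain 1/2 at the nominal cutoff, which the squared response
  ## of a Butterworth at its own cutoff satisfies by construction.
  filt <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  pad <- min(n - 1, max(3L * order, ceiling(8 * rate / cutoff_hz)))
  front <- 2 * series[1] - series[(pad + 1):2]
  back <- 2 * series[n] - series[(n - 1):(n - pad)]
  x <- c(front, series, back)
  y <- iir_dc_init(filt$b, filt$a, x)
  y <- rev(iir_dc_init(filt$b, filt$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

## One IIR pass initialized at the DC steady state of the first sample, so a
## constant series passes through with no start-up transient at all.
iir_dc_init <- function(b, a, x) {
  nb <- length(b)
  xx <- c(rep(x[1], nb - 1), x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xx)]
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(x[1], length(a) - 1))
  as.numeric(y)
}

#' Detect stance phases from the vertical ground reaction force
#'
#' Heel strike is the first sample at or above the force threshold after a
#' below-threshold run; toe off is the last sample at or above the threshold
#' before the next below-threshold run (30 N by convention). A hysteresis
#' rejects force-plate chatter: above-threshold runs shorter than
#' `min_stance_s` are discarded, and below-threshold gaps shorter than
#' `min_flight_s` are bridged (a gap touching the series boundary is always
#' treated as genuine flight).
#'
#' @param grf_v vertical GRF, N (raw or filtered; see Details of
#'   [run_pipeline()] for the pipeline default).
#' @param rate sampling rate, Hz.
#' @param threshold_n force threshold, N.
#' @param min_stance_s,min_flight_s hysteresis durations, s.
#' @return data.frame with one row per stance: `heel_strike`, `toe_off`
#'   (1-based sample indices) and `duration_s`. Zero rows when no stance is
#'   found.
#' @export
detect_stance <- function(grf_v, rate, threshold_n = 30,
                          min_stance_s = 0.010, min_flight_s = 0.050) {
  if (anyNA(grf_v) || any(!is.finite(grf_v)))
    stop("grf_v contains missing or non-finite values", call. = FALSE)
  if (rate <= 0) stop_config("rate", "must be > 0")
  above <- grf_v >= threshold_n
  empty <- data.frame(heel_strike = integer(), toe_off = integer(),
                      duration_s = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## bridge short interior below-threshold gaps (chatter within stance)
  min_flight <- max(1L, ceiling(min_flight_s * rate))
  interior <- which(!r$values & starts > 1L & ends < length(grf_v))
  r$values[interior[r$lengths[interior] < min_flight]] <- TRUE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## drop above-threshold blips shorter than the minimum stance
  min_stance <- max(1L, ceiling(min_stance_s * rate))
  keep <- which(r$values & r$lengths >= min_stance)
  if (!length(keep)) return(empty)
  data.frame(heel_strike = starts[keep], toe_off = ends[keep],
             duration_s = (ends[keep] - starts[keep]) / rate)
}

#' Time-normalize a series to the stance phase
#'
#' Linear interpolation of one channel onto `n_nodes` equally spaced points
#' spanning heel strike to toe off (node 0 = heel strike, node
#' `n_nodes - 1` = toe off). The window may be given in sample indices of
#' this series or in seconds on its own clock (sample `i` sits at time
#' `(i - 1) / rate`), which lets a window detected on the force-plate clock
#' be applied to a kinematic channel sampled at a different rate.
#'
#' @param series numeric vector.
#' @param window length-2 numeric: `c(heel_strike, toe_off)`.
#' @param rate sampling rate of `series`, Hz.
#' @param n_nodes number of output nodes (101 = percent of stance).
#' @param units `"samples"` (1-based indices, default) or `"seconds"`.
#' @return numeric vector of length `n_nodes`.
#' @export
normalize_to_stance <- function(series, window, rate, n_nodes = 101,
                                units = c("samples", "seconds")) {
  units <- match.arg(units)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(heel_strike, toe_off) with toe_off > heel_strike",
         call. = FALSE)
  n <- length(series)
  x <- if (units == "samples") window else window * rate + 1
  if (x[1] < 1 - 1e-9 || x[2] > n + 1e-9)
    stop("window lies outside the series", call. = FALSE)
  if (x[2] - x[1] < 1)
    stop("window shorter than 2 samples", call. = FALSE)
  xout <- seq(x[1], x[2], length.out = n_nodes)
  stats::approx(seq_len(n), series, xout = pmin(pmax(xout, 1), n))$y
}
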