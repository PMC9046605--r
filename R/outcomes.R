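## Discrete biomechanical risk factors for running-related injury, extracted
## from 101-node normalized kinematic trajectories and raw-time GRF series:
## MLA range of motion, rearfoot (shank-calcaneus) frontal peaks, vertical
## impact peak, vertical average loading rate (VALR), and peak braking force.

#' Medial longitudinal arch range of motion
#'
#' `max - min` of the arch-angle trajectory over stance, degrees.
#'
#' @param mla_trajectory numeric trajectory (conventionally 101 nodes).
#' @return ROM in degrees (>= 0).
#' @export
mla_rom <- function(mla_trajectory) {
  if (anyNA(mla_trajectory) || any(!is.finite(mla_trajectory)))
    stop("trajectory contains missing or non-finite nodes", call. = FALSE)
  max(mla_trajectory) - min(mla_trajectory)
}

#' Rearfoot frontal-plane peaks
#'
#' Inversion and eversion peaks of the shank-calcaneus frontal angle:
#' inversion peak = minimum (most negative), eversion peak = maximum.
#'
#' @param shacal_frontal_trajectory numeric trajectory, degrees (eversion
#'   positive, inversion negative).
#' @return named vector `c(inv_peak, eve_peak)`.
#' @export
rearfoot_peaks <- function(shacal_frontal_trajectory) {
  if (anyNA(shacal_frontal_trajectory) || any(!is.finite(shacal_frontal_trajectory)))
    stop("trajectory contains missing or non-finite nodes", call. = FALSE)
  c(inv_peak = min(shacal_frontal_trajectory),
    eve_peak = max(shacal_frontal_trajectory))
}

## First local maximum of the vertical GRF within the early-stance search
## region. Plateau-aware: the first sample that is >= both neighbours and
## strictly above at least one of them counts, so an exactly flat peak is
## found at its first sample.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[x[i] >= x[i - 1] & x[i] >= x[i + 1] & (x[i] > x[i - 1] | x[i] > x[i + 1])]
}

#' Vertical impact peak
#'
#' Local maximum of the vertical GRF at initial contact, in body weights.
#' The first local maximum within the early-stance search window (first
#' `search_frac` of stance after heel strike) is taken as the impact
#' transient. Runners without a detectable transient (e.g. forefoot
#' strikers) yield `NA` with attribute `missing = TRUE`.
#'
#' @param grf_v_raw_time vertical GRF on its native time base, N.
#' @param window stance window: `c(heel_strike, toe_off)` sample indices (or
#'   a row of [detect_stance()] output).
#' @param body_weight_n body weight, N (> 0).
#' @param search_frac early-stance search region as a fraction of stance.
#' @return impact peak in BW, with attribute `index` (sample index of the
#'   peak); `NA` + attribute `missing` when no early transient exists.
#' @export
impact_peak <- function(grf_v_raw_time, window, body_weight_n,
                        search_frac = 0.30) {
  w <- as_window(window)
  if (body_weight_n <= 0) stop_config("body_weight_n", "must be > 0")
  seg <- grf_v_raw_time[w[1]:w[2]]
  if (anyNA(seg)) stop("GRF contains missing values in stance", call. = FALSE)
  lm_all <- find_local_maxima(seg)
  if (!length(lm_all))
    stop("no local maximum anywhere in stance", call. = FALSE)
  lim <- 1 + search_frac * (length(seg) - 1)
  lm_early <- lm_all[lm_all <= lim]
  if (!length(lm_early)) {
    out <- NA_real_
    attr(out, "missing") <- TRUE
    return(out)
  }
  idx <- lm_early[1]
  out <- seg[idx] / body_weight_n
  attr(out, "index") <- w[1] + idx - 1L
  out
}

#' Vertical average loading rate (VALR)
#'
#' Average slope of the vertical GRF between 20% and 80% of the interval
#' from foot contact to the first (impact) peak, divided by body weight.
#' The default is the secant through the 20% and 80% points (values taken
#' by linear interpolation of the sampled force); `method = "regression"`
#' fits a least-squares line to all samples in the interval instead.
#'
#' @inheritParams impact_peak
#' @param rate sampling rate of the GRF, Hz.
#' @param method `"secant"` (default) or `"regression"`.
#' @return loading rate in BW/s; `NA` + attribute `missing` when the impact
#'   transient is absent.
#' @export
valr <- function(grf_v_raw_time, window, body_weight_n, rate,
                 search_frac = 0.30, method = c("secant", "regression")) {
  method <- match.arg(method)
  w <- as_window(window)
  pk <- impact_peak(grf_v_raw_time, w, body_weight_n, search_frac)
  if (is.na(pk)) return(pk)
  t0 <- (w[1] - 1) / rate
  tp <- (attr(pk, "index") - 1) / rate
  delta <- tp - t0
  if (delta * rate < 5)
    stop("contact-to-peak interval under 5 samples: insufficient resolution for VALR",
         call. = FALSE)
  times <- (seq_along(grf_v_raw_time) - 1) / rate
  if (method == "secant") {
    f <- stats::approx(times, grf_v_raw_time,
                       xout = t0 + c(0.2, 0.8) * delta)$y
    (f[2] - f[1]) / (0.6 * delta) / body_weight_n
  } else {
    lo <- t0 + 0.2 * delta; hi <- t0 + 0.8 * delta
    sel <- which(times >= lo & times <= hi)
    x <- c(lo, times[sel], hi)
    y <- c(stats::approx(times, grf_v_raw_time, lo)$y,
           grf_v_raw_time[sel],
           stats::approx(times, grf_v_raw_time, hi)$y)
    unname(stats::coef(stats::lm(y ~ x))[2]) / body_weight_n
  }
}

#' Peak braking force
#'
#' Most negative anterior-posterior GRF within stance (maximum posterior
#' force), in body weights; returned negative. If the series follows a
#' posterior-positive convention, set `posterior_negative = FALSE` and the
#' maximum is taken and returned with a negative sign.
#'
#' @param grf_ap_raw_time anterior-posterior GRF on its native time base, N.
#' @inheritParams impact_peak
#' @param posterior_negative sign convention of the input.
#' @return peak braking force in BW (<= 0 in normal data).
#' @export
peak_braking <- function(grf_ap_raw_time, window, body_weight_n,
                         posterior_negative = TRUE) {
  w <- as_window(window)
  if (body_weight_n <= 0) stop_config("body_weight_n", "must be > 0")
  seg <- grf_ap_raw_time[w[1]:w[2]]
  if (anyNA(seg)) stop("GRF contains missing values in stance", call. = FALSE)
  if (!posterior_negative) return(-max(seg) / body_weight_n)
  if (all(seg > 0))
    warning("anterior-posterior trace has no posterior (negative) phase",
            call. = FALSE)
  min(seg) / body_weight_n
}

as_window <- function(window) {
  if (is.data.frame(window)) window <- c(window$heel_strike[1], window$toe_off[1])
  window <- as.integer(window[1:2])
  if (anyNA(window) || window[2] <= window[1])
    stop("invalid stance window", call. = FALSE)
  window
}
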