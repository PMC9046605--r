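## Synthetic stance-phase ground reaction forces with analytically plantable
## discrete parameters. The vertical waveform is piecewise: a linear rise at
## exactly the planted loading rate up to the impact-transient peak, a short
## plateau at the exact peak value (so the sampled maximum equals the planted
## peak at any sampling rate), a smooth dip, a half-cosine rise to the active
## peak, and a half-cosine decay to zero at toe off. The anterior-posterior
## waveform is a braking bump (with a plateau at the planted minimum) followed
## by a propulsive bump.

#' Synthesize a stance-phase GRF pair
#'
#' Builds vertical and anterior-posterior ground-reaction-force series whose
#' discrete risk factors are exactly the planted values: the first local
#' maximum of the vertical force equals `impact_peak_bw * BW`; the secant
#' slope between any two points of the rise to that peak (hence the 20-80%
#' average loading rate) equals `valr_bw_s * BW`; and the minimum of the
#' anterior-posterior force equals `braking_peak_bw * BW` (posterior
#' negative). `BW = body_mass * 9.80665` N.
#'
#' @param stance_duration_s stance duration, s.
#' @param body_mass body mass, kg.
#' @param impact_peak_bw vertical impact-transient peak, BW (> 0).
#' @param active_peak_bw vertical active peak, BW (> `impact_peak_bw`).
#' @param valr_bw_s vertical average loading rate, BW/s (> 0).
#' @param braking_peak_bw peak braking (posterior) force, BW (<= 0).
#' @param rate sampling rate, Hz.
#' @param propulsive_peak_bw anterior propulsive peak, BW.
#' @param active_peak_frac stance fraction of the active peak.
#' @param noise_sd_n additive white measurement noise, N.
#' @return list with `grf_v`, `grf_ap` (N), `rate`, `duration_s`, and
#'   `events` = true 1-based indices of the 30 N up/down crossings.
#' @export
synth_grf <- function(stance_duration_s, body_mass, impact_peak_bw,
                      active_peak_bw, valr_bw_s, braking_peak_bw, rate,
                      propulsive_peak_bw = 0.22, active_peak_frac = 0.45,
                      noise_sd_n = 0) {
  if (impact_peak_bw <= 0) stop_config("impact_peak_bw", "must be > 0")
  if (active_peak_bw <= impact_peak_bw)
    stop("unreachable constraints: impact peak must precede and stay below the active peak",
         call. = FALSE)
  if (valr_bw_s <= 0) stop_config("valr_bw_s", "must be > 0")
  if (braking_peak_bw > 0) stop_config("braking_peak_bw", "must be <= 0")
  if (rate <= 0) stop_config("rate", "must be > 0")
  if (stance_duration_s <= 0) stop_config("stance_duration_s", "must be > 0")

  bw <- body_mass * GRAVITY
  T <- stance_duration_s
  f_imp <- impact_peak_bw * bw
  f_act <- active_peak_bw * bw
  slope <- valr_bw_s * bw
  t1 <- f_imp / slope                       # impact-peak time
  t_pl <- 2.5 / rate                        # plateau: guarantees >= 2 samples
  t_act <- active_peak_frac * T
  if (t1 < 4.5 / rate)
    stop("unreachable constraints: loading rate too high for the sampling rate (impact rise under 5 samples)",
         call. = FALSE)
  if (t1 + t_pl >= 0.30 * T)
    stop("unreachable constraints: impact transient would fall outside early stance (loading rate too low)",
         call. = FALSE)
  if (0.8 * f_imp <= 30)
    stop("unreachable constraints: impact peak too small relative to the 30 N event threshold",
         call. = FALSE)

  n <- round(T * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  f_dip <- 0.8 * f_imp
  t2 <- t1 + t_pl                           # plateau end
  t_mid <- (t2 + t_act) / 2                 # dip bottom

  grf_v <- numeric(n)
  a <- t <= t1
  grf_v[a] <- slope * t[a]
  b <- t > t1 & t <= t2
  grf_v[b] <- f_imp
  c_ <- t > t2 & t <= t_mid
  grf_v[c_] <- f_dip + (f_imp - f_dip) * (1 + cos(pi * (t[c_] - t2) / (t_mid - t2))) / 2
  d <- t > t_mid & t <= t_act
  grf_v[d] <- f_dip + (f_act - f_dip) * (1 - cos(pi * (t[d] - t_mid) / (t_act - t_mid))) / 2
  e <- t > t_act
  grf_v[e] <- f_act * (1 + cos(pi * (t[e] - t_act) / (T - t_act))) / 2

  ## anterior-posterior: braking bump with an exact-minimum plateau, then a
  ## propulsive bump; posterior negative.
  f_brk <- braking_peak_bw * bw
  f_prop <- propulsive_peak_bw * bw
  tb0 <- 0.04 * T; tb1 <- 0.22 * T; tb2 <- tb1 + t_pl; tb3 <- 0.48 * T
  grf_ap <- numeric(n)
  s1 <- t > tb0 & t <= tb1
  grf_ap[s1] <- f_brk * (1 - cos(pi * (t[s1] - tb0) / (tb1 - tb0))) / 2
  s2 <- t > tb1 & t <= tb2
  grf_ap[s2] <- f_brk
  s3 <- t > tb2 & t <= tb3
  grf_ap[s3] <- f_brk * (1 + cos(pi * (t[s3] - tb2) / (tb3 - tb2))) / 2
  tp0 <- 0.52 * T; tp1 <- 0.98 * T
  s4 <- t > tp0 & t <= tp1
  grf_ap[s4] <- f_prop * (1 - cos(2 * pi * (t[s4] - tp0) / (tp1 - tp0))) / 2

  above <- which(grf_v >= 30)   # true events, from the noiseless waveform
  if (noise_sd_n > 0) {
    grf_v <- grf_v + stats::rnorm(n, 0, noise_sd_n)
    grf_ap <- grf_ap + stats::rnorm(n, 0, noise_sd_n)
  }
  list(grf_v = grf_v, grf_ap = grf_ap, rate = rate, duration_s = T,
       events = c(heel_strike = above[1], toe_off = above[length(above)]))
}
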