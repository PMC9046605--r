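## Synthetic multi-segment foot kinematics. Joint angle "programs" (functions
## of stance fraction, degrees) are turned into segment pose trajectories by
## composing rotations in the exact inverse order of the Joint Coordinate
## System decomposition, which makes the synthesis/decomposition round trip an
## identity. Marker clouds are rigidly attached to the segments; a separate
## arch triad (heel / apex / first-metatarsal-head) is driven directly by the
## medial-longitudinal-arch program so the planted arch angle is recovered
## exactly by the apex-angle definition.

#' Piecewise-linear trapezoid angle program
#'
#' Program equal to `end_value` on the plateaus near heel strike and toe off
#' and `mid_value` on the mid-stance plateau, with linear ramps in between.
#' Because the extreme values sit on plateaus, the extrema survive sampling
#' and 101-node linear re-interpolation exactly - the backbone of planted
#' peak/range outcomes.
#'
#' @param end_value,mid_value program values (degrees) at the stance ends
#'   and at mid stance.
#' @param edges four stance fractions: end-plateau end, mid-plateau start,
#'   mid-plateau end, end-plateau start.
#' @return function of stance fraction in `[0, 1]`, vectorized.
#' @export
program_trapezoid <- function(end_value, mid_value,
                              edges = c(0.10, 0.42, 0.58, 0.90)) {
  force(end_value); force(mid_value); force(edges)
  function(tau) {
    w <- numeric(length(tau))
    up <- tau > edges[1] & tau < edges[2]
    w[up] <- (tau[up] - edges[1]) / (edges[2] - edges[1])
    w[tau >= edges[2] & tau <= edges[3]] <- 1
    dn <- tau > edges[3] & tau < edges[4]
    w[dn] <- (edges[4] - tau[dn]) / (edges[4] - edges[3])
    end_value + (mid_value - end_value) * w
  }
}

#' Constant angle program
#' @param value program value, degrees.
#' @return function of stance fraction.
#' @export
program_constant <- function(value) {
  force(value)
  function(tau) rep(value, length(tau))
}

#' Smooth low-order Fourier perturbation program
#'
#' Mean-zero sum of the first `k` sine harmonics with random amplitudes
#' `N(0, sd/harmonic)` and phases; used for between-trial trajectory
#' variation with the smoothness 1D random-field inference assumes.
#'
#' @param sd amplitude scale, degrees; `0` gives the zero program.
#' @param k number of harmonics.
#' @return function of stance fraction.
#' @export
program_fourier <- function(sd, k = 3) {
  if (sd <= 0) return(program_constant(0))
  a <- stats::rnorm(k, 0, sd / seq_len(k))
  ph <- stats::runif(k, 0, 2 * pi)
  function(tau) {
    out <- numeric(length(tau))
    for (j in seq_len(k)) out <- out + a[j] * sin(2 * pi * j * tau + ph[j])
    out
  }
}

sum_programs <- function(...) {
  fns <- list(...)
  function(tau) Reduce(`+`, lapply(fns, function(f) f(tau)))
}

## Rigid local marker coordinates (mm) per segment, y up, x anterior.
segment_marker_local <- function() {
  list(
    calcaneus = list(heel = c(-30, -20, 0), sustentaculum = c(20, -5, -15)),
    metatarsus = list(met1_base = c(0, -5, -20), met1_head = c(60, -15, -22),
                      met2_base = c(5, -4, 0), met2_head = c(65, -16, -2),
                      met5_base = c(0, -8, 25), met5_head = c(55, -18, 27)),
    hallux = list(hallux = c(30, -5, -20))
  )
}

segment_origin_local <- function() {
  list(shank = c(0, 120, 0), calcaneus = c(0, 30, 0),
       midfoot = c(45, 25, 0), metatarsus = c(80, 20, 0),
       hallux = c(150, 12, -18))
}

#' Synthesize segment pose and marker trajectories from angle programs
#'
#' Builds the shank-calcaneus-midfoot-metatarsus-hallux pose chain whose
#' JCS decomposition reproduces the prescribed joint programs exactly, plus
#' rigidly attached markers and the arch triad driven by the `mla` program.
#'
#' @param angle_programs named list with elements `sha_cal`, `cal_mid`,
#'   `mid_met`, `met_hal` (each a list of `sagittal`, `frontal`,
#'   `transverse` programs) and `mla` (a single program of the arch angle in
#'   degrees, within (90, 180)).
#' @param rate kinematic sampling rate, Hz.
#' @param duration stance duration, s.
#' @param noise_sd_marker iid marker noise, mm.
#' @param arch_length heel-to-metatarsal-head arch base length, mm.
#' @return list with `poses` (named list of `3 x 3 x n` arrays per segment),
#'   `markers` (named list of `3 x n` world-coordinate matrices, mm),
#'   `times` (s) and `tau` (stance fraction).
#' @export
synth_segment_poses <- function(angle_programs, rate, duration,
                                noise_sd_marker = 0, arch_length = 150) {
  joints <- c("sha_cal", "cal_mid", "mid_met", "met_hal")
  if (!all(c(joints, "mla") %in% names(angle_programs)))
    stop_config("angle_programs",
                paste("needs programs:", paste(c(joints, "mla"), collapse = ", ")))
  n <- round(duration * rate) + 1L
  times <- (seq_len(n) - 1) / rate
  tau <- times / duration

  ang <- lapply(angle_programs[joints], function(pr) {
    cbind(sagittal = pr$sagittal(tau), frontal = pr$frontal(tau),
          transverse = pr$transverse(tau))
  })
  for (j in joints) {
    if (any(abs(ang[[j]][, "frontal"]) >= 90))
      stop(sprintf("gimbal proximity in joint '%s': |frontal| >= 90 degrees", j),
           call. = FALSE)
    if (any(abs(ang[[j]]) >= 90))
      warning(sprintf("joint '%s' program exceeds 90 degrees", j), call. = FALSE)
  }

  segs <- c("shank", "calcaneus", "midfoot", "metatarsus", "hallux")
  poses <- lapply(segs, function(s) array(0, c(3, 3, n)))
  names(poses) <- segs
  for (i in seq_len(n)) {
    R_sh <- diag(3)
    R_ca <- R_sh %*% jcs_compose(ang$sha_cal[i, 1], ang$sha_cal[i, 2], ang$sha_cal[i, 3])
    R_mi <- R_ca %*% jcs_compose(ang$cal_mid[i, 1], ang$cal_mid[i, 2], ang$cal_mid[i, 3])
    R_me <- R_mi %*% jcs_compose(ang$mid_met[i, 1], ang$mid_met[i, 2], ang$mid_met[i, 3])
    R_ha <- R_me %*% jcs_compose(ang$met_hal[i, 1], ang$met_hal[i, 2], ang$met_hal[i, 3])
    poses$shank[, , i] <- R_sh; poses$calcaneus[, , i] <- R_ca
    poses$midfoot[, , i] <- R_mi; poses$metatarsus[, , i] <- R_me
    poses$hallux[, , i] <- R_ha
  }

  origins <- segment_origin_local()
  locals <- segment_marker_local()
  markers <- list()
  for (s in names(locals)) {
    for (m in names(locals[[s]])) {
      loc <- locals[[s]][[m]]
      world <- matrix(0, 3, n)
      for (i in seq_len(n)) world[, i] <- origins[[s]] + poses[[s]][, , i] %*% loc
      markers[[m]] <- world
    }
  }

  ## arch triad: apex height follows the planted arch-angle program exactly
  mla_deg <- angle_programs$mla(tau)
  if (any(mla_deg <= 90 | mla_deg >= 180))
    stop_config("angle_programs$mla", "arch angle must stay inside (90, 180) degrees")
  h <- (arch_length / 2) / tan(deg2rad(mla_deg) / 2)
  markers$arch_heel <- rbind(rep(0, n), rep(0, n), rep(0, n))
  markers$arch_apex <- rbind(rep(arch_length / 2, n), h, rep(0, n))
  markers$arch_head <- rbind(rep(arch_length, n), rep(0, n), rep(0, n))

  if (noise_sd_marker > 0)
    markers <- lapply(markers, function(w)
      w + matrix(stats::rnorm(length(w), 0, noise_sd_marker), nrow = 3))

  list(poses = poses, markers = markers, times = times, tau = tau)
}
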