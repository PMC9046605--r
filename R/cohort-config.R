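## Cohort configuration for the synthetic-gait generator. Defaults reproduce
## the trial conditions the pipeline is meant to analyze: a two-arm cohort
## (41 intervention / 46 control), two assessment times, kinematics at 200 Hz,
## force plates at 1,000 Hz, body mass ~ normal(70.5, 13.1) kg truncated at
## +/-3 sd, and a per-outcome effect table of group-by-time cell means (sd).

#' Default group-by-time effect table
#'
#' Cell means and standard deviations for the six discrete risk factors, one
#' row per outcome, columns `ig_pre/ig_post/cg_pre/cg_post` (means) and
#' `*_sd` (cell standard deviations). Units: degrees for the angle outcomes,
#' BW for forces, BW/s for the loading rate.
#'
#' @return data.frame with row names `mla_rom`, `shacal_inv_peak`,
#'   `shacal_eve_peak`, `vertical_impact_peak`, `valr`, `peak_braking_force`.
#' @export
default_effect_table <- function() {
  tab <- data.frame(
    ig_pre  = c(6.16, -0.56, 6.72, 1.13, 75.19, -0.24),
    ig_sd_pre  = c(8.14, 7.42, 3.29, 0.39, 46.43, 0.05),
    ig_post = c(0.17, -5.74, 5.90, 1.14, 77.17, -0.24),
    ig_sd_post = c(6.86, 6.31, 2.95, 0.55, 57.52, 0.07),
    cg_pre  = c(3.59, -3.30, 6.89, 1.21, 73.48, -0.24),
    cg_sd_pre  = c(7.89, 8.71, 2.35, 0.44, 43.17, 0.05),
    cg_post = c(2.88, -3.51, 6.39, 1.09, 72.84, -0.24),
    cg_sd_post = c(5.36, 5.70, 1.88, 0.58, 65.73, 0.05),
    row.names = c("mla_rom", "shacal_inv_peak", "shacal_eve_peak",
                  "vertical_impact_peak", "valr", "peak_braking_force")
  )
  tab
}

#' Configure a synthetic cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' are the study conditions the pipeline targets; `sd_scale = 0` gives the
#' fully deterministic (zero-noise) degenerate cohort in which every planted
#' outcome equals its cell mean exactly, and `null_effects = TRUE` equalizes
#' all four cells of every outcome (no group, time, or interaction effect)
#' while keeping the noise structure.
#'
#' @param n_per_group subjects per arm; scalar or named `c(IG=, CG=)`.
#' @param seed integer seed; the same seed and configuration give a
#'   bit-identical cohort.
#' @param times labels of the two assessments.
#' @param effect_table per-outcome cell means/sds, see
#'   [default_effect_table()].
#' @param between_subject_sd named vector of between-subject random-intercept
#'   sds per outcome (same units as the outcome), or `NULL` to use half of
#'   each outcome's smallest cell variance.
#' @param noise_sd_marker marker measurement noise, mm.
#' @param noise_sd_angle smooth per-trial angle-trajectory perturbation, deg.
#' @param noise_sd_grf force-plate noise on the synthesized GRF, N.
#' @param between_subject_angle_sd between-subject offset of the non-planted
#'   angle channels, deg.
#' @param stance_duration_s mean stance duration, s.
#' @param stance_sd_s between-trial stance-duration jitter, s.
#' @param kin_rate,grf_rate sampling rates, Hz (kinematics / force plates).
#' @param body_mass_kg `c(mean, sd)` of the truncated-normal body mass, kg.
#' @param active_peak_bw vertical active (propulsive) peak, BW.
#' @param sd_scale common multiplier on every sd in the configuration.
#' @param null_effects logical; plant no group-by-time effects.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(IG = 41L, CG = 46L),
                          seed = 1L,
                          times = c("baseline", "week8"),
                          effect_table = default_effect_table(),
                          between_subject_sd = NULL,
                          noise_sd_marker = 0.5,
                          noise_sd_angle = 0.5,
                          noise_sd_grf = 1.0,
                          between_subject_angle_sd = 2.0,
                          stance_duration_s = 0.25,
                          stance_sd_s = 0.015,
                          kin_rate = 200,
                          grf_rate = 1000,
                          body_mass_kg = c(mean = 70.5, sd = 13.1),
                          active_peak_bw = 2.4,
                          sd_scale = 1,
                          null_effects = FALSE) {
  if (length(n_per_group) == 1) n_per_group <- c(IG = n_per_group, CG = n_per_group)
  n_per_group <- stats::setNames(as.integer(round(n_per_group)),
                                 names(n_per_group))
  if (!all(c("IG", "CG") %in% names(n_per_group)))
    stop_config("n_per_group", "must be named c(IG = , CG = )")
  if (any(is.na(n_per_group)) || any(n_per_group < 2))
    stop_config("n_per_group", "each arm needs at least 2 subjects")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")
  if (length(times) != 2) stop_config("times", "exactly two assessment labels")
  if (kin_rate <= 0) stop_config("kin_rate", "must be > 0")
  if (grf_rate <= 0) stop_config("grf_rate", "must be > 0")
  if (grf_rate %% kin_rate != 0)
    stop_config("grf_rate", "must be an integer multiple of kin_rate")
  if (stance_duration_s <= 0) stop_config("stance_duration_s", "must be > 0")
  if (stance_sd_s < 0) stop_config("stance_sd_s", "must be >= 0")
  if (noise_sd_marker < 0) stop_config("noise_sd_marker", "must be >= 0")
  if (noise_sd_angle < 0) stop_config("noise_sd_angle", "must be >= 0")
  if (noise_sd_grf < 0) stop_config("noise_sd_grf", "must be >= 0")
  if (sd_scale < 0) stop_config("sd_scale", "must be >= 0")
  if (body_mass_kg[1] <= 0 || body_mass_kg[2] < 0)
    stop_config("body_mass_kg", "mean must be > 0 and sd >= 0")
  need <- c("ig_pre", "ig_sd_pre", "ig_post", "ig_sd_post",
            "cg_pre", "cg_sd_pre", "cg_post", "cg_sd_post")
  if (!all(need %in% names(effect_table)))
    stop_config("effect_table", paste("missing columns:",
                paste(setdiff(need, names(effect_table)), collapse = ", ")))
  if (any(as.matrix(effect_table[, grep("_sd_", names(effect_table))]) < 0))
    stop_config("effect_table", "cell sds must be >= 0")
  outcomes <- rownames(effect_table)

  if (null_effects) {
    m <- (effect_table$ig_pre + effect_table$cg_pre) / 2
    effect_table$ig_pre <- effect_table$ig_post <- m
    effect_table$cg_pre <- effect_table$cg_post <- m
  }
  sd_cols <- grep("_sd_", names(effect_table))
  effect_table[, sd_cols] <- effect_table[, sd_cols] * sd_scale

  if (is.null(between_subject_sd)) {
    min_sd <- apply(as.matrix(effect_table[, sd_cols]), 1, min)
    between_subject_sd <- stats::setNames(min_sd * sqrt(0.5), outcomes)
  } else {
    if (!all(outcomes %in% names(between_subject_sd)))
      stop_config("between_subject_sd", "must name every outcome")
    if (any(between_subject_sd < 0))
      stop_config("between_subject_sd", "must be >= 0")
    between_subject_sd <- between_subject_sd[outcomes] * sd_scale
  }

  structure(list(
    n_per_group = n_per_group, seed = as.integer(seed), times = times,
    effect_table = effect_table, between_subject_sd = between_subject_sd,
    noise_sd_marker = noise_sd_marker * sd_scale,
    noise_sd_angle = noise_sd_angle * sd_scale,
    noise_sd_grf = noise_sd_grf * sd_scale,
    between_subject_angle_sd = between_subject_angle_sd * sd_scale,
    stance_duration_s = stance_duration_s,
    stance_sd_s = stance_sd_s * sd_scale,
    kin_rate = kin_rate, grf_rate = grf_rate,
    body_mass_kg = c(mean = unname(body_mass_kg[1]),
                     sd = unname(body_mass_kg[2]) * sd_scale),
    active_peak_bw = active_peak_bw,
    null_effects = null_effects
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  arms: IG n=%d, CG n=%d; times: %s\n",
              x$n_per_group[["IG"]], x$n_per_group[["CG"]],
              paste(x$times, collapse = " / ")))
  cat(sprintf("  rates: kinematics %g Hz, GRF %g Hz; stance %.3f s (sd %.3f)\n",
              x$kin_rate, x$grf_rate, x$stance_duration_s, x$stance_sd_s))
  cat(sprintf("  body mass: %.1f (%.1f) kg; seed %d\n",
              x$body_mass_kg[["mean"]], x$body_mass_kg[["sd"]], x$seed))
  cat("  effect table (cell means):\n")
  print(round(x$effect_table[, c("ig_pre", "ig_post", "cg_pre", "cg_post")], 3))
  invisible(x)
}
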