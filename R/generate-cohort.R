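## Cohort generation: subjects, planted per-trial outcome values, and full
## synthetic recordings (GRF + segment poses + markers). Planted values are
## stored alongside each trial so every downstream stage has ground truth:
## `planted` is the raw statistical draw (cell mean + between-subject effect +
## residual), `realized` is the value the waveforms actually encode after
## folding/ordering/physical-range truncation - at zero noise the two
## coincide with the cell means.

#' Generate a synthetic cohort
#'
#' Draws subjects and per-trial planted outcome values from the configured
#' group-by-time effect table and synthesizes, for every subject and
#' assessment, a stance recording whose discrete risk factors equal the
#' planted (realized) values. Identical configuration and seed give a
#' bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @param trajectories logical; `FALSE` skips waveform/pose synthesis and
#'   returns only subjects and planted truth (fast path for statistical
#'   studies of the generator itself).
#' @return object of class `foot_cohort`: list with `subjects` (data.frame),
#'   `truth` (long data.frame: subject_id, group, time, outcome, planted,
#'   realized), `trials` (list of trial recordings) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), trajectories = TRUE) {
  if (!inherits(config, "cohort_config"))
    stop_config("config", "must be built with cohort_config()")
  with_seed(config$seed, generate_cohort_impl(config, trajectories))
}

generate_cohort_impl <- function(config, trajectories) {
  et <- config$effect_table
  outcomes <- rownames(et)
  n_ig <- config$n_per_group[["IG"]]; n_cg <- config$n_per_group[["CG"]]
  n_sub <- n_ig + n_cg
  groups <- c(rep("IG", n_ig), rep("CG", n_cg))
  ids <- sprintf("S%03d", seq_len(n_sub))

  mass <- rtrunc_norm(n_sub, config$body_mass_kg[["mean"]],
                      config$body_mass_kg[["sd"]], 3)
  subjects <- data.frame(subject_id = ids, group = groups, body_mass_kg = mass)

  ## between-subject random intercepts, one per outcome
  b <- sapply(outcomes, function(o)
    stats::rnorm(n_sub, 0, config$between_subject_sd[[o]]))
  b <- matrix(b, nrow = n_sub, dimnames = list(NULL, outcomes))
  ## between-subject offsets for the non-planted angle channels
  shape_channels <- c("sha_cal.sagittal", "sha_cal.transverse",
                      "cal_mid.sagittal", "cal_mid.frontal", "cal_mid.transverse",
                      "mid_met.sagittal", "mid_met.frontal", "mid_met.transverse",
                      "met_hal.sagittal", "met_hal.frontal", "met_hal.transverse")
  shape_off <- matrix(stats::rnorm(n_sub * length(shape_channels), 0,
                                   config$between_subject_angle_sd),
                      nrow = n_sub, dimnames = list(NULL, shape_channels))

  truth <- list(); trials <- list(); k <- 0L
  for (i in seq_len(n_sub)) {
    for (tm in config$times) {
      k <- k + 1L
      mcol <- if (groups[i] == "IG") {
        if (tm == config$times[1]) "ig_pre" else "ig_post"
      } else {
        if (tm == config$times[1]) "cg_pre" else "cg_post"
      }
      scol <- sub("^(ig|cg)_", "\\1_sd_", mcol)
      cell_sd <- et[[scol]]; names(cell_sd) <- outcomes
      resid_sd <- sqrt(pmax(cell_sd^2 - config$between_subject_sd[outcomes]^2, 0))
      planted <- et[[mcol]] + b[i, outcomes] + stats::rnorm(length(outcomes), 0, resid_sd)
      names(planted) <- outcomes

      ## stance duration, snapped to the kinematic sample grid
      T <- config$stance_duration_s +
        if (config$stance_sd_s > 0) stats::rnorm(1, 0, config$stance_sd_s) else 0
      T <- min(max(T, 0.18), 0.35)
      T <- round(T * config$kin_rate) / config$kin_rate

      realized <- realize_planted(planted, config, T)

      truth[[k]] <- data.frame(subject_id = ids[i], group = groups[i], time = tm,
                               outcome = outcomes,
                               planted = unname(planted[outcomes]),
                               realized = unname(realized$values[outcomes]))

      if (trajectories) {
        trials[[k]] <- build_trial(ids[i], groups[i], tm, mass[i], T,
                                   realized, shape_off[i, ], config)
      }
    }
  }
  structure(list(subjects = subjects,
                 truth = do.call(rbind, truth),
                 trials = trials,
                 config = config),
            class = "foot_cohort")
}

## Fold/order/truncate raw draws into physically realizable planted values.
realize_planted <- function(planted, config, stance_s = config$stance_duration_s) {
  v <- planted
  notes <- character()
  ## arch amplitude: keep the signed draw for the trajectory, magnitude is
  ## what max-min extraction returns
  amp <- min(max(v[["mla_rom"]], -40), 40)
  v[["mla_rom"]] <- abs(amp)
  inv <- min(max(planted[["shacal_inv_peak"]], -55), 55)
  eve <- min(max(planted[["shacal_eve_peak"]], -55), 55)
  v[["shacal_inv_peak"]] <- min(inv, eve)
  v[["shacal_eve_peak"]] <- max(inv, eve)
  act <- config$active_peak_bw
  v[["vertical_impact_peak"]] <- min(max(v[["vertical_impact_peak"]], 0.2), act - 0.2)
  lo <- max(1, v[["vertical_impact_peak"]] / (0.27 * stance_s))
  hi <- v[["vertical_impact_peak"]] * config$grf_rate / 5.5
  v[["valr"]] <- min(max(v[["valr"]], lo), hi)
  v[["peak_braking_force"]] <- min(max(v[["peak_braking_force"]], -2), -0.005)
  list(values = v, mla_amplitude = amp)
}

build_trial <- function(id, group, tm, mass, T, realized, shape_off, config) {
  v <- realized$values
  grf <- synth_grf(T, mass,
                   impact_peak_bw = v[["vertical_impact_peak"]],
                   active_peak_bw = config$active_peak_bw,
                   valr_bw_s = v[["valr"]],
                   braking_peak_bw = v[["peak_braking_force"]],
                   rate = config$grf_rate,
                   noise_sd_n = config$noise_sd_grf)

  wig <- function() program_fourier(config$noise_sd_angle)
  base <- base_angle_programs(shape_off)
  programs <- list(
    sha_cal = list(
      sagittal = sum_programs(base$sha_cal.sagittal, wig()),
      frontal = sum_programs(
        program_trapezoid(v[["shacal_inv_peak"]], v[["shacal_eve_peak"]]), wig()),
      transverse = sum_programs(base$sha_cal.transverse, wig())),
    cal_mid = list(
      sagittal = sum_programs(base$cal_mid.sagittal, wig()),
      frontal = sum_programs(base$cal_mid.frontal, wig()),
      transverse = sum_programs(base$cal_mid.transverse, wig())),
    mid_met = list(
      sagittal = sum_programs(base$mid_met.sagittal, wig()),
      frontal = sum_programs(base$mid_met.frontal, wig()),
      transverse = sum_programs(base$mid_met.transverse, wig())),
    met_hal = list(
      sagittal = sum_programs(base$met_hal.sagittal, wig()),
      frontal = sum_programs(base$met_hal.frontal, wig()),
      transverse = sum_programs(base$met_hal.transverse, wig())),
    mla = sum_programs(
      program_trapezoid(135, 135 + realized$mla_amplitude), wig())
  )
  kin <- synth_segment_poses(programs, config$kin_rate, T,
                             noise_sd_marker = config$noise_sd_marker)
  list(subject_id = id, group = group, time = tm, body_mass_kg = mass,
       duration_s = T, grf_rate = config$grf_rate, kin_rate = config$kin_rate,
       grf_v = grf$grf_v, grf_ap = grf$grf_ap, events_true = grf$events,
       segment_poses = kin$poses, markers = kin$markers, kin_times = kin$times)
}

## Plausible smooth base shapes for the channels with no planted discrete
## outcome (they only feed the trajectory-level analyses).
base_angle_programs <- function(off) {
  list(
    sha_cal.sagittal = function(tau) off[["sha_cal.sagittal"]] - 8 + 20 * sin(pi * tau)^2,
    sha_cal.transverse = function(tau) off[["sha_cal.transverse"]] + 2 - 5 * tau,
    cal_mid.sagittal = function(tau) off[["cal_mid.sagittal"]] + 2 + 4 * sin(pi * tau),
    cal_mid.frontal = function(tau) off[["cal_mid.frontal"]] - 2 + 3 * sin(pi * tau),
    cal_mid.transverse = function(tau) off[["cal_mid.transverse"]] + 1 + 2 * sin(2 * pi * tau),
    mid_met.sagittal = function(tau) off[["mid_met.sagittal"]] - 3 - 4 * sin(pi * tau),
    mid_met.frontal = function(tau) off[["mid_met.frontal"]] + 1.5 * sin(pi * tau),
    mid_met.transverse = function(tau) off[["mid_met.transverse"]] + 2 * sin(2 * pi * tau),
    met_hal.sagittal = function(tau) off[["met_hal.sagittal"]] + 5 + 20 * tau^3,
    met_hal.frontal = function(tau) off[["met_hal.frontal"]] + 0.5 * sin(pi * tau),
    met_hal.transverse = function(tau) off[["met_hal.transverse"]] + 3 * tau + 4 * sin(pi * tau)
  )
}

rtrunc_norm <- function(n, mean, sd, k) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- abs(x - mean) > k * sd))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' @export
print.foot_cohort <- function(x, ...) {
  cat(sprintf("Synthetic foot cohort: %d subjects (%d IG / %d CG), %d trials\n",
              nrow(x$subjects), sum(x$subjects$group == "IG"),
              sum(x$subjects$group == "CG"), length(x$trials)))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `subjects.csv`, `truth.json` (planted ground truth) and one
#' long-format CSV per trial (`time_s, channel, value`: GRF channels on the
#' force-plate clock, angle channels on the kinematic clock).
#'
#' @param cohort a `foot_cohort` with trials.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "foot_cohort"), length(cohort$trials) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  for (tr in cohort$trials) {
    ang <- trial_kinematics(tr)
    long <- rbind(
      data.frame(time_s = (seq_along(tr$grf_v) - 1) / tr$grf_rate,
                 channel = "grf_v", value = tr$grf_v),
      data.frame(time_s = (seq_along(tr$grf_ap) - 1) / tr$grf_rate,
                 channel = "grf_ap", value = tr$grf_ap),
      do.call(rbind, lapply(colnames(ang), function(ch)
        data.frame(time_s = tr$kin_times, channel = ch, value = ang[, ch])))
    )
    utils::write.csv(long,
                     file.path(dir, sprintf("%s_%s.csv", tr$subject_id, tr$time)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a long-format trial CSV
#'
#' Reads a `time_s, channel, value` CSV (as written by [write_cohort()] or
#' prepared from user data) back into per-channel series with their
#' sampling rates inferred from the time stamps.
#'
#' @param path CSV file path.
#' @return named list, one element per channel: list with `values`, `rate`
#'   (Hz) and `times` (s).
#' @export
read_trial_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "value")
  if (!all(need %in% names(long)))
    stop("trial CSV needs columns time_s, channel, value", call. = FALSE)
  out <- list()
  for (ch in unique(long$channel)) {
    d <- long[long$channel == ch, ]
    d <- d[order(d$time_s), ]
    dt <- diff(d$time_s)
    if (any(dt <= 0)) stop(sprintf("non-increasing time in channel '%s'", ch),
                           call. = FALSE)
    out[[ch]] <- list(values = d$value, rate = 1 / stats::median(dt),
                      times = d$time_s)
  }
  out
}

#' Compute all raw-time kinematic channels of one trial
#'
#' Joint Coordinate System angles of the five joints (including the derived
#' calcaneus-metatarsus joint) plus the planar metatarsal/arch channels,
#' one column per channel on the kinematic clock.
#'
#' @param trial one element of a `foot_cohort`'s `trials`.
#' @return numeric matrix `n_samples x channels`; channel names like
#'   `"sha_cal.frontal"`, `"f2g"`, `"mla"`.
#' @export
trial_kinematics <- function(trial) {
  p <- trial$segment_poses
  joints <- list(sha_cal = c("shank", "calcaneus"),
                 cal_mid = c("calcaneus", "midfoot"),
                 mid_met = c("midfoot", "metatarsus"),
                 cal_met = c("calcaneus", "metatarsus"),
                 met_hal = c("metatarsus", "hallux"))
  cols <- list()
  for (j in names(joints)) {
    a <- jcs_angle_series(p[[joints[[j]][1]]], p[[joints[[j]][2]]])
    cols[[paste0(j, ".sagittal")]] <- a[, "sagittal"]
    cols[[paste0(j, ".frontal")]] <- a[, "frontal"]
    cols[[paste0(j, ".transverse")]] <- a[, "transverse"]
  }
  m <- trial$markers
  n <- ncol(m$met1_base)
  f2g <- s2g <- v2g <- s2f <- s2v <- mla <- numeric(n)
  for (i in seq_len(n)) {
    a1 <- m$met1_head[, i] - m$met1_base[, i]
    a2 <- m$met2_head[, i] - m$met2_base[, i]
    a5 <- m$met5_head[, i] - m$met5_base[, i]
    f2g[i] <- metatarsal_inclination(m$met1_base[, i], m$met1_head[, i])
    s2g[i] <- metatarsal_inclination(m$met2_base[, i], m$met2_head[, i])
    v2g[i] <- metatarsal_inclination(m$met5_base[, i], m$met5_head[, i])
    s2f[i] <- metatarsal_divergence(a2, a1)
    s2v[i] <- metatarsal_divergence(a2, a5)
    mla[i] <- mla_angle(m$arch_heel[, i], m$arch_apex[, i], m$arch_head[, i])
  }
  cols$f2g <- f2g; cols$s2g <- s2g; cols$v2g <- v2g
  cols$s2f <- s2f; cols$s2v <- s2v; cols$mla <- mla
  do.call(cbind, cols)
}
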