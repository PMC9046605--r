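## Pipeline orchestration: simulate -> preprocess -> kinematics -> discrete
## outcomes -> statistics, with plain CSV/JSON artifacts and a provenance
## manifest so every run is reproducible from its configuration and seed.

#' Process one trial recording
#'
#' Filters the GRF (80 Hz default) and the derived kinematic angle channels
#' (10 Hz default) with the zero-lag Butterworth filter, detects the stance
#' window from the 30 N rule on the vertical GRF (filtered by default, raw
#' selectable), time-normalizes every channel to 101 nodes, and extracts the
#' six discrete risk factors.
#'
#' @param trial one trial of a `foot_cohort` (or an equivalent list).
#' @param filter logical; apply the Butterworth stage. Disable for strictly
#'   noiseless synthetic data, where the planted values are then recovered
#'   exactly.
#' @param cutoff_kin_hz,cutoff_grf_hz low-pass cutoffs, Hz.
#' @param threshold_n stance event threshold, N.
#' @param detect_on `"filtered"` (default) or `"raw"` vertical GRF.
#' @param valr_method passed to [valr()].
#' @param n_nodes stance-normalization nodes.
#' @return list with `trajectories` (matrix `n_nodes x channels`, plus
#'   `grf_v_bw`/`grf_ap_bw` columns), `outcomes` (one-row data.frame),
#'   `window` (stance window on the GRF clock).
#' @export
process_trial <- function(trial, filter = TRUE, cutoff_kin_hz = 10,
                          cutoff_grf_hz = 80, threshold_n = 30,
                          detect_on = c("filtered", "raw"),
                          valr_method = "secant", n_nodes = 101) {
  detect_on <- match.arg(detect_on)
  grf_v <- trial$grf_v; grf_ap <- trial$grf_ap
  if (filter) {
    grf_v <- butterworth_zero_lag(grf_v, trial$grf_rate, cutoff_grf_hz)
    grf_ap <- butterworth_zero_lag(grf_ap, trial$grf_rate, cutoff_grf_hz)
  }
  det_series <- if (detect_on == "filtered") grf_v else trial$grf_v
  win <- detect_stance(det_series, trial$grf_rate, threshold_n)
  if (nrow(win) == 0) stop("no stance phase detected", call. = FALSE)
  win <- win[1, ]

  ang <- trial_kinematics(trial)
  if (filter)
    ang <- apply(ang, 2, butterworth_zero_lag, rate = trial$kin_rate,
                 cutoff_hz = cutoff_kin_hz)

  t0 <- (win$heel_strike - 1) / trial$grf_rate
  t1 <- (win$toe_off - 1) / trial$grf_rate
  norm_kin <- apply(ang, 2, normalize_to_stance, window = c(t0, t1),
                    rate = trial$kin_rate, n_nodes = n_nodes,
                    units = "seconds")
  bw <- trial$body_mass_kg * GRAVITY
  norm_grf <- cbind(
    grf_v_bw = normalize_to_stance(grf_v, c(win$heel_strike, win$toe_off),
                                   trial$grf_rate, n_nodes) / bw,
    grf_ap_bw = normalize_to_stance(grf_ap, c(win$heel_strike, win$toe_off),
                                    trial$grf_rate, n_nodes) / bw)

  ip <- impact_peak(grf_v, win, bw)
  vl <- if (is.na(ip)) NA_real_ else valr(grf_v, win, bw, trial$grf_rate,
                                          method = valr_method)
  rf <- rearfoot_peaks(norm_kin[, "sha_cal.frontal"])
  outcomes <- data.frame(
    subject_id = trial$subject_id, group = trial$group, time = trial$time,
    mla_rom = mla_rom(norm_kin[, "mla"]),
    shacal_inv_peak = rf[["inv_peak"]],
    shacal_eve_peak = rf[["eve_peak"]],
    vertical_impact_peak = as.numeric(ip),
    valr = as.numeric(vl),
    peak_braking_force = peak_braking(grf_ap, win, bw))

  list(trajectories = cbind(norm_kin, norm_grf), outcomes = outcomes,
       window = win)
}

#' Process every trial of a cohort
#'
#' @param cohort a `foot_cohort` with trials.
#' @param ... passed to [process_trial()].
#' @return list with `outcomes` (long data.frame: one row per trial per
#'   outcome, columns `subject_id, group, time, outcome, value`),
#'   `trajectories` (list per channel of `trials x nodes` matrices),
#'   `meta` (data.frame aligned with trajectory rows), `n_failed`.
#' @export
process_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "foot_cohort"), length(cohort$trials) > 0)
  rows <- list(); traj <- list(); meta <- list(); failed <- 0L
  for (tr in cohort$trials) {
    res <- tryCatch(process_trial(tr, ...), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning(sprintf("trial %s/%s skipped: %s", tr$subject_id, tr$time,
                      conditionMessage(res)), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- res$outcomes
    meta[[length(meta) + 1L]] <- data.frame(subject_id = tr$subject_id,
                                            group = tr$group, time = tr$time)
    for (ch in colnames(res$trajectories))
      traj[[ch]] <- rbind(traj[[ch]], res$trajectories[, ch])
  }
  wide <- do.call(rbind, rows)
  outcome_cols <- setdiff(names(wide), c("subject_id", "group", "time"))
  long <- do.call(rbind, lapply(outcome_cols, function(o)
    data.frame(subject_id = wide$subject_id, group = wide$group,
               time = wide$time, outcome = o, value = wide[[o]])))
  list(outcomes = long, outcomes_wide = wide, trajectories = traj,
       meta = do.call(rbind, meta), n_failed = failed)
}

#' Group-by-time summary table for the discrete outcomes
#'
#' The cohort-level results table: pre/post mean (sd) per arm, the mixed
#' model interaction p-value, and Cohen's d between groups at post.
#'
#' @param outcomes long outcomes data.frame (see [process_cohort()]).
#' @param times the two assessment labels, baseline first.
#' @return data.frame, one row per outcome; the fitted `foot_mixedfx`
#'   objects are attached as attribute `fits`.
#' @export
outcome_summary_table <- function(outcomes, times = NULL) {
  if (is.null(times)) times <- unique(outcomes$time)
  rows <- list(); fits <- list()
  for (o in unique(outcomes$outcome)) {
    d <- outcomes[outcomes$outcome == o & !is.na(outcomes$value), ]
    cell <- function(g, tm) {
      v <- d$value[d$group == g & d$time == tm]
      sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
    }
    fit <- fit_interaction_model(d)
    fit$outcome <- o
    fits[[o]] <- fit
    rows[[o]] <- data.frame(
      outcome = o,
      ig_pre = cell("IG", times[1]), ig_post = cell("IG", times[2]),
      cg_pre = cell("CG", times[1]), cg_post = cell("CG", times[2]),
      interaction_p = fit$interaction$p,
      cohens_d = fit$cohens_d %||% NA_real_,
      d_label = fit$d_label %||% NA_character_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

## channel -> SPM analysis plan: scalar channels get t fields, three-plane
## joints get Hotelling T2 vector fields.
spm_plan <- function() {
  list(scalar = c("f2g", "s2g", "v2g", "s2f", "s2v", "mla"),
       vector = list(sha_cal = c("sha_cal.sagittal", "sha_cal.frontal", "sha_cal.transverse"),
                     cal_mid = c("cal_mid.sagittal", "cal_mid.frontal", "cal_mid.transverse"),
                     mid_met = c("mid_met.sagittal", "mid_met.frontal", "mid_met.transverse"),
                     cal_met = c("cal_met.sagittal", "cal_met.frontal", "cal_met.transverse"),
                     met_hal = c("met_hal.sagittal", "met_hal.frontal", "met_hal.transverse")))
}

#' Trajectory-level SPM analysis of a processed cohort
#'
#' Between-group comparison at one assessment: SPM t tests for the 1D
#' variables (metatarsal inclinations/divergences and the arch angle) and
#' Hotelling T2 vector-field tests for the three-plane joint rotations,
#' followed, where the T2 field crosses its threshold, by component t
#' fields at a Sidak-adjusted alpha.
#'
#' @param processed output of [process_cohort()].
#' @param time assessment to compare (default the second/post assessment).
#' @param alpha family-wise level.
#' @param method `"rft"` or `"perm"`.
#' @param seed seed for the permutation method.
#' @return named list of `spm_field` objects; vector-field entries carry a
#'   `post_hoc` attribute with the component t fields when run.
#' @export
spm_group_comparison <- function(processed, time = NULL, alpha = 0.05,
                                 method = "rft", seed = 1) {
  meta <- processed$meta
  if (is.null(time)) time <- utils::tail(unique(meta$time), 1)
  sel_ig <- meta$group == "IG" & meta$time == time
  sel_cg <- meta$group == "CG" & meta$time == time
  plan <- spm_plan()
  out <- list()
  for (ch in plan$scalar) {
    M <- processed$trajectories[[ch]]
    out[[ch]] <- spm_test(M[sel_ig, , drop = FALSE], M[sel_cg, , drop = FALSE],
                          statistic = "t", alpha = alpha, method = method,
                          seed = seed)
  }
  for (j in names(plan$vector)) {
    chans <- plan$vector[[j]]
    n_nodes <- ncol(processed$trajectories[[chans[1]]])
    arr_ig <- array(0, c(sum(sel_ig), n_nodes, 3))
    arr_cg <- array(0, c(sum(sel_cg), n_nodes, 3))
    for (k in 1:3) {
      arr_ig[, , k] <- processed$trajectories[[chans[k]]][sel_ig, , drop = FALSE]
      arr_cg[, , k] <- processed$trajectories[[chans[k]]][sel_cg, , drop = FALSE]
    }
    res <- spm_test(arr_ig, arr_cg, statistic = "T2", alpha = alpha,
                    method = method, seed = seed)
    if (nrow(res$clusters)) {
      a_post <- sidak_alpha(alpha, 3)
      ph <- lapply(1:3, function(k)
        spm_test(arr_ig[, , k], arr_cg[, , k], statistic = "t",
                 alpha = a_post, method = method, seed = seed))
      names(ph) <- c("sagittal", "frontal", "transverse")
      attr(res, "post_hoc") <- ph
    }
    out[[j]] <- res
  }
  out
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> kinematics -> outcomes -> statistics. With an
#' output directory, writes the outcomes table, the group-by-time summary
#' table, per-variable SPM JSON, mean +/- SD trajectory figures with
#' significance bars, and a provenance manifest (config digest, seed,
#' package version).
#'
#' @param config a [cohort_config()]; its seed drives all randomness.
#' @param alpha significance level.
#' @param filter,cutoff_kin_hz,cutoff_grf_hz,detect_on,valr_method see
#'   [process_trial()].
#' @param spm_method `"rft"` or `"perm"`.
#' @param spm logical; run the trajectory-level analyses.
#' @param outdir optional output directory.
#' @return list with `cohort`, `processed`, `summary_table`, `fits`,
#'   `spm` (when run) and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), alpha = 0.05,
                         filter = TRUE, cutoff_kin_hz = 10,
                         cutoff_grf_hz = 80, detect_on = "filtered",
                         valr_method = "secant", spm_method = "rft",
                         spm = TRUE, outdir = NULL) {
  cohort <- generate_cohort(config)
  processed <- process_cohort(cohort, filter = filter,
                              cutoff_kin_hz = cutoff_kin_hz,
                              cutoff_grf_hz = cutoff_grf_hz,
                              detect_on = detect_on,
                              valr_method = valr_method)
  tab <- outcome_summary_table(processed$outcomes, times = config$times)
  spm_res <- if (spm) spm_group_comparison(processed, alpha = alpha,
                                           method = spm_method,
                                           seed = config$seed) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("footspm")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    alpha = alpha,
    filter = filter, cutoffs_hz = list(kin = cutoff_kin_hz, grf = cutoff_grf_hz),
    detect_on = detect_on, valr_method = valr_method,
    spm_method = spm_method,
    n_per_group = as.list(config$n_per_group),
    n_trials_failed = processed$n_failed)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(processed$outcomes,
                     file.path(outdir, "outcomes.csv"), row.names = FALSE)
    utils::write.csv(tab, file.path(outdir, "summary_table.csv"),
                     row.names = FALSE)
    if (!is.null(spm_res)) {
      spm_json <- lapply(spm_res, function(s)
        list(statistic = s$statistic, dof = s$dof, fwhm = s$fwhm,
             critical = s$critical, alpha = s$alpha, field = s$field,
             clusters = s$clusters))
      jsonlite::write_json(spm_json, file.path(outdir, "spm.json"),
                           auto_unbox = TRUE, digits = NA)
      grDevices::png(file.path(outdir, "spm_fields.png"), width = 1200,
                     height = 900)
      old <- graphics::par(mfrow = c(4, 3), mar = c(4, 4, 2, 1))
      for (nm in names(spm_res)) plot(spm_res[[nm]], main = nm)
      graphics::par(old)
      grDevices::dev.off()
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, processed = processed, summary_table = tab,
       fits = attr(tab, "fits"), spm = spm_res, manifest = manifest)
}
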