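test_that("GRF waveform encodes the planted kinetic parameters exactly", {
  g <- synth_grf(0.25, 70.5, impact_peak_bw = 1.14, active_peak_bw = 2.4,
                 valr_bw_s = 75.19, braking_peak_bw = -0.24, rate = 1000)
  bw <- 70.5 * 9.80665
  w <- detect_stance(g$grf_v, 1000)
  expect_equal(nrow(w), 1)
  expect_equal(unname(c(w$heel_strike, w$toe_off)), unname(g$events))
  # the early-stance local maximum equals impact_peak_bw * BW
  ip <- impact_peak(g$grf_v, w, bw)
  expect_equal(as.numeric(ip), 1.14, tolerance = 1e-12)
  expect_equal(max(g$grf_v[1:round(0.3 * length(g$grf_v))]), 1.14 * bw,
               tolerance = 1e-12)
  expect_equal(valr(g$grf_v, w, bw, 1000), 75.19, tolerance = 1e-12)
  expect_equal(peak_braking(g$grf_ap, w, bw), -0.24, tolerance = 1e-12)
  expect_equal(min(g$grf_ap), -0.24 * bw, tolerance = 1e-12)
  # exactly one upward and one downward 30 N crossing
  above <- g$grf_v >= 30
  expect_equal(sum(diff(above) == 1), 1)
  expect_equal(sum(diff(above) == -1), 1)
})

test_that("planted braking force scales with the stated body weight", {
  mass <- 700 / 9.80665   # BW of 700 N
  g <- synth_grf(0.25, mass, 1.2, 2.4, 80, -0.24, 1000)
  expect_equal(min(g$grf_ap), -168, tolerance = 1e-9)
})

test_that("VALR of the linear rise is rate- and interval-independent", {
  g <- synth_grf(0.25, 70, 1.2, 2.4, 20, -0.2, 1000)
  bw <- 70 * 9.80665
  w <- detect_stance(g$grf_v, 1000)
  expect_equal(valr(g$grf_v, w, bw, 1000), 20, tolerance = 1e-12)
  expect_equal(valr(g$grf_v, w, bw, 1000, method = "regression"), 20,
               tolerance = 1e-9)
  # doubling the sampling rate leaves all planted outcomes in place
  g2 <- synth_grf(0.25, 70, 1.2, 2.4, 20, -0.2, 2000)
  w2 <- detect_stance(g2$grf_v, 2000)
  expect_equal(valr(g2$grf_v, w2, bw, 2000), 20, tolerance = 1e-3)
  expect_equal(as.numeric(impact_peak(g2$grf_v, w2, bw)), 1.2, tolerance = 1e-3)
  expect_equal(peak_braking(g2$grf_ap, w2, bw), -0.2, tolerance = 1e-3)
})

test_that("unreachable waveform constraints are rejected", {
  expect_error(synth_grf(0.25, 70, 2.5, 2.4, 80, -0.2, 1000), "active peak")
  expect_error(synth_grf(0.25, 70, 1.2, 2.4, 3, -0.2, 1000), "early stance")
  expect_error(synth_grf(0.25, 70, 1.2, 2.4, 80, 0.2, 1000), "braking_peak_bw")
  expect_error(synth_grf(0.25, 70, 1.2, 2.4, 5000, -0.2, 1000), "sampling rate")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohort_config(n_per_group = 3, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(cohort_config(n_per_group = 3, seed = 43))
  expect_false(identical(serialize(c1, NULL), serialize(c3, NULL)))
})

test_that("zero-noise degenerate cohort plants the cell means exactly", {
  cfg <- cohort_config(n_per_group = 2, sd_scale = 0, seed = 1)
  co <- generate_cohort(cfg, trajectories = FALSE)
  tr <- co$truth
  ig_pre <- tr[tr$group == "IG" & tr$time == "baseline" & tr$outcome == "mla_rom", ]
  expect_true(all(ig_pre$planted == 6.16))
  expect_true(all(ig_pre$realized == 6.16))
  # implied difference-in-differences of the default MLA ROM configuration
  cell <- function(g, tm) mean(tr$planted[tr$group == g & tr$time == tm &
                                            tr$outcome == "mla_rom"])
  did <- (cell("IG", "week8") - cell("IG", "baseline")) -
    (cell("CG", "week8") - cell("CG", "baseline"))
  expect_equal(did, -5.28, tolerance = 1e-12)
})

test_that("planted outcome draws are statistically faithful to the config", {
  cfg <- cohort_config(n_per_group = 500, seed = 99)
  co <- generate_cohort(cfg, trajectories = FALSE)
  et <- default_effect_table()
  for (o in rownames(et)) {
    for (cellcol in c("ig_pre", "ig_post", "cg_pre", "cg_post")) {
      g <- toupper(substr(cellcol, 1, 2))
      tm <- if (grepl("pre", cellcol)) "baseline" else "week8"
      v <- co$truth$planted[co$truth$group == g & co$truth$time == tm &
                              co$truth$outcome == o]
      se <- et[o, sub("^(ig|cg)_", "\\1_sd_", cellcol)] / sqrt(length(v))
      expect_lt(abs(mean(v) - et[o, cellcol]), 3 * max(se, 1e-12))
    }
  }
})

test_that("invalid configuration errors name the offending field", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(kin_rate = -1), "kin_rate")
  expect_error(cohort_config(grf_rate = 999), "grf_rate")
  expect_error(cohort_config(noise_sd_marker = -1), "noise_sd_marker")
  expect_error(cohort_config(sd_scale = -0.1), "sd_scale")
  et <- default_effect_table(); et$ig_sd_pre[1] <- -1
  expect_error(cohort_config(effect_table = et), "effect_table")
})

test_that("cohorts round-trip through the plain-text export", {
  cfg <- cohort_config(n_per_group = 2, seed = 3)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  f <- file.path(dir, sprintf("%s_%s.csv", co$trials[[1]]$subject_id,
                              co$trials[[1]]$time))
  expect_true(file.exists(f))
  long <- utils::read.csv(f)
  expect_setequal(unique(long$channel),
                  c("grf_v", "grf_ap", colnames(trial_kinematics(co$trials[[1]]))))
  v <- long$value[long$channel == "grf_v"]
  expect_equal(v, co$trials[[1]]$grf_v, tolerance = 1e-10)
  # the reader reconstructs channels and rates, ready for preprocessing
  tr <- read_trial_csv(f)
  expect_equal(tr$grf_v$rate, 1000, tolerance = 1e-6)
  expect_equal(tr$mla$rate, 200, tolerance = 1e-6)
  w <- detect_stance(tr$grf_v$values, tr$grf_v$rate)
  expect_equal(nrow(w), 1)
  n <- normalize_to_stance(tr$mla$values,
                           c((w$heel_strike - 1), (w$toe_off - 1)) / 1000,
                           tr$mla$rate, units = "seconds")
  expect_length(n, 101)
})
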