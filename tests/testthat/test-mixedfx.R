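test_that("identical cell means give a null interaction", {
  set.seed(31)
  tab <- make_outcomes_table(list(IG = 12, CG = 12),
                             list(ig_pre = 5, ig_post = 5, cg_pre = 5, cg_post = 5),
                             list(ig_pre = 3, ig_post = 3, cg_pre = 3, cg_post = 3))
  # force all four cell means to exactly zero: the balanced interaction
  # estimate is then exactly the zero difference-in-differences
  for (g in c("IG", "CG")) for (tm in c("baseline", "week8")) {
    sel <- tab$group == g & tab$time == tm
    tab$value[sel] <- tab$value[sel] - mean(tab$value[sel])
  }
  fit <- fit_interaction_model(tab, "y")
  expect_equal(fit$interaction$estimate, 0, tolerance = 1e-9)
  expect_equal(fit$interaction$p, 1, tolerance = 1e-9)
})

test_that("EMMs of a balanced design equal the raw cell means", {
  set.seed(32)
  tab <- make_outcomes_table(list(IG = 10, CG = 10),
                             list(ig_pre = 6.16, ig_post = 0.17,
                                  cg_pre = 3.59, cg_post = 2.88),
                             list(ig_pre = 8, ig_post = 7, cg_pre = 8, cg_post = 5))
  fit <- fit_interaction_model(tab, "y")
  raw <- aggregate(value ~ group + time, tab, mean)
  emm <- fit$emm
  for (i in seq_len(nrow(raw))) {
    got <- emm$emmean[emm$group == raw$group[i] & emm$time == raw$time[i]]
    expect_equal(got, raw$value[i], tolerance = 1e-9)
  }
})

test_that("zero between-subject variance reduces to the fixed-effects ANOVA", {
  set.seed(33)
  tab <- make_outcomes_table(list(IG = 15, CG = 15),
                             list(ig_pre = 2, ig_post = 4, cg_pre = 2, cg_post = 2),
                             list(ig_pre = 1, ig_post = 1, cg_pre = 1, cg_post = 1),
                             sigma_b = 0)
  fit <- suppressMessages(fit_interaction_model(tab, "y"))
  ols <- lm(value ~ group * time,
            transform(tab, group = factor(group, c("CG", "IG"))))
  irow <- grep(":", names(coef(ols)))
  expect_equal(unname(fit$interaction$estimate), unname(coef(ols)[irow]),
               tolerance = 1e-4)
})

test_that("group label permutation flips the interaction sign only", {
  set.seed(34)
  tab <- make_outcomes_table(list(IG = 12, CG = 14),
                             list(ig_pre = 6, ig_post = 1, cg_pre = 4, cg_post = 3),
                             list(ig_pre = 5, ig_post = 5, cg_pre = 5, cg_post = 5))
  fit1 <- fit_interaction_model(tab, "y", emm = FALSE)
  tab2 <- tab
  tab2$group <- ifelse(tab$group == "IG", "CG", "IG")
  fit2 <- fit_interaction_model(tab2, "y", emm = FALSE)
  expect_equal(fit1$interaction$estimate, -fit2$interaction$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$interaction$p, fit2$interaction$p, tolerance = 1e-6)
})

test_that("interaction test holds its nominal size under the null", {
  set.seed(35)
  reps <- 300
  rej <- logical(reps)
  for (r in 1:reps) {
    tab <- make_outcomes_table(list(IG = 20, CG = 22),
                               list(ig_pre = 5, ig_post = 5, cg_pre = 5, cg_post = 5),
                               list(ig_pre = 4, ig_post = 4, cg_pre = 4, cg_post = 4),
                               sigma_b = 2.5, seed = 5000 + r)
    fit <- suppressMessages(fit_interaction_model(tab, "y", emm = FALSE))
    rej[r] <- fit$interaction$p < 0.05
  }
  # 0.05 +/- binomial noise; bound mirrors the <= 0.06 size requirement
  # with 3 sd of Monte-Carlo slack
  expect_lte(mean(rej), 0.06 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Cohen's d uses the n-weighted pooled sd and the stated bins", {
  d <- cohens_d(c(5.90, 6.39), c(2.95, 1.88), c(41, 46))
  expect_equal(round(d$d, 2), 0.20)
  expect_identical(d$label, "small")
  expect_equal(cohens_d(c(3, 3), c(1, 1), c(10, 10))$d, 0)
  expect_identical(cohens_d(c(3, 3), c(1, 1), c(10, 10))$label, "negligible")
  u <- cohens_d(c(0, 1), c(1, 1), c(20, 20))
  expect_equal(u$d, 1)
  expect_identical(u$label, "large")
  expect_identical(cohens_d(c(0, 0.65), c(1, 1), c(20, 20))$label, "medium")
  expect_error(cohens_d(c(1, 2), c(0, 1), c(10, 10)), "standard deviations")
})

test_that("Bonferroni adjustment caps at one and dominates raw p-values", {
  expect_equal(bonferroni_adjust(0.01, 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_error(bonferroni_adjust(0.1, 0), "family_size")
  expect_error(bonferroni_adjust(1.5, 2), "0, 1")
  set.seed(36)
  p <- runif(1000)
  expect_true(all(bonferroni_adjust(p, 3) >= p))
  expect_true(all(bonferroni_adjust(p, 3) <= 1))
})
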