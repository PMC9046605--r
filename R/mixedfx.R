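## Per-outcome mixed-model inference for the two-arm pre/post design: fixed
## group, time and group-by-time effects with a random intercept per
## participant (the standard pre/post RCT model), REML fit with Satterthwaite
## degrees of freedom, Bonferroni-adjusted estimated marginal means, and
## Cohen's d between groups at the post assessment.

#' Fit the group-by-time interaction model for one outcome
#'
#' Fits `value ~ group * time + (1 | subject)` by REML (optionally with a
#' random time slope) on the available cases of one outcome and reports the
#' interaction Wald test (Satterthwaite df), the four estimated marginal
#' means with confidence intervals, Bonferroni-adjusted pairwise
#' comparisons, and Cohen's d between groups at the post assessment
#' computed from the raw post summaries.
#'
#' A singular random-intercept fit (zero between-subject variance) falls
#' back to ordinary least squares with a note; estimates then match the
#' two-way fixed-effects ANOVA.
#'
#' @param outcomes_table long data.frame with columns `subject_id`, `group`
#'   (`"IG"`/`"CG"`), `time`, `outcome`, `value` (or already filtered with a
#'   `value` column).
#' @param outcome_name which outcome to fit (ignored when the table has no
#'   `outcome` column).
#' @param random_slope add a random time slope per participant.
#' @param alpha level for the EMM confidence intervals.
#' @param emm compute estimated marginal means, pairwise comparisons and
#'   Cohen's d (skip in tight simulation loops that only need the
#'   interaction test).
#' @return object of class `foot_mixedfx`.
#' @export
fit_interaction_model <- function(outcomes_table, outcome_name = NULL,
                                  random_slope = FALSE, alpha = 0.05,
                                  emm = TRUE) {
  df <- outcomes_table
  if (!is.null(outcome_name) && "outcome" %in% names(df))
    df <- df[df$outcome == outcome_name, , drop = FALSE]
  need <- c("subject_id", "group", "time", "value")
  if (!all(need %in% names(df)))
    stop("outcomes table needs columns subject_id, group, time, value",
         call. = FALSE)
  df <- df[stats::complete.cases(df[need]), need]
  times <- unique(df$time)
  if (length(times) != 2) stop("exactly two assessment times required", call. = FALSE)
  df$group <- factor(df$group, levels = c("CG", "IG"))
  df$time <- factor(df$time, levels = times)
  if (any(table(unique(df[c("subject_id", "group")])$group) < 2))
    stop("need at least 2 subjects per group", call. = FALSE)

  form <- if (random_slope) value ~ group * time + (1 + time | subject_id)
          else value ~ group * time + (1 | subject_id)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE)),
    error = function(e) NULL)
  note <- NULL
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-6)) {
    note <- if (is.null(fit)) "mixed fit failed; ordinary least squares fallback"
            else "singular random-intercept fit (zero between-subject variance); ordinary least squares fallback"
    fit <- stats::lm(value ~ group * time, data = df)
  }

  if (inherits(fit, "lmerModLmerTest")) {
    co <- stats::coef(summary(fit))
  } else {
    co <- stats::coef(summary(fit))
    co <- cbind(co[, 1:2], df = stats::df.residual(fit), co[, 3:4])
  }
  colnames(co) <- c("estimate", "se", "df", "t", "p")
  irow <- grep(":", rownames(co))
  interaction <- list(estimate = co[irow, "estimate"], se = co[irow, "se"],
                      df = co[irow, "df"], p = co[irow, "p"],
                      ci = co[irow, "estimate"] +
                        c(-1, 1) * stats::qt(1 - alpha / 2, co[irow, "df"]) * co[irow, "se"])

  emm_df <- pw <- d <- NULL
  if (emm) {
    em <- emmeans::emmeans(fit, ~ group * time, level = 1 - alpha,
                           lmer.df = "satterthwaite")
    emm_df <- as.data.frame(em)
    pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "bonferroni"))
    post <- df[df$time == times[2], ]
    ns <- tapply(post$value, post$group, length)
    if (all(c("IG", "CG") %in% names(ns)) && all(ns >= 2)) {
      ms <- tapply(post$value, post$group, mean)
      sds <- tapply(post$value, post$group, stats::sd)
      d <- cohens_d(ms[c("IG", "CG")], sds[c("IG", "CG")], ns[c("IG", "CG")])
    }
  }

  structure(list(outcome = outcome_name %||% "value", model = fit,
                 fixed_effects = co, interaction = interaction,
                 emm = emm_df, pairwise = pw,
                 cohens_d = d$d, d_label = d$label,
                 alpha = alpha, note = note, n = nrow(df)),
            class = "foot_mixedfx")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.foot_mixedfx <- function(x, digits = 3, ...) {
  cat(sprintf("Group-by-time mixed model: %s (n obs = %d)\n", x$outcome, x$n))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  cat(sprintf("  interaction: estimate %.*f (se %.*f), df %.1f, p = %.4g\n",
              digits, x$interaction$estimate, digits, x$interaction$se,
              x$interaction$df, x$interaction$p))
  if (!is.null(x$cohens_d))
    cat(sprintf("  Cohen's d (groups at post): %.2f (%s)\n", x$cohens_d, x$d_label))
  if (!is.null(x$emm)) {
    cat("  estimated marginal means:\n")
    print(x$emm, digits = digits)
  }
  invisible(x)
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference `|m1 - m2| / s_pooled` with the n-weighted
#' pooled standard deviation, labelled with the conventional bins:
#' below 0.2 negligible, 0.2-0.5 small, 0.5-0.8 medium, 0.8 and above
#' large.
#'
#' @param post_means,post_sds,n_per_group length-2 numeric vectors (one
#'   entry per group).
#' @return list with `d` and `label`.
#' @export
cohens_d <- function(post_means, post_sds, n_per_group) {
  if (any(post_sds <= 0)) stop("standard deviations must be > 0", call. = FALSE)
  if (any(n_per_group < 2)) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- sum((n_per_group - 1) * post_sds^2) / (sum(n_per_group) - 2)
  if (sp2 == 0) stop("zero pooled standard deviation: d undefined", call. = FALSE)
  d <- abs(diff(post_means)) / sqrt(sp2)
  label <- if (d < 0.2) "negligible" else if (d < 0.5) "small"
           else if (d < 0.8) "medium" else "large"
  list(d = unname(d), label = label)
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)` applied elementwise.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param family_size number of comparisons in the family (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, family_size) {
  if (family_size < 1) stop_config("family_size", "must be >= 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p_values * family_size)
}
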