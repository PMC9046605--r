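## One-dimensional statistical parametric mapping over 101-node stance
## trajectories. Scalar t and F fields and vector-field Hotelling T2 are
## computed node-wise; family-wise inference uses random-field-theory (RFT)
## critical thresholds from the standard 1D expected-Euler-characteristic
## densities, with residual smoothness (FWHM) estimated from the gradient of
## unit-variance residuals. A label-permutation / sign-flip oracle provides a
## nonparametric alternative and the in-suite validation of the RFT path.

#' Node-wise t statistic field
#'
#' Two-sample (pooled variance) or paired t statistic at every node.
#'
#' @param matrix_a,matrix_b numeric matrices, subjects x nodes; for
#'   `paired = TRUE` rows must be matched and equal in number.
#' @param paired logical.
#' @return list with `field` (t per node), `dof`, `statistic = "t"`, and
#'   `residuals` (for smoothness estimation).
#' @export
t_field <- function(matrix_a, matrix_b, paired = FALSE) {
  a <- as.matrix(matrix_a); b <- as.matrix(matrix_b)
  if (ncol(a) != ncol(b)) stop("node counts differ", call. = FALSE)
  if (paired) {
    if (nrow(a) != nrow(b)) stop("paired design needs matched rows", call. = FALSE)
    d <- a - b
    n <- nrow(d)
    if (n < 3) stop("need at least 3 pairs", call. = FALSE)
    m <- colMeans(d)
    s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
    field <- m / (s / sqrt(n))
    res <- sweep(d, 2, m)
    dof <- n - 1
  } else {
    n1 <- nrow(a); n2 <- nrow(b)
    if (n1 < 3 || n2 < 3) stop("need at least 3 subjects per group", call. = FALSE)
    m1 <- colMeans(a); m2 <- colMeans(b)
    ra <- sweep(a, 2, m1); rb <- sweep(b, 2, m2)
    sp2 <- (colSums(ra^2) + colSums(rb^2)) / (n1 + n2 - 2)
    field <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    res <- rbind(ra, rb)
    dof <- n1 + n2 - 2
  }
  list(field = as.numeric(field), dof = dof, statistic = "t", residuals = res)
}

#' Node-wise one-way ANOVA F field
#'
#' @param matrices list of numeric matrices (subjects x nodes), one per
#'   factor level; at least two levels with at least two rows each.
#' @return list with `field`, `dof = c(df1, df2)`, `statistic = "F"`,
#'   `residuals`.
#' @export
f_field <- function(matrices) {
  matrices <- lapply(matrices, as.matrix)
  k <- length(matrices)
  if (k < 2) stop("need at least 2 factor levels", call. = FALSE)
  ns <- vapply(matrices, nrow, integer(1))
  if (any(ns < 2)) stop("every level needs at least 2 rows", call. = FALSE)
  N <- sum(ns)
  nodes <- unique(vapply(matrices, ncol, integer(1)))
  if (length(nodes) != 1) stop("node counts differ", call. = FALSE)
  grand <- colSums(do.call(rbind, matrices)) / N
  ss_b <- rep(0, nodes); ss_w <- rep(0, nodes); res <- NULL
  for (m in matrices) {
    mm <- colMeans(m)
    ss_b <- ss_b + nrow(m) * (mm - grand)^2
    r <- sweep(m, 2, mm)
    ss_w <- ss_w + colSums(r^2)
    res <- rbind(res, r)
  }
  df1 <- k - 1; df2 <- N - k
  field <- (ss_b / df1) / (ss_w / df2)
  list(field = as.numeric(field), dof = c(df1, df2), statistic = "F",
       residuals = res)
}

#' Node-wise Hotelling T2 field for vector trajectories
#'
#' Two-sample `T2 = (n1 n2 / (n1 + n2)) * d' W^-1 d` with the pooled
#' within-group covariance `W` at each node, or paired/one-sample
#' `T2 = n * dbar' S^-1 dbar` on row differences. A (near-)singular node
#' covariance is ridge-stabilized with a warning.
#'
#' @param array_a,array_b numeric arrays `subjects x nodes x components`
#'   (components 2 or 3).
#' @param paired logical.
#' @return list with `field`, `dof` (`nu` = error df, `p` = components),
#'   `statistic = "T2"`, `residuals` (component residuals stacked row-wise,
#'   used for smoothness pooling).
#' @export
hotelling_t2_field <- function(array_a, array_b, paired = FALSE) {
  da <- dim(array_a); db <- dim(array_b)
  if (length(da) != 3 || length(db) != 3 || !all(da[2:3] == db[2:3]))
    stop("arrays must be subjects x nodes x components with matching shape",
         call. = FALSE)
  p <- da[3]
  if (p < 1 || p > 3) stop("components must be 1, 2, or 3", call. = FALSE)
  nodes <- da[2]
  flag <- new.env(); flag$ridged <- FALSE
  on.exit(if (flag$ridged)
    warning("singular node covariance: ridge-stabilized", call. = FALSE))
  if (paired) {
    if (da[1] != db[1]) stop("paired design needs matched rows", call. = FALSE)
    d <- array_a - array_b
    n <- da[1]
    if (n < p + 2) stop("too few pairs for the component count", call. = FALSE)
    field <- numeric(nodes); res <- matrix(0, n, 0)
    resid <- array(0, dim(d))
    for (j in seq_len(nodes)) {
      X <- matrix(d[, j, ], nrow = n)
      mu <- colMeans(X)
      R <- sweep(X, 2, mu)
      S <- crossprod(R) / (n - 1)
      field[j] <- n * drop(crossprod(mu, solve_spd(S, mu, flag)))
      resid[, j, ] <- R
    }
    list(field = field, dof = c(nu = n - 1, p = p), statistic = "T2",
         residuals = stack_components(resid))
  } else {
    n1 <- da[1]; n2 <- db[1]
    if (n1 + n2 < p + 3) stop("too few subjects for the component count", call. = FALSE)
    field <- numeric(nodes)
    resid_a <- array(0, dim(array_a)); resid_b <- array(0, dim(array_b))
    for (j in seq_len(nodes)) {
      Xa <- matrix(array_a[, j, ], nrow = n1)
      Xb <- matrix(array_b[, j, ], nrow = n2)
      ma <- colMeans(Xa); mb <- colMeans(Xb)
      Ra <- sweep(Xa, 2, ma); Rb <- sweep(Xb, 2, mb)
      W <- (crossprod(Ra) + crossprod(Rb)) / (n1 + n2 - 2)
      dlt <- ma - mb
      field[j] <- (n1 * n2 / (n1 + n2)) *
        drop(crossprod(dlt, solve_spd(W, dlt, flag)))
      resid_a[, j, ] <- Ra; resid_b[, j, ] <- Rb
    }
    list(field = field, dof = c(nu = n1 + n2 - 2, p = p), statistic = "T2",
         residuals = rbind(stack_components(resid_a), stack_components(resid_b)))
  }
}

## Solve S x = b, ridge-stabilizing singular node covariances; `flag` is an
## environment used to emit a single warning per field.
solve_spd <- function(S, x, flag = NULL) {
  out <- tryCatch(solve(S, x), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    if (is.environment(flag)) flag$ridged <- TRUE
    else warning("singular node covariance: ridge-stabilized", call. = FALSE)
    out <- solve(S + diag(1e-8 * max(diag(S), 1e-12), nrow(S)), x)
  }
  out
}

stack_components <- function(a) {
  do.call(rbind, lapply(seq_len(dim(a)[3]), function(k) a[, , k, drop = TRUE]))
}

#' Estimate residual field smoothness (FWHM)
#'
#' Smoothness of the residual field in nodes, from the root-mean-square
#' node-to-node derivative of unit-variance residuals:
#' `fwhm = sqrt(4 log 2) / rms-gradient`. Nodes with zero residual variance
#' are excluded with a warning.
#'
#' @param residual_matrix residuals, observations x nodes (>= 2 rows).
#' @return estimated FWHM in nodes (> 0).
#' @export
estimate_fwhm <- function(residual_matrix) {
  R <- as.matrix(residual_matrix)
  if (nrow(R) < 2 || ncol(R) < 3)
    stop("need at least 2 residual rows and 3 nodes", call. = FALSE)
  ssq <- colSums(R^2)
  keep <- ssq > 0
  if (!all(keep)) {
    warning("zero-variance nodes excluded from smoothness estimation",
            call. = FALSE)
    R <- R[, keep, drop = FALSE]
    ssq <- ssq[keep]
    if (ncol(R) < 3) stop("too few informative nodes", call. = FALSE)
  }
  dR <- R[, -1, drop = FALSE] - R[, -ncol(R), drop = FALSE]
  num <- colSums(dR^2)
  den <- (ssq[-1] + ssq[-length(ssq)]) / 2
  v <- mean(num / den)
  sqrt(4 * log(2) / v)
}

## 1D expected-Euler-characteristic densities (unit-variance fields), the
## standard Worsley forms. `ec1` is the density per resel.
ec_density <- function(statistic, z, dof) {
  four_log2 <- 4 * log(2)
  switch(statistic,
    gauss = list(
      ec0 = stats::pnorm(z, lower.tail = FALSE),
      ec1 = sqrt(four_log2) / (2 * pi) * exp(-z^2 / 2)),
    t = {
      v <- dof[1]
      list(ec0 = stats::pt(z, v, lower.tail = FALSE),
           ec1 = sqrt(four_log2) / (2 * pi) * (1 + z^2 / v)^(-(v - 1) / 2))
    },
    F = {
      k <- dof[1]; v <- dof[2]
      if (z <= 0) return(list(ec0 = 1, ec1 = 0))
      lg <- lgamma((v + k - 1) / 2) - lgamma(v / 2) - lgamma(k / 2)
      list(ec0 = stats::pf(z, k, v, lower.tail = FALSE),
           ec1 = sqrt(four_log2 / (2 * pi)) * exp(lg) * sqrt(2) *
             (k * z / v)^((k - 1) / 2) * (1 + k * z / v)^(-(v + k - 2) / 2))
    },
    stop("unknown statistic", call. = FALSE))
}

## Upper-bound probability that the field maximum exceeds u, from the
## expected Euler characteristic of the excursion set: EC0 + resels * EC1.
rft_exceedance <- function(statistic, u, dof, resels) {
  d <- ec_density(statistic, u, dof)
  min(1, d$ec0 + resels * d$ec1)
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Smallest `u` with expected-Euler-characteristic exceedance probability
#' `P(max field > u) = alpha` for a smooth field over `n_nodes` nodes with
#' the given smoothness (`resels = (n_nodes - 1) / fwhm`). Scalar t fields
#' are thresholded two-sided by default (`alpha/2` per tail, threshold on
#' `|t|`); F is one-sided. Hotelling T2 uses its exact monotone F transform:
#' for error df `nu` and `p` components, `F = (nu - p + 1) / (nu p) * T2`
#' with F-field dof `(p, nu - p + 1)`.
#'
#' @param statistic_name one of `"t"`, `"F"`, `"T2"`, `"gauss"`.
#' @param dof degrees of freedom: scalar for t, `c(df1, df2)` for F,
#'   `c(nu, p)` for T2.
#' @param n_nodes number of field nodes.
#' @param fwhm smoothness in nodes (> 0).
#' @param alpha family-wise error level, in (0, 0.5].
#' @param two_tailed two-sided thresholding for t/gauss fields.
#' @return critical value on the statistic's own scale.
#' @export
rft_threshold <- function(statistic_name = c("t", "F", "T2", "gauss"), dof,
                          n_nodes, fwhm, alpha = 0.05, two_tailed = TRUE) {
  statistic_name <- match.arg(statistic_name)
  if (fwhm <= 0) stop_config("fwhm", "must be > 0")
  if (alpha <= 0 || alpha > 0.5) stop_config("alpha", "must lie in (0, 0.5]")
  resels <- (n_nodes - 1) / fwhm
  a <- if (statistic_name %in% c("t", "gauss") && two_tailed) alpha / 2 else alpha
  if (statistic_name == "T2") {
    nu <- unname(dof[1]); p <- unname(dof[2])
    if (nu - p + 1 <= 0) stop("error df too small for the component count",
                              call. = FALSE)
    scale <- (nu - p + 1) / (nu * p)
    uf <- rft_threshold("F", c(p, nu - p + 1), n_nodes, fwhm, alpha,
                        two_tailed = FALSE)
    return(uf / scale)
  }
  f <- function(u) rft_exceedance(statistic_name, u, dof, resels) - a
  lo <- if (statistic_name == "F") 1e-8 else 0
  hi <- if (statistic_name == "F") 10 else 2
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(lo) < 0) return(lo)   # alpha not attainable below the floor
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Suprathreshold clusters of a statistic field
#'
#' Maximal runs of consecutive nodes exceeding the critical threshold
#' (absolute value for two-sided scalar fields), reported as stance-percent
#' intervals (node 1 of the field = 0% of stance) with RFT cluster-extent
#' p-values.
#'
#' @param field numeric statistic field.
#' @param critical critical threshold.
#' @param two_tailed cluster on `|field|`.
#' @param statistic,dof,fwhm optional field metadata for cluster p-values;
#'   when omitted, `cluster_p` is `NA`.
#' @return data.frame with `start_node`, `end_node` (0-based, i.e. percent
#'   of stance for a 101-node field), `extent_nodes`, `max_stat`,
#'   `cluster_p`.
#' @export
suprathreshold_clusters <- function(field, critical, two_tailed = TRUE,
                                    statistic = NULL, dof = NULL, fwhm = NULL) {
  if (any(!is.finite(field))) stop("field must be finite", call. = FALSE)
  x <- if (two_tailed) abs(field) else field
  above <- x > critical
  out <- data.frame(start_node = integer(), end_node = integer(),
                    extent_nodes = integer(), max_stat = numeric(),
                    cluster_p = numeric())
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  for (i in keep) {
    seg <- starts[i]:ends[i]
    p <- NA_real_
    if (!is.null(statistic) && !is.null(dof) && !is.null(fwhm)) {
      p <- rft_cluster_p(length(seg), critical, statistic, dof, fwhm,
                         n_nodes = length(field), two_tailed = two_tailed)
    }
    out <- rbind(out, data.frame(start_node = starts[i] - 1L,
                                 end_node = ends[i] - 1L,
                                 extent_nodes = length(seg),
                                 max_stat = field[seg][which.max(x[seg])],
                                 cluster_p = p))
  }
  out
}

## Cluster-extent p-value, 1D form of the classic Gaussian-field cluster
## approximation: P ~ 1 - exp(-E[m] * P(extent >= k)), with
## P(extent >= k) = exp(-beta k^2), beta = (Gamma(3/2) E[m]/E[N])^2,
## extents in resels.
rft_cluster_p <- function(extent_nodes, u, statistic, dof, fwhm, n_nodes,
                          two_tailed = TRUE) {
  if (statistic == "T2") {   # exact monotone transform to the F field
    nu <- dof[1]; p <- dof[2]
    u <- u * (nu - p + 1) / (nu * p)
    dof <- c(p, nu - p + 1)
    statistic <- "F"
    two_tailed <- FALSE
  }
  resels <- (n_nodes - 1) / fwhm
  d <- ec_density(statistic, u, dof)
  mult <- if (statistic %in% c("t", "gauss") && two_tailed) 2 else 1
  Em <- mult * resels * d$ec1          # expected number of clusters
  EN <- mult * resels * d$ec0          # expected suprathreshold resels
  if (Em <= 0 || EN <= 0) return(NA_real_)
  k <- extent_nodes / fwhm
  beta <- (gamma(1.5) * Em / EN)^2
  p_ext <- exp(-beta * k^2)
  1 - exp(-Em * p_ext)
}

#' Sidak-adjusted alpha for post-hoc comparisons
#'
#' `1 - (1 - alpha)^(1/k)`.
#'
#' @param alpha family-wise level.
#' @param k number of comparisons (>= 1).
#' @return per-comparison alpha.
#' @export
sidak_alpha <- function(alpha, k) {
  if (k < 1) stop_config("k", "must be >= 1")
  1 - (1 - alpha)^(1 / k)
}

#' Permutation critical threshold for a statistic field
#'
#' Nonparametric family-wise threshold: the `(1 - alpha)` quantile of the
#' maximum statistic over nodes across label permutations (independent
#' designs) or sign flips of the paired differences. Serves as the
#' distribution-free oracle for [rft_threshold()].
#'
#' @param matrix_a,matrix_b scalar matrices (subjects x nodes) or
#'   3-dimensional arrays for T2.
#' @param statistic_name `"t"`, `"F"`, or `"T2"` (matched to the inputs).
#' @param paired logical.
#' @param n_perm number of permutations (>= 100); the observed labelling is
#'   always included.
#' @param seed integer seed; output is deterministic given the seed.
#' @param alpha family-wise level.
#' @param two_tailed maximum of `|t|` for scalar t fields.
#' @return critical value, with attribute `max_dist` (the permutation
#'   distribution of the field maximum).
#' @export
permutation_threshold <- function(matrix_a, matrix_b,
                                  statistic_name = c("t", "F", "T2"),
                                  paired = FALSE, n_perm = 1000, seed = 1,
                                  alpha = 0.05, two_tailed = TRUE) {
  statistic_name <- match.arg(statistic_name)
  if (n_perm < 100) stop_config("n_perm", "must be >= 100")
  n1 <- dim(as.array(matrix_a))[1]; n2 <- dim(as.array(matrix_b))[1]
  n_distinct <- if (paired) 2^n1 else choose(n1 + n2, n1)
  if (n_distinct < 1 / alpha)
    stop("too few distinct permutations for the requested alpha", call. = FALSE)

  stat_max <- function(a, b) {
    f <- switch(statistic_name,
                t = t_field(a, b, paired = paired),
                F = f_field(list(a, b)),
                T2 = hotelling_t2_field(a, b, paired = paired))
    if (statistic_name == "t" && two_tailed) max(abs(f$field)) else max(f$field)
  }

  with_seed(seed, {
    scalar <- length(dim(as.array(matrix_a))) == 2
    maxes <- numeric(n_perm)
    maxes[1] <- stat_max(matrix_a, matrix_b)   # observed labelling
    if (paired) {
      d <- if (scalar) as.matrix(matrix_a) - as.matrix(matrix_b)
           else matrix_a - matrix_b
      zero <- if (scalar) matrix(0, nrow(d), ncol(d)) else array(0, dim(d))
      for (i in seq_len(n_perm - 1)) {
        s <- sample(c(-1, 1), n1, replace = TRUE)
        ds <- if (scalar) d * s else d * array(s, dim(d))
        maxes[i + 1] <- stat_max(ds, zero)
      }
    } else {
      pooled <- if (scalar) rbind(as.matrix(matrix_a), as.matrix(matrix_b))
                else abind3(matrix_a, matrix_b)
      for (i in seq_len(n_perm - 1)) {
        idx <- sample(n1 + n2)
        if (scalar) {
          maxes[i + 1] <- stat_max(pooled[idx[1:n1], , drop = FALSE],
                                   pooled[idx[(n1 + 1):(n1 + n2)], , drop = FALSE])
        } else {
          maxes[i + 1] <- stat_max(pooled[idx[1:n1], , , drop = FALSE],
                                   pooled[idx[(n1 + 1):(n1 + n2)], , , drop = FALSE])
        }
      }
    }
    crit <- stats::quantile(maxes, 1 - alpha, names = FALSE, type = 7)
    attr(crit, "max_dist") <- maxes
    crit
  })
}

## paired sign flips for T2 compare the flipped differences against zero via
## the one-sample (paired) T2, so `paired = TRUE` there is correct.

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' Full SPM inference for a trajectory comparison
#'
#' Convenience wrapper: computes the requested statistic field, estimates
#' residual smoothness, finds the critical threshold (RFT by default, or the
#' permutation oracle), and extracts suprathreshold clusters.
#'
#' @param matrix_a,matrix_b subjects x nodes matrices (t/F) or subjects x
#'   nodes x components arrays (T2).
#' @param statistic `"t"`, `"F"`, or `"T2"`.
#' @param paired logical (t/T2).
#' @param alpha family-wise level.
#' @param method `"rft"` or `"perm"`.
#' @param n_perm,seed permutation settings for `method = "perm"`.
#' @param two_tailed two-sided thresholding of scalar t fields.
#' @return object of class `spm_field`.
#' @export
spm_test <- function(matrix_a, matrix_b, statistic = c("t", "F", "T2"),
                     paired = FALSE, alpha = 0.05,
                     method = c("rft", "perm"), n_perm = 1000, seed = 1,
                     two_tailed = TRUE) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  f <- switch(statistic,
              t = t_field(matrix_a, matrix_b, paired = paired),
              F = f_field(list(matrix_a, matrix_b)),
              T2 = hotelling_t2_field(matrix_a, matrix_b, paired = paired))
  fwhm <- estimate_fwhm(f$residuals)
  n_nodes <- length(f$field)
  crit <- if (method == "rft") {
    rft_threshold(statistic, f$dof, n_nodes, fwhm, alpha, two_tailed)
  } else {
    as.numeric(permutation_threshold(matrix_a, matrix_b, statistic,
                                     paired = paired, n_perm = n_perm,
                                     seed = seed, alpha = alpha,
                                     two_tailed = two_tailed))
  }
  cl <- suprathreshold_clusters(f$field, crit,
                                two_tailed = statistic == "t" && two_tailed,
                                statistic = if (method == "rft") statistic else NULL,
                                dof = f$dof, fwhm = fwhm)
  structure(list(statistic = statistic, field = f$field, dof = f$dof,
                 fwhm = fwhm, critical = crit, clusters = cl,
                 alpha = alpha, method = method,
                 two_tailed = statistic == "t" && two_tailed,
                 residuals = f$residuals),
            class = "spm_field")
}

#' @export
print.spm_field <- function(x, ...) {
  dof <- paste(round(x$dof, 2), collapse = ", ")
  cat(sprintf("SPM{%s} field: %d nodes, dof (%s), FWHM %.1f nodes\n",
              x$statistic, length(x$field), dof, x$fwhm))
  cat(sprintf("  critical threshold (%s, alpha = %g%s): %.3f\n",
              x$method, x$alpha, if (x$two_tailed) ", two-sided" else "",
              x$critical))
  if (nrow(x$clusters)) {
    cat("  suprathreshold clusters (% of stance):\n")
    print(x$clusters, row.names = FALSE)
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Plot an SPM field
#'
#' Statistic field over stance with the critical threshold and
#' suprathreshold clusters marked as the conventional black bars below the
#' curve.
#'
#' @param x an `spm_field`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spm_field <- function(x, ...) {
  pct <- seq(0, 100, length.out = length(x$field))
  ylim <- range(c(x$field, x$critical, -x$critical, 0))
  graphics::plot(pct, x$field, type = "l", lwd = 2,
                 xlab = "stance (%)",
                 ylab = sprintf("SPM{%s}", x$statistic), ylim = ylim, ...)
  graphics::abline(h = x$critical, lty = 2, col = "red")
  if (x$two_tailed) graphics::abline(h = -x$critical, lty = 2, col = "red")
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters)) {
    y <- ylim[1]
    for (i in seq_len(nrow(x$clusters)))
      graphics::segments(x$clusters$start_node[i], y, x$clusters$end_node[i], y,
                         lwd = 6)
  }
  invisible(x)
}

#' Generate smooth unit-variance Gaussian null fields
#'
#' White noise convolved with a Gaussian kernel whose FWHM equals the
#' requested field smoothness (the kernel FWHM is the field FWHM for
#' Gaussian autocorrelation), rescaled to unit pointwise variance. Used by
#' the Monte-Carlo validation of the RFT machinery.
#'
#' @param n number of fields (rows).
#' @param n_nodes nodes per field.
#' @param fwhm field smoothness in nodes.
#' @return matrix `n x n_nodes`.
#' @export
smooth_gaussian_fields <- function(n, n_nodes, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sqrt(sum(kern^2))   # unit output variance
  pad <- n_nodes + 2 * half
  z <- matrix(stats::rnorm(n * pad), n, pad)
  out <- matrix(0, n, n_nodes)
  for (i in seq_len(n)) {
    cv <- stats::convolve(z[i, ], rev(kern), type = "filter")
    out[i, ] <- cv[seq_len(n_nodes)]
  }
  out
}
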