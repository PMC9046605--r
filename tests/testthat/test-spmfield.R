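test_that("t field matches the per-node textbook statistic", {
  set.seed(41)
  A <- matrix(rnorm(8 * 31), 8)
  B <- matrix(rnorm(9 * 31), 9) + 0.4
  f <- t_field(A, B)
  oracle <- sapply(1:31, function(j)
    t.test(A[, j], B[, j], var.equal = TRUE)$statistic)
  expect_equal(f$field, unname(oracle), tolerance = 1e-10)
  expect_equal(f$dof, 15)
  # paired
  P <- matrix(rnorm(10 * 31), 10); Q <- P + matrix(rnorm(10 * 31, 0.2), 10)
  fp <- t_field(P, Q, paired = TRUE)
  op <- sapply(1:31, function(j) t.test(P[, j], Q[, j], paired = TRUE)$statistic)
  expect_equal(fp$field, unname(op), tolerance = 1e-10)
  expect_equal(fp$dof, 9)
  # constant trajectories reproduce the scalar t at every node
  Ac <- matrix(rep(rnorm(8), 31), 8)
  Bc <- matrix(rep(rnorm(9), 31), 9)
  fc <- t_field(Ac, Bc)
  expect_equal(fc$field, rep(fc$field[1], 31), tolerance = 1e-10)
  expect_equal(fc$field[1],
               unname(t.test(Ac[, 1], Bc[, 1], var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  # identical groups give the zero field
  expect_equal(t_field(A, A)$field, rep(0, 31))
})

test_that("F field equals squared t for two groups and matches aov for three", {
  set.seed(42)
  A <- matrix(rnorm(8 * 21), 8); B <- matrix(rnorm(9 * 21), 9) + 0.5
  expect_equal(f_field(list(A, B))$field, t_field(A, B)$field^2,
               tolerance = 1e-9)
  C <- matrix(rnorm(7 * 21), 7) - 0.3
  f3 <- f_field(list(A, B, C))
  expect_equal(f3$dof, c(2, 21))
  oracle <- sapply(1:21, function(j) {
    y <- c(A[, j], B[, j], C[, j])
    g <- factor(rep(1:3, c(8, 9, 7)))
    summary(aov(y ~ g))[[1]]$`F value`[1]
  })
  expect_equal(f3$field, oracle, tolerance = 1e-10)
  expect_equal(f_field(list(A, A))$field, rep(0, 21))
})

test_that("Hotelling T2 field reduces to t-squared and matches the oracle", {
  set.seed(43)
  A <- matrix(rnorm(10 * 11), 10); B <- matrix(rnorm(12 * 11), 12)
  h1 <- hotelling_t2_field(array(A, c(10, 11, 1)), array(B, c(12, 11, 1)))
  expect_equal(h1$field, t_field(A, B)$field^2, tolerance = 1e-10)
  # constant-in-time 3-component vectors equal the classic two-sample T2
  Xa <- matrix(rnorm(10 * 3), 10); Xb <- matrix(rnorm(12 * 3, 0.5), 12)
  Aa <- array(0, c(10, 5, 3)); Bb <- array(0, c(12, 5, 3))
  for (j in 1:5) { Aa[, j, ] <- Xa; Bb[, j, ] <- Xb }
  h3 <- hotelling_t2_field(Aa, Bb)
  S <- (crossprod(scale(Xa, scale = FALSE)) +
          crossprod(scale(Xb, scale = FALSE))) / 20
  d <- colMeans(Xa) - colMeans(Xb)
  T2 <- (10 * 12 / 22) * drop(t(d) %*% solve(S) %*% d)
  expect_equal(h3$field, rep(T2, 5), tolerance = 1e-9)
  # paired version against the one-sample oracle on differences
  Pa <- array(rnorm(9 * 5 * 2), c(9, 5, 2)); Pb <- array(rnorm(9 * 5 * 2), c(9, 5, 2))
  hp <- hotelling_t2_field(Pa, Pb, paired = TRUE)
  D <- Pa[, 2, ] - Pb[, 2, ]
  mu <- colMeans(D)
  T2p <- 9 * drop(t(mu) %*% solve(cov(D)) %*% mu)
  expect_equal(hp$field[2], T2p, tolerance = 1e-9)
  # identical arrays: zero field, with the singular-covariance warning
  expect_warning(z <- hotelling_t2_field(Aa, Aa, paired = TRUE), "singular")
  expect_equal(z$field, rep(0, 5))
})

test_that("fields are invariant under shared affine maps", {
  set.seed(44)
  A <- matrix(rnorm(10 * 21), 10); B <- matrix(rnorm(10 * 21), 10) + 0.3
  sc <- runif(21, 0.5, 3); sh <- rnorm(21)
  A2 <- sweep(sweep(A, 2, sc, `*`), 2, sh, `+`)
  B2 <- sweep(sweep(B, 2, sc, `*`), 2, sh, `+`)
  expect_equal(t_field(A2, B2)$field, t_field(A, B)$field, tolerance = 1e-9)
  expect_equal(f_field(list(A2, B2))$field, f_field(list(A, B))$field,
               tolerance = 1e-9)
  # T2: common invertible linear map of the components
  Aa <- array(rnorm(10 * 7 * 3), c(10, 7, 3))
  Bb <- array(rnorm(12 * 7 * 3, 0.3), c(12, 7, 3))
  M <- matrix(c(1, 0.4, -0.2, 0, 1.5, 0.3, 0.2, -0.1, 0.8), 3)
  tr <- function(a) {
    out <- a
    for (j in 1:dim(a)[2]) out[, j, ] <- matrix(a[, j, ], ncol = 3) %*% t(M)
    out
  }
  expect_equal(hotelling_t2_field(tr(Aa), tr(Bb))$field,
               hotelling_t2_field(Aa, Bb)$field, tolerance = 1e-8)
})

test_that("FWHM estimation recovers known smoothness and is scale-free", {
  set.seed(45)
  # white noise: smoothness near the node scale
  expect_lt(estimate_fwhm(matrix(rnorm(50 * 101), 50)), 3)
  # smoothed noise with kernel FWHM 20: mean estimate within 2 nodes
  est <- replicate(120, estimate_fwhm(smooth_gaussian_fields(10, 101, 20)))
  expect_lt(abs(mean(est) - 20), 2)
  R <- smooth_gaussian_fields(10, 101, 15)
  expect_equal(estimate_fwhm(10 * R), estimate_fwhm(R), tolerance = 1e-12)
  Rz <- cbind(R, 0)
  expect_warning(estimate_fwhm(Rz), "zero-variance")
})

test_that("RFT threshold has the right limits and orderings", {
  # very smooth field: the single-test quantile
  expect_equal(rft_threshold("t", 20, 101, 1e9, 0.05), qt(0.975, 20),
               tolerance = 1e-5)
  expect_equal(rft_threshold("t", 20, 101, 1e9, 0.05, two_tailed = FALSE),
               qt(0.95, 20), tolerance = 1e-5)
  # monotone decreasing in smoothness, always above the pointwise quantile
  u <- sapply(c(2, 5, 10, 25, 50), function(w) rft_threshold("t", 20, 101, w))
  expect_true(all(diff(u) < 0))
  expect_true(all(u > qt(0.975, 20)))
  # at moderate smoothness the threshold is below the Bonferroni bound
  expect_lt(rft_threshold("t", 20, 101, 10), qt(1 - 0.025 / 101, 20))
  # F threshold consistent with the squared two-sided t threshold (k = 1)
  ut <- rft_threshold("t", 20, 101, 15, 0.05)
  uf <- rft_threshold("F", c(1, 20), 101, 15, 0.05)
  expect_equal(uf, ut^2, tolerance = 1e-4)
  # T2 with one component is the F threshold under the exact transform
  u2 <- rft_threshold("T2", c(nu = 20, p = 1), 101, 15, 0.05)
  expect_equal(u2, uf, tolerance = 1e-9)
  expect_error(rft_threshold("t", 20, 101, -1), "fwhm")
  expect_error(rft_threshold("t", 20, 101, 10, alpha = 0.7), "alpha")
})

test_that("suprathreshold clusters are maximal runs in stance percent", {
  f <- rep(0, 101)
  expect_equal(nrow(suprathreshold_clusters(f, 2)), 0)
  f[81:97] <- 3   # nodes 80..96 in 0-based stance percent
  cl <- suprathreshold_clusters(f, 2)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_node, cl$end_node), c(80, 96))
  f[11:16] <- -4  # negative excursion, two-sided clustering
  cl2 <- suprathreshold_clusters(f, 2)
  expect_equal(cl2$start_node, c(10, 80))
  expect_equal(cl2$end_node, c(15, 96))
  cl3 <- suprathreshold_clusters(f, 2, two_tailed = FALSE)
  expect_equal(nrow(cl3), 1)
  # cluster p-values are in (0, 1] and shrink with extent
  long_p <- suprathreshold_clusters(f, 2, statistic = "t", dof = 20,
                                    fwhm = 10)$cluster_p
  expect_true(all(long_p > 0 & long_p <= 1))
  expect_lt(long_p[2], long_p[1])
})

test_that("Sidak adjustment has its closed form and Bonferroni bound", {
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  expect_equal(sidak_alpha(0.05, 3), 1 - 0.95^(1 / 3), tolerance = 1e-12)
  expect_equal(sidak_alpha(0.05, 3), 0.016952, tolerance = 1e-4)
  for (k in 1:8) expect_gte(sidak_alpha(0.05, k), 0.05 / k)
  expect_error(sidak_alpha(0.05, 0), "k")
})

test_that("permutation threshold is seed-deterministic and guards degeneracy", {
  set.seed(46)
  A <- smooth_gaussian_fields(10, 51, 12)
  B <- smooth_gaussian_fields(10, 51, 12)
  u1 <- permutation_threshold(A, B, "t", n_perm = 200, seed = 7)
  u2 <- permutation_threshold(A, B, "t", n_perm = 200, seed = 7)
  expect_identical(as.numeric(u1), as.numeric(u2))
  u3 <- permutation_threshold(A, B, "t", n_perm = 200, seed = 8)
  expect_false(identical(as.numeric(u1), as.numeric(u3)))
  # too few distinct relabellings for the requested alpha
  expect_error(permutation_threshold(A[1:2, ], B[1:2, ], "t", n_perm = 200,
                                     alpha = 0.05),
               "distinct permutations")
  expect_error(permutation_threshold(A, B, "t", n_perm = 50), "n_perm")
})

test_that("spm_test assembles inference and the plot method runs", {
  set.seed(47)
  A <- smooth_gaussian_fields(12, 101, 20)
  B <- smooth_gaussian_fields(12, 101, 20)
  B[, 40:60] <- B[, 40:60] + 2
  s <- spm_test(A, B, "t")
  expect_s3_class(s, "spm_field")
  expect_gt(nrow(s$clusters), 0)
  expect_true(all(abs(s$field)[s$clusters$start_node[1]:s$clusters$end_node[1] + 1] >
                    s$critical))
  expect_output(print(s), "SPM\\{t\\}")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(s); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
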