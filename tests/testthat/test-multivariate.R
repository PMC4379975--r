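test_that("euclidean_distance is the standard metric", {
  d <- euclidean_distance(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(euclidean_distance(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  set.seed(21)
  x <- matrix(rnorm(100 * 3), 100)
  D <- euclidean_distance(x)
  for (i in 1:50) {
    ijk <- sample(100, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("pcoa reconstructs Euclidean-embeddable distances", {
  # collinear points at 0, 3, 7 -> one positive axis
  D <- as.matrix(dist(c(0, 3, 7)))
  p <- pcoa(D)
  expect_equal(ncol(p$vectors), 1L)
  expect_equal(as.matrix(dist(p$vectors)), D, ignore_attr = TRUE)

  # three unit-equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa(D3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-10]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2])

  expect_equal(ncol(pcoa(matrix(0, 3, 3))$vectors), 0L)

  set.seed(31)
  x <- matrix(rnorm(12 * 4), 12)
  D <- euclidean_distance(x)
  p <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(p$vectors)) - D)), 1e-8)
  # eigenvalues agree with an independent implementation
  ref <- ape::pcoa(D)
  expect_equal(p$eigenvalues[seq_along(ref$values$Eigenvalues)],
               ref$values$Eigenvalues, tolerance = 1e-8)
})

test_that("one-factor pseudo-F equals classical ANOVA F on univariate data", {
  x <- c(0, 1, 4, 5)
  f <- factor(c("a", "a", "b", "b"))
  D <- euclidean_distance(matrix(x, ncol = 1))
  res <- permanova(D, f, n_perm = 99)
  expect_true(res$exhaustive)
  expect_equal(res$table$pseudo_F, 32, tolerance = 1e-12)
  expect_equal(res$table$p_value, 1 / 3)  # 2 of 6 arrangements reach F
  expect_equal(res$ss_total, res$table$SS + res$ss_within)

  set.seed(41)
  for (i in 1:10) {
    y <- rnorm(12)
    g <- factor(rep(c("a", "b", "c"), each = 4))
    Dy <- euclidean_distance(matrix(y, ncol = 1))
    pf <- permanova(Dy, g, n_perm = 19, seed = i)$table$pseudo_F
    ref <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pf, ref, tolerance = 1e-10)
  }
})

test_that("permanova agrees with vegan::adonis2 and respects p bounds", {
  set.seed(51)
  x <- matrix(rnorm(18 * 3), 18)
  x[1:6, 1] <- x[1:6, 1] + 2
  g <- factor(rep(c("a", "b", "c"), each = 6))
  D <- euclidean_distance(x)
  res <- permanova(D, g, n_perm = 199, seed = 4)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 199)
  expect_equal(res$table$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(res$table$SS, ref$SumOfSqs[1], tolerance = 1e-8)
  expect_gte(res$table$p_value, 1 / 200)
  expect_lte(res$table$p_value, 1)

  # two crossed factors, main effects only
  ab <- expand.grid(A = c("x", "y"), B = c("u", "v", "w"))
  ab <- ab[rep(1:6, 3), ]
  set.seed(52)
  y <- matrix(rnorm(18 * 2), 18)
  y[ab$A == "x", 1] <- y[ab$A == "x", 1] + 1.5
  Dy <- euclidean_distance(y)
  res2 <- permanova(Dy, ab, n_perm = 99, seed = 9)
  ref2 <- vegan::adonis2(as.dist(Dy) ~ A + B, data = ab,
                         permutations = 99, by = "terms")
  expect_equal(res2$table$pseudo_F, ref2$F[1:2], tolerance = 1e-8)
  expect_equal(res2$df_residual, ref2$Df[3])

  expect_error(permanova(D, factor(rep("a", 18))), "single level")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(61)
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (i in 1:n_rep) {
    y <- rnorm(10)
    g <- factor(rep(c("a", "b"), each = 5))
    D <- euclidean_distance(matrix(y, ncol = 1))
    pvals[i] <- permanova(D, g, n_perm = 125)$table$p_value
  }
  # exhaustive mode (252 arrangements, but F is symmetric) -- p uniform-ish
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise posthoc t is the square root of the pairwise pseudo-F", {
  x <- c(0, 1, 4, 5)
  f <- factor(c("a", "a", "b", "b"))
  D <- euclidean_distance(matrix(x, ncol = 1))
  ph <- pairwise_posthoc(D, f, n_perm = 99)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$t, sqrt(32), tolerance = 1e-12)
  expect_equal(ph$t^2, permanova(D, f, n_perm = 9)$table$pseudo_F,
               tolerance = 1e-12)

  # three groups with identical composition: t ~ 0, p near 1
  z <- rbind(c(0, 0), c(1, 1), c(2, 2))[rep(1:3, 3), ]
  g3 <- factor(rep(c("a", "b", "c"), each = 3))
  Dz <- euclidean_distance(z)
  ph3 <- pairwise_posthoc(Dz, g3, n_perm = 49, seed = 2)
  expect_equal(nrow(ph3), 3L)
  expect_true(all(abs(ph3$t) < 1e-6))
  expect_true(all(ph3$p_value > 0.9))
})

test_that("cap_correlation finds perfect, null and closed-form correlations", {
  set.seed(71)
  x <- matrix(rnorm(10 * 3), 10)
  D <- euclidean_distance(x)
  res <- cap_correlation(D, D, n_perm = 49, seed = 1)
  expect_equal(res$delta2_1, 1, tolerance = 1e-10)
  expect_true(all(res$squared_correlations >= 0 &
                    res$squared_correlations <= 1 + 1e-12))

  # 4 objects with known 1-d coordinates: delta^2_1 is the squared
  # correlation computed directly from the coordinates
  xs <- c(0, 1, 3, 6)
  ys <- c(1, 0, 2, 5)
  r <- cap_correlation(euclidean_distance(matrix(xs)),
                       euclidean_distance(matrix(ys)),
                       m_axes = 1, n_perm = 23, seed = 3)
  expect_equal(r$delta2_1, cor(xs, ys)^2, tolerance = 1e-10)

  # null behaviour: independent data rarely give small p
  rejections <- 0L
  for (i in 1:60) {
    set.seed(100 + i)
    a <- matrix(rnorm(12 * 2), 12)
    b <- matrix(rnorm(12 * 2), 12)
    p <- cap_correlation(euclidean_distance(a), euclidean_distance(b),
                         n_perm = 199, seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 6L)  # >= 95% of runs keep p > 0.05 (with slack)
  expect_error(cap_correlation(D, D, m_axes = 10), "m_axes")
})

test_that("exhaustive permanova has no hidden order dependence", {
  set.seed(81)
  y <- rnorm(8)
  g <- factor(rep(c("a", "b"), each = 4))
  D <- euclidean_distance(matrix(y, ncol = 1))
  res <- permanova(D, g, n_perm = 100)
  idx <- sample(8)
  res2 <- permanova(D[idx, idx], g[idx], n_perm = 100)
  expect_true(res$exhaustive && res2$exhaustive)
  expect_equal(res$table$pseudo_F, res2$table$pseudo_F, tolerance = 1e-10)
  expect_equal(res$table$p_value, res2$table$p_value)
})
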