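make_labels <- function(n1, n2) {
  data.frame(subject_id = sprintf("s%02d", seq_len(n1 + n2)),
             group = rep(c("A", "B"), c(n1, n2)), stringsAsFactors = FALSE)
}

make_grouped <- function(mat, n1, n2, ...) {
  rownames(mat) <- sprintf("s%02d", seq_len(n1 + n2))
  build_curves(mat, make_labels(n1, n2), ...)
}

test_that("curve building: knot interpolation, constants, spline oracle", {
  set.seed(3)
  mat <- matrix(rnorm(4 * 22, 100, 10), 4, 22)
  g <- make_grouped(mat, 2, 2)
  # interpolant passes through the knots
  at_knots <- t(vapply(g$splines, function(f) f(g$knots), numeric(22)))
  expect_equal(unname(at_knots), unname(mat), tolerance = 1e-9)

  cmat <- matrix(7, 4, 22)
  gc <- make_grouped(cmat, 2, 2)
  expect_true(all(abs(gc$dense_values - 7) < 1e-9))

  # dense evaluation matches an independently solved natural cubic spline
  tpts <- sort(runif(10, 1, 22))
  for (j in 1:2) {
    oracle <- oracle_natural_spline(g$knots, mat[j, ], tpts)
    mine <- vapply(tpts, function(t) g$splines[[j]](t), numeric(1))
    expect_equal(mine, oracle, tolerance = 1e-8)
  }

  expect_error(build_curves(matrix(1, 3, 5), make_labels(2, 1)),
               class = "qar_shape_error")   # no rownames
  df <- data.frame(subject_id = c("a", "a", "b"), minute = c(1, 2, 1),
                   qar_score = 1:3)         # ragged long input
  expect_error(build_curves(df, data.frame(subject_id = c("a", "b"),
                                           group = c("A", "B"))),
               class = "qar_shape_error")
})

test_that("pointwise F: zero under equal means, hand ANOVA, oracle sweep", {
  # mirrored data with coinciding group means
  mat <- rbind(c(1, 2, 3), c(3, 2, 1), c(0, 2, 4), c(4, 2, 0))
  mat22 <- cbind(mat, matrix(2, 4, 19))
  g <- make_grouped(mat22, 2, 2)
  expect_equal(pointwise_F(g, t = 2), 0)

  g2 <- make_grouped(cbind(c(0, 2, 3, 5), matrix(1, 4, 21)), 2, 2)
  expect_equal(pointwise_F(g2, t = 1), 4.5)    # SSB 9, SSW 4 => (9/1)/(4/2)

  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- matrix(rnorm((n1 + n2) * 5), n1 + n2, 5)
    gg <- make_grouped(vals, n1, n2)
    t0 <- sample(gg$dense_grid, 1)
    v <- gg$dense_values[, match(t0, gg$dense_grid)]
    expect_equal(pointwise_F(gg, t = t0),
                 oracle_anova_F(v, gg$group), tolerance = 1e-10)
  }
})

test_that("GPF and Fmax match quadrature/max oracles and degenerate nulls", {
  set.seed(5)
  mat <- matrix(rnorm(10 * 22, 50, 5), 10, 22)
  mat[6:10, ] <- mat[6:10, ] + 3
  g <- make_grouped(mat, 5, 5)
  res <- fanova_tests(g, n_resamples = 199, seed = 4)
  FF <- pointwise_F(g)
  expect_equal(res$gpf$statistic,
               oracle_trapz(g$dense_grid, FF) / diff(range(g$dense_grid)),
               tolerance = 1e-10)
  expect_identical(res$fmax$statistic, max(FF))

  # identical groups curve-for-curve: F == 0 everywhere, p = 1
  dup <- rbind(mat[1:5, ], mat[1:5, ])
  gdup <- make_grouped(dup, 5, 5)
  resdup <- fanova_tests(gdup, n_resamples = 99, seed = 1)
  expect_equal(resdup$gpf$statistic, 0)
  expect_equal(resdup$fmax$statistic, 0)
  expect_equal(resdup$gpf$p_value, 1)
  expect_equal(resdup$fmax$p_value, 1)
})

test_that("permutation p-values: range, reproducibility, label-swap symmetry", {
  set.seed(9)
  mat <- matrix(rnorm(12 * 22), 12, 22)
  g <- make_grouped(mat, 5, 7)
  B <- 199
  r1 <- fanova_tests(g, B, seed = 31)
  r2 <- fanova_tests(g, B, seed = 31)
  expect_identical(r1$gpf$p_value, r2$gpf$p_value)
  expect_identical(r1$fmax$p_value, r2$fmax$p_value)
  for (r in r1) {
    expect_gte(r$p_value, 1 / (B + 1))
    expect_lte(r$p_value, 1)
  }

  labs <- make_labels(5, 7)
  labs$group <- ifelse(labs$group == "A", "B", "A")   # swap labels
  rownames(mat) <- labs$subject_id
  gsw <- build_curves(mat, labs)
  rsw <- fanova_tests(gsw, B, seed = 31)
  expect_equal(rsw$gpf$statistic, r1$gpf$statistic)
  expect_equal(rsw$fmax$statistic, r1$fmax$statistic)
  expect_identical(rsw$gpf$p_value, r1$gpf$p_value)
  expect_identical(rsw$fmax$p_value, r1$fmax$p_value)

  expect_warning(fanova_tests(g, 50, seed = 1), "resamples")
})

test_that("velocity: constants, linear slope, finite-difference oracle", {
  gconst <- make_grouped(matrix(4, 4, 22), 2, 2)
  vconst <- velocity(gconst)
  expect_true(all(abs(vconst$dense_values) < 1e-9))

  lin <- outer(rep(1, 4), 2.5 * (1:22))
  glin <- make_grouped(lin, 2, 2)
  vlin <- velocity(glin)
  expect_equal(unname(vlin$dense_values),
               matrix(2.5, 4, 221), tolerance = 1e-9)

  smooth <- outer(rep(1, 4), 10 + 5 * sin((1:22) / 4))
  gsm <- make_grouped(smooth, 2, 2)
  vsm <- velocity(gsm)
  f <- gsm$splines[[1]]
  h <- 1e-3
  for (k in c(5, 9, 14, 18)) {
    fd <- (f(k + h) - f(k - h)) / (2 * h)
    vk <- vsm$dense_values[1, which.min(abs(gsm$dense_grid - k))]
    expect_equal(unname(vk), unname(fd), tolerance = 0.05)
  }
})

test_that("pointwise distributions: constants, definition, oracle, range", {
  g <- make_grouped(matrix(c(rep(2, 22 * 2), rep(5, 22 * 2)), 4, 22,
                           byrow = TRUE), 2, 2)
  pw <- pointwise_distribution(g)
  expect_equal(sort(unique(pw$means$time)), c(3, 7, 9, 11, 22))
  expect_equal(pw$means$mean[pw$means$group == "A"], rep(2, 5),
               tolerance = 1e-9)
  expect_equal(pw$means$mean[pw$means$group == "B"], rep(5, 5),
               tolerance = 1e-9)

  set.seed(2)
  gr <- make_grouped(matrix(rnorm(6 * 22), 6, 22), 3, 3)
  pwr <- pointwise_distribution(gr, times = c(3, 11))
  for (tm in c(3, 11)) {
    for (grp in levels(gr$group)) {
      direct <- mean(vapply(which(gr$group == grp),
                            function(j) gr$splines[[j]](tm), numeric(1)))
      expect_equal(pwr$means$mean[pwr$means$time == tm &
                                    pwr$means$group == grp], direct)
    }
  }
  expect_error(pointwise_distribution(gr, times = 30),
               class = "qar_range_error")
})

test_that("spearman correlation: perfect ranks, ties vs midrank oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)

  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:4, 6, replace = TRUE)   # heavy ties
    b <- sample(1:4, 6, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_corr(a, b)$rho, oracle_spearman_rho(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5), class = "qar_contract_error")
  expect_error(spearman_corr(1:2, 1:2), class = "qar_contract_error")
})

test_that("curve totals: rectangle area, zero curve, fine-grid oracle", {
  gconst <- make_grouped(matrix(3, 4, 22), 2, 2)
  expect_equal(unname(curve_total(gconst)), rep(63, 4), tolerance = 1e-9)
  gzero <- make_grouped(matrix(0, 4, 22), 2, 2)
  expect_equal(unname(curve_total(gzero)), rep(0, 4))

  smooth <- outer(rep(1, 4), 10 + 5 * sin((1:22) / 4))
  gsm <- make_grouped(smooth, 2, 2)
  f <- gsm$splines[[1]]
  fine <- seq(1, 22, length.out = 20001)
  riemann <- sum(f(fine[-1]) * diff(fine))
  expect_equal(unname(curve_total(gsm)[1]), riemann, tolerance = 1e-3)
})

test_that("scalar comparisons: exact rank-sum, rank invariance, chi-square", {
  p <- scalar_group_compare(c(1, 2, 3, 4), c("a", "a", "b", "b"), "ranksum")
  expect_equal(p, 1 / 3, tolerance = 1e-12)
  expect_equal(p, oracle_ranksum_p(c(1, 2), c(3, 4)), tolerance = 1e-12)

  set.seed(4)
  x <- rnorm(10)
  labs <- rep(c("a", "b"), 5)
  expect_equal(scalar_group_compare(x, labs, "ranksum"),
               scalar_group_compare(exp(x), labs, "ranksum"))

  tab_vals <- rep(c("m", "f"), c(12, 8))
  tab_grp <- rep(c("a", "b"), 10)
  expect_true(scalar_group_compare(tab_vals, tab_grp, "chisq") >= 0)
  expect_error(scalar_group_compare(1:3, rep("a", 3)),
               class = "qar_contract_error")
})

test_that("exact rank-sum p-values are uniform on their support under the null", {
  set.seed(12)
  pooled <- rnorm(10)
  pvals <- replicate(2000, {
    idx <- sample(10, 5)
    scalar_group_compare(pooled, replace(rep("b", 10), idx, "a"), "ranksum")
  })
  support <- sort(unique(pvals))
  # exactness: P(p <= s) == s at every support point, up to MC noise
  for (s in support) {
    expect_lt(abs(mean(pvals <= s) - s), 3 * sqrt(s * (1 - s) / 2000) + 1e-3)
  }
})
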