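test_that("RDA R2 and the Ezekiel adjustment match hand computation", {
  set.seed(24)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  x <- cbind(x1 = 1:5)
  fit <- lm(y ~ x)
  r2_hand <- summary(fit)$r.squared
  adj_hand <- 1 - (1 - r2_hand) * (5 - 1) / (5 - 1 - 1)
  out <- rda_r2(y, x)
  expect_equal(out$r2, r2_hand, tolerance = 1e-12)
  expect_equal(out$adj_r2, adj_hand, tolerance = 1e-12)
  expect_equal(summary(fit)$adj.r.squared, adj_hand, tolerance = 1e-12)
  # saturating predictors: R2 = 1
  Y <- matrix(rnorm(12), 6, 2)
  expect_equal(rda_r2(Y, Y)$r2, 1, tolerance = 1e-10)
  # empty model explains nothing
  expect_equal(rda_r2(Y, NULL)$adj_r2, 0)
  # rank deficiency is reported with the collinear column named
  X <- cbind(a = rnorm(6), b = rnorm(6))
  X <- cbind(X, dup = X[, "a"])
  expect_error(rda_r2(Y, X), "dup")
})

test_that("adjusted R2 of pure noise centers on zero", {
  set.seed(25)
  adj <- replicate(400, rda_r2(rnorm(30), matrix(rnorm(30 * 5), 30, 5))$adj_r2)
  expect_lt(abs(mean(adj)), 0.02)
})

test_that("variance partition collapses correctly in degenerate designs", {
  set.seed(26)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  E <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("e1", "e2")))
  # identical predictor sets: everything is shared
  vp <- variance_partition(Y, E, E + 0, nperm = 0)
  expect_equal(unname(vp$fractions["a"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp$fractions["c"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp$fractions["b"]), rda_r2(Y, E)$adj_r2,
               tolerance = 1e-10)
  # both sets empty: all unexplained
  vp0 <- variance_partition(Y, NULL, NULL, nperm = 0)
  expect_equal(unname(vp0$fractions), c(0, 0, 0, 1))
  expect_setequal(vp0$flags, c("no environmental variables",
                               "no spatial variables"))
  # one set empty: its pure and shared fractions are zero
  S <- matrix(rnorm(20 * 2), 20, 2)
  vp1 <- variance_partition(Y, NULL, S, nperm = 0)
  expect_equal(unname(vp1$fractions["a"]), 0)
  expect_equal(unname(vp1$fractions["b"]), 0)
  expect_equal(unname(vp1$fractions["c"]), rda_r2(Y, S)$adj_r2)
})

test_that("a noiseless environmental response gives a ~ 1, c ~ 0", {
  set.seed(27)
  n <- 40
  E <- matrix(rnorm(n * 2), n, 2)
  S <- qr.Q(qr(cbind(1, E, matrix(rnorm(n * 2), n, 2))))[, 4:5]  # S _|_ E
  Y <- E %*% c(1, -2)
  vp <- variance_partition(Y, E, S, nperm = 0)
  oracle <- varpart_oracle(Y, E, S)
  expect_equal(vp$fractions, oracle, tolerance = 1e-12)
  # d is exactly 0 (saturated fit); a and c deviate from 1 and 0 only by
  # the Ezekiel adjustment term of the S-only model, order m/(n - m - 1)
  adj_slack <- 2 * ncol(S) / (n - ncol(S) - 1)
  expect_lt(abs(unname(vp$fractions["d"])), 1e-10)
  expect_lt(abs(unname(vp$fractions["a"]) - 1), adj_slack)
  expect_lt(abs(unname(vp$fractions["c"])), adj_slack)
})

test_that("fractions agree with the independent oracle and with vegan", {
  set.seed(28)
  for (i in 1:10) {
    n <- 25
    Y <- matrix(rnorm(n * 3), n, 3)
    E <- matrix(rnorm(n * 3), n, 3)
    S <- matrix(rnorm(n * 2), n, 2)
    vp <- variance_partition(Y, E, S, nperm = 0)
    expect_equal(vp$fractions, varpart_oracle(Y, E, S), tolerance = 1e-12)
    expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
    expect_equal(unname(vp$fractions["a"] + vp$fractions["b"]),
                 rda_r2(Y, E)$adj_r2, tolerance = 1e-10)
    expect_equal(unname(vp$fractions["b"] + vp$fractions["c"]),
                 rda_r2(Y, S)$adj_r2, tolerance = 1e-10)
  }
  skip_if_not_installed("vegan")
  set.seed(29)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  E <- matrix(rnorm(30 * 3), 30, 3)
  S <- matrix(rnorm(30 * 2), 30, 2)
  vp <- variance_partition(Y, E, S, nperm = 0)
  vv <- vegan::varpart(Y, E, S)$part$indfract$Adj.R.square
  # vegan rows: pure X1, pure X2, shared, residual
  expect_equal(unname(vp$fractions[c("a", "c", "b", "d")]), vv,
               tolerance = 1e-10)
})

test_that("univariate and single-column-matrix partitions are identical", {
  set.seed(30)
  y <- rnorm(20)
  E <- matrix(rnorm(20 * 2), 20, 2)
  S <- matrix(rnorm(20 * 2), 20, 2)
  v1 <- variance_partition(y, E, S, nperm = 99, seed = 5)
  v2 <- variance_partition(cbind(y), E, S, nperm = 99, seed = 5)
  expect_identical(v1$fractions, v2$fractions)
  expect_identical(v1$p, v2$p)
  # and the univariate fractions match the partial-regression partition
  ab <- summary(lm(y ~ E))$adj.r.squared
  bc <- summary(lm(y ~ S))$adj.r.squared
  abc <- summary(lm(y ~ E + S))$adj.r.squared
  expect_equal(unname(v1$fractions["a"]), abc - bc, tolerance = 1e-12)
  expect_equal(unname(v1$fractions["b"]), ab + bc - abc, tolerance = 1e-12)
})

test_that("fraction tests behave at the boundaries", {
  set.seed(31)
  y <- rnorm(25)
  # perfect predictor: minimal achievable p
  t1 <- test_fraction(y, cbind(y), nperm = 199, seed = 7)
  expect_equal(t1$p, 1 / 200)
  # p invariant to relabeling of the conditioning columns
  E <- matrix(rnorm(25 * 2), 25, 2)
  S <- matrix(rnorm(25 * 3), 25, 3)
  t2 <- test_fraction(y, E, S, nperm = 199, seed = 9)
  t3 <- test_fraction(y, E, S[, c(3, 1, 2)], nperm = 199, seed = 9)
  expect_equal(t2$p, t3$p)
  expect_equal(t2$statistic, t3$statistic, tolerance = 1e-12)
})

test_that("significance codes follow the reporting thresholds", {
  expect_equal(signif_code(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("ns", "*", "**", "***", "-"))
})
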