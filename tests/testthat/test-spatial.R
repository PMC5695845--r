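named_d <- function(coords) {
  rownames(coords) <- paste0("P", seq_len(nrow(coords)))
  distance_matrix(coords)
}

test_that("distance matrix is a Euclidean metric and rejects lat/lon", {
  d <- named_d(cbind(x = c(0, 3), y = c(0, 4)))
  expect_equal(d[1, 2], 5)
  set.seed(3)
  co <- cbind(x = runif(7, 0, 100), y = runif(7, 0, 100))
  d <- named_d(co)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) {
    tri <- sample(7, 3)
    expect_lte(d[tri[1], tri[3]],
               d[tri[1], tri[2]] + d[tri[2], tri[3]] + 1e-12)
  }
  expect_error(distance_matrix(data.frame(lon = c(1, 2), lat = c(3, 4))),
               "project")
  expect_message(named_d(cbind(x = c(1, 1, 5), y = c(2, 2, 2))), "duplicate")
})

test_that("truncation threshold is the longest minimum spanning tree edge", {
  # regular transect: the MST is the chain, threshold = spacing
  tr <- gen_coords(8, 21, "transect")
  expect_equal(truncation_threshold(distance_matrix(tr)), 3)
  # two clusters: the bridge edge dominates
  co <- rbind(cbind(runif(4, 0, 10), runif(4, 0, 10)),
              cbind(runif(4, 500, 510), runif(4, 0, 10)))
  d <- named_d(co)
  gap <- min(d[1:4, 5:8])
  expect_equal(truncation_threshold(d), gap)
  # exhaustive spanning-tree enumeration oracle on tiny point sets
  set.seed(11)
  for (n in c(4, 5, 6)) {
    d <- named_d(cbind(runif(n, 0, 50), runif(n, 0, 50)))
    expect_equal(truncation_threshold(d), mst_longest_edge_oracle(d))
  }
})

test_that("two-point PCNM reproduces the hand-worked eigenpair", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  b <- pcnm_basis(d)
  expect_equal(b$values, 2)
  expect_equal(unname(abs(b$vectors[, 1])), rep(1 / sqrt(2), 2))
  expect_equal(sum(b$vectors[, 1]), 0, tolerance = 1e-12)
})

test_that("PCNM eigenvectors are orthonormal eigenpairs of the centered matrix", {
  set.seed(21)
  co <- cbind(x = runif(12, 0, 100), y = runif(12, 0, 100))
  d <- named_d(co)
  b <- pcnm_basis(d)
  # orthonormal columns
  expect_equal(crossprod(b$vectors), diag(ncol(b$vectors)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # B e_k = lambda_k e_k for the reconstructed centered matrix
  ds <- truncate_oracle(d, b$threshold)
  n <- nrow(ds)
  H <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * H %*% ds^2 %*% H
  resid <- B %*% b$vectors - b$vectors %*% diag(b$values)
  expect_lt(max(abs(resid)), 1e-8)
  # eigenvalue sum equals the trace
  expect_equal(sum(b$values), sum(diag(B)), tolerance = 1e-8)
  expect_error(pcnm_basis(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCNM eigenvalues match brute-force PCoA and survive rigid motions", {
  set.seed(8)
  for (n in c(5, 8, 10)) {
    co <- cbind(x = runif(n, 0, 60), y = runif(n, 0, 60))
    d <- named_d(co)
    b <- pcnm_basis(d)
    oracle <- pcoa_oracle(truncate_oracle(d, b$threshold))
    oracle <- oracle[abs(oracle) > 1e-9 * max(abs(oracle))]
    expect_equal(b$values, oracle, tolerance = 1e-8)
    # rotation + translation leave the distances, hence eigenvalues, fixed
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    co2 <- sweep(co %*% R, 2, c(-40, 15), "+")
    expect_equal(pcnm_basis(named_d(co2))$values, b$values,
                 tolerance = 1e-8)
  }
})

test_that("PCNM agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  co <- cbind(x = runif(15, 0, 200), y = runif(15, 0, 200))
  d <- named_d(co)
  b <- pcnm_basis(d)
  v <- vegan::pcnm(d)
  expect_equal(b$threshold, v$threshold)
  ours <- sort(b$values[b$values > 0], decreasing = TRUE)
  theirs <- sort(v$values[v$values > sqrt(.Machine$double.eps)],
                 decreasing = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("transect PCNMs look like sinusoids from coarse to fine", {
  xy <- gen_coords(20, 19, "transect")
  b <- pcnm_basis(distance_matrix(xy))
  pos <- which(b$values > 0)
  t <- seq_len(20)
  for (k in 1:3) {
    v <- b$vectors[, pos[k]]
    r2 <- summary(lm(v ~ sin(pi * k * t / 20) + cos(pi * k * t / 20)))$r.squared
    expect_gt(r2, 0.6)
  }
  # eigenvalues strictly ordered: broad-scale axes come first
  expect_true(all(diff(b$values) <= 1e-12))
})

test_that("Moran's I matches hand values and its permutation null", {
  w <- matrix(0, 4, 4); w[cbind(1:3, 2:4)] <- 1; w <- w + t(w)
  mi <- morans_i(c(1, -1, 1, -1), w, nperm = 0)
  expect_equal(mi$observed, -1)
  expect_equal(mi$expected, -1 / 3)
  skip_if_not_installed("ape")
  expect_equal(ape::Moran.I(c(1, -1, 1, -1), w)$observed, mi$observed)
  # null mean of permuted I approximates -1/(n-1)
  set.seed(4)
  x <- rnorm(12)
  w12 <- (as.matrix(dist(cbind(1:12, 0))) == 1) * 1
  perm_mean <- mean(replicate(10000, {
    xp <- sample(x); z <- xp - mean(xp)
    (12 / sum(w12)) * sum(w12 * outer(z, z)) / sum(z^2)
  }))
  expect_lt(abs(perm_mean - (-1 / 11)), 0.02)
  # smooth gradient on a transect: strong positive autocorrelation
  g <- morans_i(1:12, w12, nperm = 199, seed = 6)
  expect_gt(g$observed, 0.5)
  expect_lte(g$p, 0.01)
  expect_error(morans_i(rep(1, 4), w), "constant")
  expect_error(morans_i(c(1, 2, 3, 4), diag(4)), "zero diagonal|symmetric")
})

test_that("screening keeps positive-eigenvalue, autocorrelated axes only", {
  xy <- gen_coords(20, 190, "transect")
  d <- distance_matrix(xy)
  b <- pcnm_basis(d)
  s <- screen_eigenbasis(b, d, alpha = 0.05, nperm = 199, seed = 42)
  expect_true(all(s$values[s$retained] > 0))
  expect_true(all(s$moran$observed_i[s$retained] > -1 / 19))
  # the broad-scale first axis is retained
  expect_true(s$retained[1])
  # negative-eigenvalue axes are never retained
  expect_true(all(!s$retained[s$values < 0]))
  expect_equal(ncol(retained_vectors(s)), sum(s$retained))
  expect_error(retained_vectors(b), "screened")
})
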