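#' Euclidean distance matrix between plots
#'
#' Coordinates must be projected (metres).  Inputs that look like
#' geographic coordinates (columns named `lat`/`lon`/`latitude`/`longitude`)
#' are rejected: project them first.  Duplicate coordinates are allowed but
#' reported, since they produce zero off-diagonal distances.
#'
#' @param coords numeric matrix or data.frame, one row per plot, two columns
#'   (x, y) in metres; row names are plot ids.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    geo <- grepl("^(lat|lon|latitude|longitude)", names(coords),
                 ignore.case = TRUE)
    if (any(geo))
      stop("coordinates look geographic (lat/lon); project to metres first")
    coords <- as.matrix(coords)
  }
  if (nrow(coords) < 2L) stop("need at least 2 plots")
  d <- as.matrix(stats::dist(coords[, 1:2, drop = FALSE]))
  if (any(d[upper.tri(d)] == 0))
    message("duplicate coordinates: some off-diagonal distances are zero")
  d
}

#' PCNM truncation threshold
#'
#' Longest edge of the minimum spanning tree of the complete distance
#' graph — the smallest threshold at which the plot network stays
#' connected, the standard PCNM truncation convention.
#'
#' @param d symmetric distance matrix.
#' @return scalar threshold (same units as `d`).
#' @export
truncation_threshold <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 plots")
  ## Prim's algorithm; track the largest edge added
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  longest <- 0
  for (step in seq_len(n - 1L)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' Spatial eigenfunctions by principal coordinates of neighbour matrices
#'
#' Builds the truncated distance matrix (distances beyond the threshold
#' replaced by `beyond_mult * t`), double-centers `-d^2/2` (Gower
#' centering) and eigendecomposes it.  The eigenvectors ("PCNMs") are
#' orthonormal spatial patterns ordered from broad scale (large
#' eigenvalues) to fine scale; eigenvalues within `1e-9 * max|lambda|` of
#' zero are dropped as numerical zeros.  Eigenvector signs are fixed by
#' making each column's largest-magnitude loading positive.
#'
#' @param d symmetric Euclidean distance matrix from [distance_matrix()].
#' @param truncation distance threshold; default [truncation_threshold()].
#' @param beyond_mult multiplier replacing distances beyond the threshold
#'   (default 4, the classical convention).
#' @return a `pcnm_basis`: list with `vectors` (plots x k, orthonormal,
#'   columns `PCNM1..k`), `values` (descending), `threshold`, `plot_ids`.
#' @export
pcnm_basis <- function(d, truncation = NULL, beyond_mult = 4) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  t0 <- truncation %||% truncation_threshold(d)
  if (t0 <= 0) stop("truncation threshold must be positive")
  dstar <- ifelse(d <= t0, d, beyond_mult * t0)
  diag(dstar) <- 0
  a <- -0.5 * dstar^2
  b <- a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
  eig <- eigen(b, symmetric = TRUE)
  keep <- abs(eig$values) > 1e-9 * max(abs(eig$values))
  vec <- eig$vectors[, keep, drop = FALSE]
  val <- eig$values[keep]
  ## deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(rownames(d), paste0("PCNM", seq_len(ncol(vec))))
  structure(list(vectors = vec, values = val, threshold = t0,
                 plot_ids = rownames(d)),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d eigenvectors (%d positive), truncation %.3g\n",
              length(x$values), sum(x$values > 0), x$threshold))
  if (!is.null(x$moran))
    cat(sprintf("  screened: %d retained (Moran's I > E[I], p <= %.3g)\n",
                sum(x$moran$retained), attr(x$moran, "alpha")))
  invisible(x)
}

#' Moran's I with a permutation test
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `W = sum_ij w_ij`.  Expected value under the spatial-randomness null
#' is `-1/(n-1)`.  The p-value is one-sided (observed or larger) from
#' random relabeling of the values over the plots.
#'
#' @param x numeric vector (non-constant).
#' @param w symmetric weight matrix, zero diagonal, at least one positive
#'   weight.
#' @param nperm number of permutations (default 999).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `observed`, `expected`, `p`.
#' @export
morans_i <- function(x, w, nperm = 999, seed = NULL) {
  n <- length(x)
  w <- as.matrix(w)
  if (stats::var(x) == 0) stop("Moran's I undefined for a constant vector")
  if (!isSymmetric(unname(w), tol = 1e-10) || any(diag(w) != 0))
    stop("weights must be symmetric with zero diagonal")
  if (all(w <= 0)) stop("need at least one positive weight")
  sw <- sum(w)
  istat <- function(zm) {
    ## zm: n x k matrix of centered vectors
    (n / sw) * colSums(zm * (w %*% zm)) / colSums(zm^2)
  }
  z <- x - mean(x)
  obs <- istat(cbind(z))
  p <- NA_real_
  if (nperm > 0) {
    perm <- with_seed(seed, {
      zp <- replicate(nperm, sample(z))
      istat(zp)
    })
    p <- (1 + sum(perm >= obs)) / (1 + nperm)
  }
  list(observed = unname(obs), expected = -1 / (n - 1), p = p)
}

#' Screen PCNM eigenvectors by eigenvalue sign and spatial autocorrelation
#'
#' Retains the eigenvectors with a positive eigenvalue and positive,
#' significant spatial autocorrelation: Moran's I above its null
#' expectation `-1/(n-1)` with permutation p-value at most `alpha`.
#' Weights are binary connectivity at the truncation threshold
#' (`w_ij = 1` iff `0 < d_ij <= t`), coherent with the truncation graph.
#'
#' @param basis a [pcnm_basis()].
#' @param d the distance matrix the basis was built from.
#' @param alpha significance level (default 0.05).
#' @param nperm permutations per eigenvector (default 999).
#' @param seed RNG seed for the permutation tests.
#' @return the basis with a `moran` data.frame (`eigenvalue`, `observed_i`,
#'   `p`, `retained`) and `retained` logical mask added.
#' @export
screen_eigenbasis <- function(basis, d, alpha = 0.05, nperm = 999,
                              seed = NULL) {
  stopifnot(inherits(basis, "pcnm_basis"), alpha > 0, alpha < 1)
  d <- as.matrix(d)
  w <- (d > 0 & d <= basis$threshold) * 1
  k <- length(basis$values)
  res <- with_seed(seed, {
    obs <- numeric(k); pv <- numeric(k)
    for (j in seq_len(k)) {
      mi <- morans_i(basis$vectors[, j], w, nperm = nperm, seed = NULL)
      obs[j] <- mi$observed; pv[j] <- mi$p
    }
    list(obs = obs, pv = pv)
  })
  expected <- -1 / (nrow(d) - 1)
  retained <- basis$values > 0 & res$obs > expected & res$pv <= alpha
  moran <- data.frame(axis = colnames(basis$vectors),
                      eigenvalue = basis$values,
                      observed_i = res$obs, p = res$pv,
                      retained = retained)
  attr(moran, "alpha") <- alpha
  basis$moran <- moran
  basis$retained <- retained
  basis
}

#' Retained spatial predictors
#'
#' @param basis a screened [pcnm_basis()].
#' @return matrix of retained eigenvectors (plots x k_retained).
#' @export
retained_vectors <- function(basis) {
  if (is.null(basis$retained))
    stop("basis has not been screened; call screen_eigenbasis() first")
  basis$vectors[, basis$retained, drop = FALSE]
}
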