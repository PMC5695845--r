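#' Redundancy-analysis R-squared and adjusted R-squared
#'
#' Least squares of each response column on the predictors (with
#' intercept, absorbed by centering).  The trace R-squared is the total
#' fitted sum of squares over the total sum of squares across columns,
#' reducing to the ordinary R-squared for a single-column response.  The
#' adjustment is Ezekiel's: `1 - (1 - R2) (n - 1) / (n - m - 1)` with `m`
#' predictors — unbiased near zero under the null, which is what makes
#' variance fractions comparable across predictor sets of different size.
#'
#' @param Y response vector or matrix.
#' @param X predictor matrix (or `NULL`/zero columns for the empty model).
#' @return list with `r2`, `adj_r2`, `m` (number of predictors).
#' @export
rda_r2 <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- center_cols(Y)
  ss_tot <- sum(Yc^2)
  if (is.null(X) || ncol(as.matrix(X)) == 0)
    return(list(r2 = 0, adj_r2 = 0, m = 0L))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("Y and X row counts differ")
  Xc <- center_cols(X)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient predictors; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  m <- qx$rank
  if (n <= m + 1) stop("need more plots than predictors + 1")
  r2 <- sum(ssq_fitted(qx, Yc)) / ss_tot
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1), m = m)
}

## Like rda_r2 but tolerant of rank deficiency: aliased columns are
## absorbed by the pivoted QR and m is the effective rank.
rda_r2_rank <- function(Y, X) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- center_cols(Y)
  Xc <- center_cols(as.matrix(X))
  qx <- qr(Xc)
  m <- qx$rank
  if (n <= m + 1) stop("need more plots than predictors + 1")
  r2 <- sum(ssq_fitted(qx, Yc)) / sum(Yc^2)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1), m = m)
}

#' Permutation test of a (partial) variance fraction
#'
#' Freedman-Lane permutation test of `Y ~ X_test | X_cond` with the
#' pseudo-F statistic: residuals of the reduced model (`Y ~ X_cond`) are
#' permuted and the reduced fit added back.  With no conditioning set this
#' is the marginal test (rows of centered `Y` permuted).
#'
#' @inheritParams pseudo_f
#' @param nperm number of permutations (default 999).
#' @param seed RNG seed (`NULL`: current stream).
#' @return list with `statistic` (pseudo-F) and `p`
#'   (`(1 + #(F* >= F)) / (1 + nperm)`).
#' @export
test_fraction <- function(Y, X_test, X_cond = NULL, nperm = 999,
                          seed = NULL) {
  res <- perm_pseudo_f(Y, X_test, X_cond, nperm = nperm, seed = seed)
  res[c("statistic", "p")]
}

#' Two-set variance partitioning on adjusted R-squared
#'
#' Partitions the variance of `Y` explained by an environmental
#' (topographic) set `E` and a spatial set `S` into the pure topographic
#' fraction `a`, the shared fraction `b`, the pure spatial fraction `c`
#' and the unexplained fraction `d`, by inclusion-exclusion on adjusted
#' R-squared:
#' `a = adjR2(E+S) - adjR2(S)`, `c = adjR2(E+S) - adjR2(E)`,
#' `b = adjR2(E) + adjR2(S) - adjR2(E+S)`, `d = 1 - adjR2(E+S)`.
#' `a` and `c` can be negative (a known property of adjusted fractions)
#' and are reported as computed.  Permutation tests are attached to the
#' testable fractions: conditional tests for `a` (`E | S`) and `c`
#' (`S | E`), marginal tests for `a+b` and `b+c`; `b` and `d` admit no
#' permutation test.
#'
#' An empty predictor set is legal (e.g. when forward selection retained
#' nothing): its marginal adjusted R-squared is 0 and the corresponding
#' pure and shared fractions are 0, with a degeneracy flag recorded.
#'
#' @param Y response vector or matrix.
#' @param E environmental predictor matrix (or `NULL`).
#' @param S spatial predictor matrix (or `NULL`).
#' @param nperm permutations for the fraction tests; 0 skips testing.
#' @param seed RNG seed.
#' @return a `variance_partition`: list with `fractions` (named a, b, c,
#'   d), `adj` (ab, bc, abc), `p` (a, c, ab, bc; NA where untestable or
#'   degenerate), `n_env`, `n_spa`, `flags`.
#' @export
variance_partition <- function(Y, E = NULL, S = NULL, nperm = 999,
                               seed = NULL) {
  Y <- as.matrix(Y)
  ncol0 <- function(X) if (is.null(X)) 0L else ncol(as.matrix(X))
  if (ncol0(E) == 0) E <- NULL
  if (ncol0(S) == 0) S <- NULL
  flags <- character(0)
  if (is.null(E)) flags <- c(flags, "no environmental variables")
  if (is.null(S)) flags <- c(flags, "no spatial variables")
  ab <- rda_r2(Y, E)$adj_r2
  bc <- rda_r2(Y, S)$adj_r2
  ## the union may be collinear across sets (shared information is the
  ## point of fraction b); fit it on its effective rank
  abc <- if (!is.null(E) && !is.null(S)) rda_r2_rank(Y, cbind(E, S))$adj_r2
         else if (!is.null(E)) ab else bc
  fr <- c(a = abc - bc, b = ab + bc - abc, c = abc - ab, d = 1 - abc)
  p <- c(a = NA_real_, c = NA_real_, ab = NA_real_, bc = NA_real_)
  if (nperm > 0) {
    ## a conditional test is undefined when the tested set adds no rank
    ## over the conditioning set (e.g. identical sets): report NA
    try_p <- function(...) tryCatch(perm_pseudo_f(...)$p,
                                    error = function(e) NA_real_)
    p[] <- with_seed(seed, {
      pa <- if (!is.null(E))
        try_p(Y, E, S, nperm = nperm, seed = NULL) else NA_real_
      pc <- if (!is.null(S))
        try_p(Y, S, E, nperm = nperm, seed = NULL) else NA_real_
      pab <- if (!is.null(E))
        try_p(Y, E, NULL, nperm = nperm, seed = NULL) else NA_real_
      pbc <- if (!is.null(S))
        try_p(Y, S, NULL, nperm = nperm, seed = NULL) else NA_real_
      c(pa, pc, pab, pbc)
    })
  }
  structure(list(fractions = fr,
                 adj = c(ab = ab, bc = bc, abc = abc),
                 p = p,
                 n_env = ncol0(E), n_spa = ncol0(S),
                 flags = flags),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  f <- x$fractions * 100
  cat("variance partition (adjusted R2, %):\n")
  cat(sprintf("  topography (a)  %7.1f   p = %s\n", f["a"], format_p(x$p["a"])))
  cat(sprintf("  shared (b)      %7.1f   (untestable)\n", f["b"]))
  cat(sprintf("  space (c)       %7.1f   p = %s\n", f["c"], format_p(x$p["c"])))
  cat(sprintf("  unexplained (d) %7.1f\n", f["d"]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

format_p <- function(p) ifelse(is.na(p), "-", sprintf("%.4g", p))

#' Significance code for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, `ns` otherwise;
#' `NA` maps to `"-"` (fraction not computed or untestable).
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
signif_code <- function(p) {
  out <- ifelse(is.na(p), "-",
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns"))))
  out
}
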