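## Permutation machinery shared by forward selection and the fraction tests.
## All models are fitted on column-centered Y and X, so the intercept is
## absorbed and one intercept df is charged in the residual df.

ssq_fitted <- function(qr_obj, Y) {
  if (is.null(qr_obj)) return(if (is.matrix(Y)) colSums(Y * 0) else 0)
  f <- qr.fitted(qr_obj, Y)
  if (is.matrix(Y)) colSums(f^2) else sum(f^2)
}

## F = (SS_add / q) / (SS_res / (n - p - 1)), p = rank of the full design
## (intercept excluded; centering supplies it).  Reduces to the classical
## partial F of nested linear models for a single-column response; for a
## matrix response the sums of squares are traces across columns.
f_from_ss <- function(ss_full, ss_red, ss_tot, n, rank_full, rank_red) {
  q <- rank_full - rank_red
  df_res <- n - 1 - rank_full
  if (q <= 0 || df_res <= 0) stop("degenerate design for pseudo-F")
  ## clamp: a saturated fit can leave a residual SS of -eps
  ss_res <- pmax(ss_tot - ss_full, 0)
  ((ss_full - ss_red) / q) / (ss_res / df_res)
}

#' Pseudo-F statistic of a (partial) redundancy model
#'
#' Constrained-ordination test statistic: the additional variance of `Y`
#' explained by `X_test` over `X_cond`, scaled by the residual variance of
#' the full model.  For a single-column `Y` it equals the classical
#' partial F of nested linear models; for a matrix `Y` the sums of squares
#' are totals (traces) across columns.
#'
#' @param Y response vector or matrix (centered internally).
#' @param X_test matrix of predictors under test.
#' @param X_cond optional conditioning predictors (`NULL` for a marginal
#'   test).
#' @return scalar pseudo-F.
#' @export
pseudo_f <- function(Y, X_test, X_cond = NULL) {
  pt <- perm_pseudo_f(Y, X_test, X_cond, nperm = 0)
  pt$statistic
}

## Permutation test of Y ~ X_test | X_cond.  Marginal tests permute rows of
## (centered) Y; conditioned tests use Freedman-Lane: permute residuals of
## the reduced model and add back its fitted values.  Univariate responses
## are batched across permutations in a single QR solve.
perm_pseudo_f <- function(Y, X_test, X_cond = NULL, nperm = 999,
                          seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- center_cols(Y)
  Xt <- center_cols(as.matrix(X_test))
  if (nrow(Xt) != n) stop("Y and X_test row counts differ")
  has_cond <- !is.null(X_cond) && ncol(as.matrix(X_cond)) > 0
  Xc <- if (has_cond) center_cols(as.matrix(X_cond)) else NULL
  qr_red <- if (has_cond) qr(Xc) else NULL
  rank_red <- if (has_cond) qr_red$rank else 0L
  if (has_cond && rank_red < ncol(Xc))
    stop("singular conditioning design")
  qr_full <- qr(cbind(Xc, Xt))
  rank_full <- qr_full$rank
  ss_tot <- colSums(Yc^2)
  fstat <- function(Ym) {
    f_from_ss(sum(ssq_fitted(qr_full, Ym)), sum(ssq_fitted(qr_red, Ym)),
              sum(colSums(Ym^2)), n, rank_full, rank_red)
  }
  obs <- fstat(Yc)
  if (nperm <= 0) return(list(statistic = obs, p = NA_real_))
  fit_red <- if (has_cond) qr.fitted(qr_red, Yc) else matrix(0, n, ncol(Yc))
  e_red <- Yc - fit_red
  fperm <- with_seed(seed, {
    if (ncol(Yc) == 1L) {
      idx <- replicate(nperm, sample.int(n))
      ystar <- fit_red[, 1] + matrix(e_red[idx], n, nperm)
      ssf <- ssq_fitted(qr_full, ystar)
      ssr <- ssq_fitted(qr_red, ystar)
      sst <- colSums(ystar^2)
      q <- rank_full - rank_red
      ((ssf - ssr) / q) / (pmax(sst - ssf, 0) / (n - 1 - rank_full))
    } else {
      vapply(seq_len(nperm), function(i) {
        fstat(fit_red + e_red[sample.int(n), , drop = FALSE])
      }, numeric(1))
    }
  })
  list(statistic = obs,
       p = (1 + sum(fperm >= obs)) / (1 + nperm),
       permuted = fperm)
}

#' Permutation-based forward selection with the double stopping criterion
#'
#' Stepwise selection for redundancy models: (1) a global permutation test
#' of `Y` against all candidates gates the whole procedure — if the global
#' model is not significant at `alpha`, nothing is selected; (2) candidates
#' are added one at a time, each addition maximizing the extra explained
#' variance and tested by a Freedman-Lane permutation pseudo-F conditioned
#' on the variables already selected; selection stops when the best
#' candidate's p-value exceeds `alpha` or when the cumulative adjusted
#' R-squared would exceed that of the global model (the double stopping
#' rule).  Exact ties in extra variance are broken by candidate name
#' ascending.
#'
#' @param Y response vector or matrix.
#' @param X candidate predictor matrix with column names.
#' @param alpha per-step (and global) significance level, default 0.05.
#' @param nperm permutations per test, default 999 (minimum 99).
#' @param seed RNG seed; mandatory for reproducible selection.
#' @return a `forward_selection`: list with `candidates`, `selected`
#'   (in entry order), `steps` (data.frame: variable, statistic, p,
#'   cum_adj_r2), `global_p`, `global_adj_r2`, `dropped`
#'   (zero-variance candidates).
#' @export
forward_select <- function(Y, X, alpha = 0.05, nperm = 999, seed) {
  if (missing(seed) || is.null(seed)) stop("forward_select needs a seed")
  if (nperm < 99) stop("nperm must be at least 99")
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance candidates: ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  n <- nrow(Y)
  if (ncol(X) > n - 1) stop("more candidates than plots - 1")
  X <- X[, order(colnames(X)), drop = FALSE]   # tie-break order
  Xs <- scale(X)
  Yc <- center_cols(Y)
  empty_steps <- data.frame(variable = character(), statistic = numeric(),
                            p = numeric(), cum_adj_r2 = numeric())
  out <- with_seed(seed, {
    glob <- perm_pseudo_f(Yc, Xs, NULL, nperm = nperm, seed = NULL)
    gfit <- rda_r2(Yc, Xs)
    sel <- character(0)
    steps <- empty_steps
    if (glob$p <= alpha) {
      remaining <- colnames(Xs)
      repeat {
        if (!length(remaining) || length(sel) >= n - 2) break
        qr_sel <- if (length(sel)) qr(Xs[, sel, drop = FALSE]) else NULL
        ss_sel <- sum(ssq_fitted(qr_sel, Yc))
        gain <- vapply(remaining, function(v) {
          sum(ssq_fitted(qr(Xs[, c(sel, v), drop = FALSE]), Yc)) - ss_sel
        }, numeric(1))
        cand <- remaining[which.max(gain)]  # first max = name ascending
        cum <- rda_r2(Yc, Xs[, c(sel, cand), drop = FALSE])
        if (cum$adj_r2 > gfit$adj_r2 + 1e-10) break
        tst <- perm_pseudo_f(Yc, Xs[, cand, drop = FALSE],
                             if (length(sel)) Xs[, sel, drop = FALSE],
                             nperm = nperm, seed = NULL)
        ## a NaN p means the selected set already saturates Y: stop
        if (!is.finite(tst$p) || tst$p > alpha) break
        sel <- c(sel, cand)
        remaining <- setdiff(remaining, cand)
        steps <- rbind(steps,
                       data.frame(variable = cand, statistic = tst$statistic,
                                  p = tst$p, cum_adj_r2 = cum$adj_r2))
      }
    }
    list(glob = glob, gfit = gfit, sel = sel, steps = steps)
  })
  structure(list(candidates = colnames(X),
                 selected = out$sel,
                 steps = out$steps,
                 global_p = out$glob$p,
                 global_statistic = out$glob$statistic,
                 global_adj_r2 = out$gfit$adj_r2,
                 global_r2 = out$gfit$r2,
                 dropped = dropped,
                 alpha = alpha, nperm = nperm),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("forward selection: %d/%d candidates selected (global p = %.4g, adj R2 = %.4f)\n",
              length(x$selected), length(x$candidates), x$global_p,
              x$global_adj_r2))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
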