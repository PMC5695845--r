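## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's stream.
## seed = NULL means "use the current stream" (callers that seed once and
## draw sequentially, e.g. forward_select).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed for a named stage, derived from a master seed.
## Keeps independent permutation streams per stage/response so adding
## permutations in one stage never perturbs another.  Result < 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

## Center columns of a numeric matrix (keeps dimnames).
center_cols <- function(x) {
  x <- as.matrix(x)
  sweep(x, 2L, colMeans(x), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
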