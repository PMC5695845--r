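## Independent oracles, deliberately coded differently from the package:
## explicit centering matrices, lm() fits, exhaustive enumeration.

## Brute-force principal coordinates: B = -1/2 H D*^2 H with the explicit
## centering matrix H = I - 11'/n.
pcoa_oracle <- function(dstar) {
  n <- nrow(dstar)
  H <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * H %*% dstar^2 %*% H
  eigen((B + t(B)) / 2, symmetric = TRUE)$values
}

## Truncated distance matrix mirroring the PCNM convention.
truncate_oracle <- function(d, t0, mult = 4) {
  ds <- ifelse(d <= t0, d, mult * t0)
  diag(ds) <- 0
  ds
}

## Adjusted R2 via lm(): residual sums of squares, Ezekiel correction.
adj_r2_lm <- function(Y, X) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(X) || ncol(as.matrix(X)) == 0) return(0)
  X <- as.matrix(X)
  fit <- lm(Y ~ X)
  Yc <- sweep(Y, 2, colMeans(Y))
  r2 <- 1 - sum(residuals(fit)^2) / sum(Yc^2)
  1 - (1 - r2) * (n - 1) / (n - ncol(X) - 1)
}

## Independent inclusion-exclusion variance partition.
varpart_oracle <- function(Y, E, S) {
  ab <- adj_r2_lm(Y, E)
  bc <- adj_r2_lm(Y, S)
  abc <- adj_r2_lm(Y, cbind(E, S))
  c(a = abc - bc, b = ab + bc - abc, c = abc - ab, d = 1 - abc)
}

## All spanning trees of the complete graph on n labelled vertices via
## Prufer sequences; returns the minimax ("longest MST edge") threshold.
mst_longest_edge_oracle <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  tree_edges <- function(prufer) {
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, 0, 2)
    for (v in prufer) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    u <- which(degree == 1L)
    rbind(edges, u)
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- tree_edges(seqs[i, ])
    w <- d[e]
    tot <- sum(w)
    if (tot < best - 1e-12) {
      best <- tot
      longest <- max(w)
    }
  }
  longest
}

## Small deterministic community fixture: 6 plots x 5 species.
small_community <- function() {
  v <- matrix(c(5, 3, 0, 1, 0,
                2, 4, 1, 0, 0,
                0, 6, 2, 0, 1,
                3, 0, 0, 2, 0,
                1, 2, 3, 0, 0,
                0, 1, 0, 4, 2), 6, 5, byrow = TRUE,
              dimnames = list(paste0("P", 1:6), paste0("sp", 1:5)))
  community_matrix(v, basis = "abundance")
}

## Deterministic mid-size synthetic study shared across pipeline tests.
small_simulation <- function(seed = 101, archetype = "species_sorting",
                             n_plots = 25, n_species = 50, ...) {
  simulate_metacommunity(
    scenario_config(archetype, n_plots = n_plots, n_species = n_species,
                    seed = seed, ...))
}
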