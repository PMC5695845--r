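#' Scenario configuration for the synthetic metacommunity generator
#'
#' Defines the generating structure of a simulated tree metacommunity.
#' The four archetypes combine environmental filtering and spatial
#' structure in the canonical ways: `species_sorting` (pure environmental
#' niches), `neutral` (pure spatially autocorrelated intensity, a
#' phenomenological stand-in for dispersal limitation and drift),
#' `mass_effect` (a mixture of the two, weighted by `mixture_w`) and
#' `null` (neither).
#'
#' Defaults mirror the study design the package targets: 46 plots over a
#' few-kilometre landscape, a 230-species pool with log-series-like base
#' abundances (few common, many rare species), and five spatially
#' autocorrelated topographic covariates.
#'
#' @param archetype one of `"species_sorting"`, `"mass_effect"`,
#'   `"neutral"`, `"null"`.
#' @param n_plots number of plots (default 46).
#' @param n_species size of the species pool (default 230).
#' @param extent landscape extent, m (default 2000).
#' @param env_range autocorrelation range of the covariate fields, m
#'   (default 500).
#' @param niche_sd niche breadth of species along the first covariate, in
#'   covariate standard deviations (default 1; smaller = stronger
#'   sorting).
#' @param mixture_w weight of the environmental term in `mass_effect`,
#'   in `[0, 1]` (default 0.5).
#' @param spatial_range range of the species-specific spatial intensity
#'   fields, m (default 500).
#' @param abundance_rank_shape log-series decay parameter `theta` of the
#'   base abundances `A_s` proportional to `theta^s / s` (default 0.99).
#' @param mean_stems expected stems per plot under the null (default 110,
#'   a typical terra-firme density for stems with DBH >= 10 cm).
#' @param noise negative-binomial overdispersion; 0 means Poisson counts.
#' @param seed integer seed; mandatory.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(archetype = c("species_sorting", "mass_effect",
                                          "neutral", "null"),
                            n_plots = 46, n_species = 230, extent = 2000,
                            env_range = 500, niche_sd = 1, mixture_w = 0.5,
                            spatial_range = 500,
                            abundance_rank_shape = 0.99, mean_stems = 110,
                            noise = 0, seed) {
  archetype <- match.arg(archetype)
  if (missing(seed)) stop("scenario_config needs a seed")
  stopifnot(n_plots >= 4, n_species >= 3, extent > 0, env_range > 0,
            niche_sd > 0, mixture_w >= 0, mixture_w <= 1, spatial_range > 0,
            abundance_rank_shape > 0, abundance_rank_shape < 1,
            mean_stems > 0, noise >= 0)
  structure(list(archetype = archetype, n_plots = n_plots,
                 n_species = n_species, extent = extent,
                 env_range = env_range, niche_sd = niche_sd,
                 mixture_w = mixture_w, spatial_range = spatial_range,
                 abundance_rank_shape = abundance_rank_shape,
                 mean_stems = mean_stems, noise = noise,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate plot coordinates
#'
#' @param n_plots number of plots.
#' @param extent landscape extent, m.
#' @param mode `"uniform_random"`, `"grid"` or `"transect"`.
#' @param seed RNG seed.
#' @return numeric matrix (n x 2, columns `x`, `y`), row names `P01`...
#' @export
gen_coords <- function(n_plots, extent,
                       mode = c("uniform_random", "grid", "transect"),
                       seed = NULL) {
  mode <- match.arg(mode)
  if (extent <= 0) stop("extent must be positive")
  xy <- switch(mode,
    transect = cbind(x = seq(0, extent, length.out = n_plots),
                     y = rep(0, n_plots)),
    grid = {
      nr <- max(1L, round(sqrt(n_plots)))
      nc <- ceiling(n_plots / nr)
      if (nr * nc != n_plots)
        warning("n_plots is not a full grid; using the first ", n_plots,
                " cells of a ", nr, "x", nc, " grid")
      g <- expand.grid(x = seq(0, extent, length.out = nc),
                       y = seq(0, extent, length.out = nr))
      as.matrix(g[seq_len(n_plots), c("x", "y")])
    },
    uniform_random = with_seed(seed,
      cbind(x = stats::runif(n_plots, 0, extent),
            y = stats::runif(n_plots, 0, extent)))
  )
  rownames(xy) <- sprintf("P%02d", seq_len(n_plots))
  xy
}

#' Generate spatially autocorrelated covariate fields
#'
#' Draws each field from a zero-mean Gaussian process over the plot
#' locations with exponential covariance `sill * exp(-d / range)`,
#' independently across fields.  Stands in for topographic covariates
#' (elevation, slope, curvatures, height above nearest drainage).
#'
#' @param coords plot coordinate matrix.
#' @param n_fields number of covariates (default 5).
#' @param range autocorrelation range, m.
#' @param sill marginal variance (0 gives constant-zero fields).
#' @param seed RNG seed.
#' @param names field names.
#' @return data.frame of covariates, rows matching `coords`.
#' @export
gen_env_fields <- function(coords, n_fields = 5, range, sill = 1,
                           seed = NULL,
                           names = c("elevation", "slope", "profile_curv",
                                     "plan_curv", "hand")[seq_len(n_fields)]) {
  if (range <= 0 || sill < 0) stop("range must be positive and sill >= 0")
  n <- nrow(coords)
  if (sill == 0) {
    z <- matrix(0, n, n_fields)
  } else {
    d <- as.matrix(stats::dist(coords))
    cv <- sill * exp(-d / range)
    L <- tryCatch(chol(cv), error = function(e) {
      warning("covariance numerically non-PD; jittering diagonal by 1e-10")
      chol(cv + diag(1e-10, n))
    })
    z <- with_seed(seed,
                   t(L) %*% matrix(stats::rnorm(n * n_fields), n, n_fields))
  }
  out <- as.data.frame(z)
  colnames(out) <- names
  rownames(out) <- rownames(coords)
  out
}

## Log-series-like base abundances: A_s proportional to theta^s / s,
## scaled so the null-model expected stems per plot is mean_stems.
base_abundances <- function(n_species, theta, mean_stems) {
  s <- seq_len(n_species)
  w <- theta^s / s
  mean_stems * w / sum(w)
}

## Draw one zero-mean unit-sill exponential-covariance field per species
## (n_plots x n_species), using the current RNG stream.
species_fields <- function(coords, n_species, range) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  L <- chol(exp(-d / range) + diag(1e-10, n))
  t(L) %*% matrix(stats::rnorm(n * n_species), n, n_species)
}

#' Generate a metacommunity abundance matrix under a known archetype
#'
#' Species `s` has log-series base abundance `A_s`; its expected count at
#' plot `j` is `A_s` times an archetype-specific factor:
#' \describe{
#'   \item{species_sorting}{Gaussian niche on the first (standardized)
#'     covariate, `exp(-(e_j - mu_s)^2 / (2 niche_sd^2))`, with optima
#'     `mu_s` spread uniformly over the observed covariate range.}
#'   \item{neutral}{`exp(g_s(x_j) - 1/2)` with `g_s` a species-specific
#'     unit-variance spatial field of range `spatial_range` (the -1/2
#'     keeps the expected factor near 1).}
#'   \item{mass_effect}{geometric mixture: `mixture_w` times the
#'     log-niche term plus `1 - mixture_w` times the log-spatial term.
#'     `mixture_w = 1` reproduces `species_sorting` exactly at the same
#'     seed.}
#'   \item{null}{factor 1.}
#' }
#' Counts are Poisson, or negative binomial with size `1/noise` when
#' `noise > 0`.
#'
#' @param config a [scenario_config()].
#' @param coords plot coordinates.
#' @param env covariate data.frame (needed by the archetypes that use it).
#' @return an abundance [community_matrix()] (plots x species,
#'   `sp001`...).
#' @export
gen_metacommunity <- function(config, coords, env = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_plots
  S <- config$n_species
  if (nrow(coords) != n) stop("coords do not match n_plots")
  A <- base_abundances(S, config$abundance_rank_shape, config$mean_stems)
  loglam <- matrix(log(A), n, S, byrow = TRUE)
  uses_env <- config$archetype %in% c("species_sorting", "mass_effect")
  uses_space <- config$archetype == "neutral" ||
    (config$archetype == "mass_effect" && config$mixture_w < 1)
  w_env <- switch(config$archetype,
                  species_sorting = 1, mass_effect = config$mixture_w, 0)
  w_spa <- switch(config$archetype,
                  neutral = 1, mass_effect = 1 - config$mixture_w, 0)
  if (uses_env) {
    if (is.null(env)) stop("archetype '", config$archetype, "' needs env")
    e <- as.numeric(scale(env[[1]]))
    mu <- with_seed(stage_seed(config$seed, "optima"),
                    stats::runif(S, min(e), max(e)))
    niche <- -outer(e, mu, "-")^2 / (2 * config$niche_sd^2)
    loglam <- loglam + w_env * niche
  }
  if (uses_space) {
    g <- with_seed(stage_seed(config$seed, "fields"),
                   species_fields(coords, S, config$spatial_range))
    loglam <- loglam + w_spa * (g - 0.5)
  }
  lam <- exp(loglam)
  counts <- with_seed(stage_seed(config$seed, "counts"), {
    if (config$noise > 0)
      stats::rnbinom(n * S, mu = lam, size = 1 / config$noise)
    else
      stats::rpois(n * S, lam)
  })
  v <- matrix(counts, n, S,
              dimnames = list(rownames(coords),
                              sprintf("sp%03d", seq_len(S))))
  community_matrix(v, basis = "abundance")
}

#' Generate a stem-level census from an abundance matrix
#'
#' Each individual implied by a cell becomes one record: DBH is drawn from
#' a shifted exponential (`min_dbh + Exp(rate)`, so every stem clears the
#' census inclusion rule) and height from the power allometry
#' `height_alpha * DBH^height_beta` with multiplicative lognormal noise.
#'
#' @param m abundance [community_matrix()].
#' @param seed RNG seed.
#' @param min_dbh smallest DBH, cm (default 10).
#' @param dbh_rate exponential rate for DBH above `min_dbh` (default
#'   0.125, i.e. mean DBH 18 cm).
#' @param height_alpha,height_beta height-allometry parameters (defaults
#'   2.6 and 0.6: a 20 cm tree is ~16 m tall).
#' @param height_sdlog lognormal noise sd on height (default 0.1).
#' @return data.frame with columns `plot_id`, `species_id`, `dbh_cm`,
#'   `height_m`.
#' @export
gen_tree_census <- function(m, seed = NULL, min_dbh = 10, dbh_rate = 0.125,
                            height_alpha = 2.6, height_beta = 0.6,
                            height_sdlog = 0.1) {
  if (matrix_basis(m) != "abundance")
    stop("census generation needs an abundance matrix")
  v <- unclass(m)
  idx <- which(v > 0, arr.ind = TRUE)
  counts <- v[idx]
  plot_id <- rep(rownames(v)[idx[, 1]], counts)
  species_id <- rep(colnames(v)[idx[, 2]], counts)
  n <- length(plot_id)
  with_seed(seed, {
    dbh <- min_dbh + stats::rexp(n, rate = dbh_rate)
    h <- height_alpha * dbh^height_beta *
      exp(stats::rnorm(n, 0, height_sdlog))
    data.frame(plot_id = plot_id, species_id = species_id,
               dbh_cm = dbh, height_m = h)
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [gen_coords()], [gen_env_fields()], [gen_metacommunity()]
#' and [gen_tree_census()] into the two tables the analysis pipeline
#' consumes, plus the ground-truth community matrix.
#'
#' @param config a [scenario_config()].
#' @param coord_mode coordinate layout (default `"uniform_random"`).
#' @return list with `trees` (stem table), `plots` (plot table with
#'   coordinates and covariates), `community` (true abundance matrix),
#'   `coords`, `env`, `config`.
#' @export
simulate_metacommunity <- function(config, coord_mode = "uniform_random") {
  stopifnot(inherits(config, "scenario_config"))
  coords <- gen_coords(config$n_plots, config$extent, coord_mode,
                       seed = stage_seed(config$seed, "coords"))
  env <- gen_env_fields(coords, n_fields = 5, range = config$env_range,
                        sill = 1, seed = stage_seed(config$seed, "env"))
  comm <- gen_metacommunity(config, coords, env)
  trees <- gen_tree_census(comm, seed = stage_seed(config$seed, "trees"))
  plots <- data.frame(plot_id = rownames(coords),
                      x_m = coords[, "x"], y_m = coords[, "y"],
                      env, row.names = NULL)
  list(trees = trees, plots = plots, community = comm,
       coords = coords, env = env, config = config)
}
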