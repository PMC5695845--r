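#' Per-plot totals
#'
#' Row sums of a community matrix: total abundance (stems) or total biomass
#' (kg) per plot.
#'
#' @param m a [community_matrix()] on the abundance or biomass basis.
#' @return named numeric vector, one value per plot.
#' @export
plot_totals <- function(m) {
  if (!matrix_basis(m) %in% c("abundance", "biomass"))
    stop("plot totals need an abundance or biomass matrix")
  rowSums(m)
}

#' Per-plot species richness
#'
#' Count of species with a positive cell in each plot; identical on the
#' incidence and abundance versions of the same matrix.
#'
#' @param m a [community_matrix()].
#' @return named integer vector, one value per plot.
#' @export
richness <- function(m) rowSums(unclass(m) > 0)

#' Standardized richness: residual richness after removing abundance
#'
#' Richness co-varies with abundance; to study richness free of abundance,
#' regress richness on total abundance by ordinary least squares and keep
#' the residuals.  Residuals sum to zero and are uncorrelated with
#' abundance by construction.
#'
#' @param rich per-plot richness (named vector).
#' @param abund per-plot total abundance (named vector, same plots).
#' @return named numeric vector of OLS residuals, in plot order.
#' @export
standardized_richness <- function(rich, abund) {
  if (length(rich) != length(abund))
    stop("richness and abundance must cover the same plots")
  if (!is.null(names(rich)) && !is.null(names(abund)) &&
      !identical(names(rich), names(abund)))
    stop("richness and abundance plot ids do not match")
  if (length(rich) < 3L) stop("need at least 3 plots")
  if (stats::var(abund) == 0)
    stop("abundance is constant across plots: regression slope undefined")
  stats::residuals(stats::lm(rich ~ abund))
}

#' Hellinger transformation
#'
#' Cell-wise square root of the row-relative abundance,
#' `sqrt(y_ij / y_i+)`.  Makes Euclidean-based ordination (PCA/RDA)
#' appropriate for sparse community data.  Rows with zero total are kept as
#' all-zero rows with a warning (dropping plots would desynchronize the
#' spatial eigenbasis).
#'
#' @param m a [community_matrix()] or non-negative matrix.
#' @return numeric matrix with attribute `transform = "hellinger"`; every
#'   row with positive total has unit sum of squares.
#' @export
hellinger <- function(m) {
  v <- unclass(as.matrix(m))
  if (any(v < 0)) stop("hellinger transform needs non-negative values")
  rt <- rowSums(v)
  if (any(rt == 0))
    warning(sum(rt == 0), " plot(s) with zero total kept as all-zero rows")
  scale_by <- ifelse(rt > 0, rt, 1)
  out <- sqrt(sweep(v, 1L, scale_by, "/"))
  attr(out, "transform") <- "hellinger"
  attr(out, "basis") <- NULL
  class(out) <- "matrix"
  out
}

response_groups <- c("total", "common", "rare")

## Assemble one response object (univariate vector or composition matrix).
make_response <- function(value, attribute, group, transform = "none",
                          rank_range = NULL) {
  structure(list(value = value, attribute = attribute, group = group,
                 transform = transform, rank_range = rank_range),
            class = "mp_response")
}

#' Build the 18 response attributes
#'
#' Six community attributes (standardized richness, total abundance, total
#' biomass, and composition on the incidence, abundance and biomass bases)
#' for each of three species groups (total community, common, trimmed
#' rare).  The abundance-based split governs standardized richness, total
#' abundance and the incidence/abundance compositions; the biomass-based
#' split governs the biomass attributes, so the two groups may cover
#' different rank ranges.
#'
#' Composition on the abundance basis is Hellinger-transformed; incidence
#' composition is raw 0/1; biomass composition is raw by default with
#' `hellinger_biomass = TRUE` available for sensitivity analysis.
#'
#' @param abund abundance [community_matrix()] (all species).
#' @param biom biomass [community_matrix()] (all species).
#' @param split_abund [split_common_rare()] on the abundance basis.
#' @param split_biom [split_common_rare()] on the biomass basis.
#' @param hellinger_biomass logical; Hellinger-transform the biomass
#'   composition matrices?
#' @return named list of 18 `mp_response` objects, keys
#'   `<attribute>.<group>`.
#' @export
build_responses <- function(abund, biom, split_abund, split_biom,
                            hellinger_biomass = FALSE) {
  n_sp <- length(split_abund$ranking$species_ids)
  groups_of <- function(split) {
    s <- length(split$ranking$species_ids)
    list(total = list(ids = split$ranking$species_ids, range = c(1L, s)),
         common = list(ids = split$common_ids,
                       range = c(1L, split$cutoff_rank)),
         rare = list(ids = split$trimmed_rare_ids,
                     range = c(s - length(split$trimmed_rare_ids) + 1L, s)))
  }
  ga <- groups_of(split_abund)
  gb <- groups_of(split_biom)
  out <- list()
  for (g in response_groups) {
    ma <- subset_matrix(abund, ga[[g]]$ids)
    mb <- subset_matrix(biom, gb[[g]]$ids)
    if (ncol(ma) < 2L || ncol(mb) < 2L)
      stop("species group '", g, "' has fewer than 2 species")
    tot_a <- plot_totals(ma)
    out[[paste0("std_richness.", g)]] <-
      make_response(standardized_richness(richness(ma), tot_a),
                    "std_richness", g, rank_range = ga[[g]]$range)
    out[[paste0("abundance.", g)]] <-
      make_response(tot_a, "abundance", g, rank_range = ga[[g]]$range)
    out[[paste0("biomass.", g)]] <-
      make_response(plot_totals(mb), "biomass", g, rank_range = gb[[g]]$range)
    out[[paste0("c_incidence.", g)]] <-
      make_response(unclass(to_incidence(ma)), "c_incidence", g,
                    rank_range = ga[[g]]$range)
    out[[paste0("c_abundance.", g)]] <-
      make_response(hellinger(ma), "c_abundance", g, transform = "hellinger",
                    rank_range = ga[[g]]$range)
    out[[paste0("c_biomass.", g)]] <-
      make_response(if (hellinger_biomass) hellinger(mb) else unclass(mb),
                    "c_biomass", g,
                    transform = if (hellinger_biomass) "hellinger" else "none",
                    rank_range = gb[[g]]$range)
  }
  out
}
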