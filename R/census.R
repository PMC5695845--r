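#' Read a stem-level tree census table
#'
#' Expects a CSV with columns `plot_id`, `species_id`, `dbh_cm`, `height_m`;
#' one censused stem per row.  Records with a blank species identifier are
#' rejected: every individual must be identified before analysis.
#'
#' @param path CSV file path.
#' @return data.frame with columns `plot_id`, `species_id`, `dbh_cm`,
#'   `height_m`.
#' @export
read_trees <- function(path) {
  df <- utils::read.csv(path, colClasses = c(plot_id = "character",
                                             species_id = "character"))
  need <- c("plot_id", "species_id", "dbh_cm", "height_m")
  if (!all(need %in% names(df)))
    stop("trees table must have columns: ", paste(need, collapse = ", "))
  validate_trees(df[need])
}

validate_trees <- function(df) {
  if (any(!nzchar(df$plot_id)))
    stop("blank plot_id in census records")
  if (any(is.na(df$species_id) | !nzchar(df$species_id)))
    stop("unidentified stems (blank species_id) are not allowed")
  if (any(!is.finite(df$dbh_cm)) || any(df$dbh_cm <= 0))
    stop("dbh_cm must be positive")
  if (any(!is.finite(df$height_m)) || any(df$height_m <= 0))
    stop("height_m must be positive")
  df
}

#' Read the plot table
#'
#' Expects a CSV with columns `plot_id`, `x_m`, `y_m` and the topographic
#' covariates (by default `elevation`, `slope`, `profile_curv`, `plan_curv`,
#' `hand`).  Coordinates must be projected, in metres — geographic
#' latitude/longitude is rejected (see [distance_matrix()]).
#'
#' @param path CSV file path.
#' @return data.frame keyed by `plot_id`.
#' @export
read_plots <- function(path) {
  df <- utils::read.csv(path, colClasses = c(plot_id = "character"))
  need <- c("plot_id", "x_m", "y_m")
  if (!all(need %in% names(df)))
    stop("plots table must have columns plot_id, x_m, y_m plus covariates")
  if (anyDuplicated(df$plot_id)) stop("duplicate plot_id in plots table")
  df
}

#' Inclusion filter on stem diameter
#'
#' Keeps the stems with DBH greater than or equal to `min_dbh` (inclusive
#' boundary), preserving record order.  The census design here admits every
#' stem with DBH >= 10 cm.
#'
#' @param trees census data.frame as returned by [read_trees()].
#' @param min_dbh minimum diameter at breast height, cm (default 10).
#' @return the filtered data.frame.
#' @export
filter_census <- function(trees, min_dbh = 10) {
  if (!is.numeric(min_dbh) || length(min_dbh) != 1L || min_dbh <= 0)
    stop("min_dbh must be a positive scalar")
  trees[trees$dbh_cm >= min_dbh, , drop = FALSE]
}

#' Allometric aboveground-biomass model
#'
#' The power-law allometry `biomass = coefficient * (DBH^2 * TH)^exponent`
#' with DBH in cm and total height (TH) in m, yielding kg per stem.  The
#' defaults (0.044, 0.9719) are the coefficients used for Amazonian
#' terra-firme trees.
#'
#' @param coefficient positive multiplier (default 0.044).
#' @param exponent positive power (default 0.9719).
#' @return an `allometric_model` object.
#' @export
allometric_model <- function(coefficient = 0.044, exponent = 0.9719) {
  if (coefficient <= 0 || exponent <= 0)
    stop("allometric coefficient and exponent must be positive")
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "allometric_model")
}

#' Per-stem aboveground biomass
#'
#' @param dbh diameter at breast height, cm (vectorized).
#' @param height total height, m (vectorized).
#' @param model an [allometric_model()].
#' @return biomass in kg.
#' @examples
#' tree_biomass(10, 10)  # 0.044 * 1000^0.9719 ~ 36.24 kg
#' @export
tree_biomass <- function(dbh, height, model = allometric_model()) {
  if (any(dbh <= 0) || any(height <= 0))
    stop("dbh and height must be positive")
  model$coefficient * (dbh^2 * height)^model$exponent
}

#' Aggregate a census to a plots-by-species matrix
#'
#' On the `abundance` basis each cell is the stem count for the
#' (plot, species) pair; on the `biomass` basis it is the sum of per-stem
#' biomass from `model`.  Plots and species are sorted lexicographically;
#' `plot_ids`/`species_ids` may supply ids that must appear even when absent
#' from the records (empty rows/columns).
#'
#' @param trees filtered census data.frame.
#' @param basis `"abundance"` or `"biomass"`.
#' @param model an [allometric_model()] (biomass basis only).
#' @param plot_ids,species_ids optional explicit identifier sets.
#' @return a [community_matrix()].
#' @export
build_matrix <- function(trees, basis = c("abundance", "biomass"),
                         model = allometric_model(),
                         plot_ids = NULL, species_ids = NULL) {
  basis <- match.arg(basis)
  plots <- sort(unique(c(trees$plot_id, plot_ids)))
  species <- sort(unique(c(trees$species_id, species_ids)))
  v <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  if (nrow(trees)) {
    w <- if (basis == "abundance") rep(1, nrow(trees))
         else tree_biomass(trees$dbh_cm, trees$height_m, model)
    agg <- tapply(w, list(factor(trees$plot_id, plots),
                          factor(trees$species_id, species)), sum)
    agg[is.na(agg)] <- 0
    v[] <- agg
  }
  community_matrix(v, basis = basis)
}

#' Census design summary
#'
#' Plot count and sampled area implied by the plot dimensions.  With the
#' default design of 25 m x 100 m plots, 46 plots cover 11.5 ha.
#'
#' @param plot_ids character vector of plot identifiers (or a plots table).
#' @param plot_width,plot_length plot dimensions, m.
#' @return list with `n_plots`, `plot_area_m2`, `sampled_area_ha`.
#' @export
census_summary <- function(plot_ids, plot_width = 25, plot_length = 100) {
  if (is.data.frame(plot_ids)) plot_ids <- plot_ids$plot_id
  n <- length(unique(plot_ids))
  area_m2 <- plot_width * plot_length
  list(n_plots = n,
       plot_area_m2 = area_m2,
       sampled_area_ha = n * area_m2 / 1e4)
}
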