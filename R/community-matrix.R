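#' Plots-by-species community matrix
#'
#' A `community_matrix` is a plain numeric matrix with plots as rows and
#' species as columns, carrying a `basis` attribute declaring what the cells
#' mean: `"incidence"` (0/1 presence), `"abundance"` (stem counts) or
#' `"biomass"` (summed aboveground biomass, kg).
#'
#' @param values numeric matrix, plots in rows, species in columns; must have
#'   unique, non-empty row and column names.
#' @param basis one of `"incidence"`, `"abundance"`, `"biomass"`.
#' @return a `community_matrix` object.
#' @examples
#' m <- community_matrix(matrix(c(1, 0, 2, 3), 2, 2,
#'                              dimnames = list(c("P1", "P2"), c("spA", "spB"))),
#'                       basis = "abundance")
#' to_incidence(m)
#' @export
community_matrix <- function(values,
                             basis = c("abundance", "biomass", "incidence")) {
  basis <- match.arg(basis)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("community matrix needs plot (row) and species (column) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate plot or species identifiers")
  if (any(values < 0)) stop("community matrix values must be non-negative")
  if (basis == "incidence" && !all(values %in% c(0, 1)))
    stop("incidence matrix must contain only 0 and 1")
  if (basis == "abundance" && any(values != round(values)))
    stop("abundance matrix must contain integer counts")
  structure(values, basis = basis, class = c("community_matrix", class(values)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix: %d plots x %d species (basis: %s)\n",
              nrow(x), ncol(x), attr(x, "basis")))
  cat(sprintf("  grand total %.4g, %.1f%% zero cells\n",
              sum(x), 100 * mean(x == 0)))
  invisible(x)
}

#' Basis of a community matrix
#' @param m a [community_matrix()].
#' @return character scalar.
#' @export
matrix_basis <- function(m) attr(m, "basis") %||% "abundance"

#' Convert a community matrix to incidence (presence/absence)
#'
#' Cells greater than zero become 1, zeros stay 0.  Idempotent.
#'
#' @param m a [community_matrix()] on any basis.
#' @return a `community_matrix` with `basis = "incidence"`.
#' @export
to_incidence <- function(m) {
  v <- unclass(m)
  v[] <- as.numeric(v > 0)
  attributes(v)$basis <- NULL
  community_matrix(v, basis = "incidence")
}

#' Column-subset a community matrix
#'
#' @param m a [community_matrix()].
#' @param species_ids character vector of species to keep; all must be present.
#' @return a `community_matrix` restricted to those species, row order kept.
#' @export
subset_matrix <- function(m, species_ids) {
  missing <- setdiff(species_ids, colnames(m))
  if (length(missing))
    stop("species not in matrix: ", paste(missing, collapse = ", "))
  community_matrix(unclass(m)[, species_ids, drop = FALSE],
                   basis = matrix_basis(m))
}

#' Read / write community matrices as CSV
#'
#' CSV layout: plot ids in the first column (`plot_id`), species ids as the
#' remaining column headers.
#'
#' @param m a [community_matrix()].
#' @param path file path.
#' @param basis basis to declare when reading.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns a `community_matrix`.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(plot_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, basis = "abundance") {
  df <- utils::read.csv(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  community_matrix(v, basis = basis)
}
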