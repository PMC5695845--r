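#' Analysis configuration
#'
#' Collects every tunable of the full pipeline.  A seed is mandatory: all
#' permutation streams are forked from it per stage and response, so two
#' runs with the same config are byte-identical and adding permutations to
#' one stage never perturbs another.
#'
#' @param seed master RNG seed (integer).
#' @param min_dbh census inclusion threshold, cm (default 10).
#' @param cutoff_abundance,cutoff_biomass optional explicit last common
#'   ranks for the two splits; `NULL` uses the automatic knee
#'   ([detect_inflection()]).
#' @param hellinger_biomass Hellinger-transform the biomass composition
#'   (default `FALSE`; sensitivity switch).
#' @param alpha significance level for forward selection (default 0.05).
#' @param nperm permutations for selection and fraction tests (default 999).
#' @param moran_alpha,moran_nperm Moran's I screening level and
#'   permutations (defaults 0.05 and 999).
#' @param truncation PCNM truncation override, m (`NULL`: longest minimum
#'   spanning tree edge).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(seed, min_dbh = 10,
                            cutoff_abundance = NULL, cutoff_biomass = NULL,
                            hellinger_biomass = FALSE,
                            alpha = 0.05, nperm = 999,
                            moran_alpha = 0.05, moran_nperm = 999,
                            truncation = NULL) {
  if (missing(seed)) stop("analysis_config needs a seed")
  stopifnot(alpha > 0, alpha < 1, moran_alpha > 0, moran_alpha < 1,
            nperm >= 99, moran_nperm >= 99)
  structure(list(seed = as.integer(seed), min_dbh = min_dbh,
                 cutoff_abundance = cutoff_abundance,
                 cutoff_biomass = cutoff_biomass,
                 hellinger_biomass = hellinger_biomass,
                 alpha = alpha, nperm = nperm,
                 moran_alpha = moran_alpha, moran_nperm = moran_nperm,
                 truncation = truncation),
            class = "analysis_config")
}

#' Run the full metacommunity variance-partitioning analysis
#'
#' Executes the complete chain: census filter, plot-by-species matrices on
#' the abundance and biomass bases, common/rare splits with
#' information-content equalization (abundance-based split for the
#' abundance-side attributes, biomass-based split for the biomass
#' attributes), the 18 response attributes, PCNM construction and Moran's I
#' screening, permutation forward selection of the topographic and spatial
#' candidate sets per response, and two-set variance partitioning with
#' fraction tests.
#'
#' @param trees stem table (`plot_id`, `species_id`, `dbh_cm`, `height_m`).
#' @param plots plot table (`plot_id`, `x_m`, `y_m`, covariates).
#' @param config an [analysis_config()].
#' @return a `report_table`: list with `table` (18-row data.frame of
#'   fractions, p-values and bookkeeping), `splits`, `pcnm`, `selections`,
#'   `partitions`, `config`.
#' @export
run_analysis <- function(trees, plots, config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "': ", conditionMessage(e), call. = FALSE))
  }
  trees <- stage("census", {
    validate_trees(trees)
    filter_census(trees, config$min_dbh)
  })
  abund <- stage("matrices",
                 build_matrix(trees, "abundance", plot_ids = plots$plot_id))
  biom <- stage("matrices",
                build_matrix(trees, "biomass", plot_ids = plots$plot_id))
  plots <- plots[match(rownames(abund), plots$plot_id), , drop = FALSE]
  split_a <- stage("commonness",
                   split_common_rare(abund, config$cutoff_abundance))
  split_b <- stage("commonness",
                   split_common_rare(biom, config$cutoff_biomass))
  responses <- stage("attributes",
                     build_responses(abund, biom, split_a, split_b,
                                     config$hellinger_biomass))
  coords <- as.matrix(plots[, c("x_m", "y_m")])
  rownames(coords) <- plots$plot_id
  topo <- as.matrix(plots[, setdiff(names(plots),
                                    c("plot_id", "x_m", "y_m")),
                          drop = FALSE])
  rownames(topo) <- plots$plot_id
  pcnm <- stage("spatial", {
    d <- distance_matrix(coords)
    b <- pcnm_basis(d, truncation = config$truncation)
    screen_eigenbasis(b, d, alpha = config$moran_alpha,
                      nperm = config$moran_nperm,
                      seed = stage_seed(config$seed, "moran"))
  })
  spa <- retained_vectors(pcnm)
  selections <- list()
  partitions <- list()
  rows <- list()
  for (key in names(responses)) {
    r <- responses[[key]]
    Y <- r$value
    fsE <- stage(paste0("selection/", key),
                 forward_select(Y, topo, alpha = config$alpha,
                                nperm = config$nperm,
                                seed = stage_seed(config$seed,
                                                  paste0("selE.", key))))
    fsS <- if (ncol(spa) > 0)
      stage(paste0("selection/", key),
            forward_select(Y, spa, alpha = config$alpha,
                           nperm = config$nperm,
                           seed = stage_seed(config$seed,
                                             paste0("selS.", key))))
    else NULL
    Esel <- topo[, fsE$selected, drop = FALSE]
    Ssel <- if (!is.null(fsS)) spa[, fsS$selected, drop = FALSE]
            else spa[, 0, drop = FALSE]
    vp <- stage(paste0("partition/", key),
                variance_partition(Y, Esel, Ssel, nperm = config$nperm,
                                   seed = stage_seed(config$seed,
                                                     paste0("part.", key))))
    selections[[key]] <- list(topography = fsE, space = fsS)
    partitions[[key]] <- vp
    rows[[key]] <- data.frame(
      attribute = r$attribute, group = r$group,
      rank_from = r$rank_range[1], rank_to = r$rank_range[2],
      n_env_selected = vp$n_env, n_spa_selected = vp$n_spa,
      topography = vp$fractions["a"], shared = vp$fractions["b"],
      space = vp$fractions["c"], unexplained = vp$fractions["d"],
      p_topography = vp$p["a"], p_space = vp$p["c"],
      p_env_marginal = vp$p["ab"], p_spa_marginal = vp$p["bc"],
      row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(factor(tab$attribute, levels = names(attribute_label)),
                   factor(tab$group, levels = response_groups)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, splits = list(abundance = split_a,
                                            biomass = split_b),
                 pcnm = pcnm, selections = selections,
                 partitions = partitions, config = config),
            class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(format_report(x, style = "text"), sep = "\n")
  invisible(x)
}

group_label <- function(group, from, to) {
  ifelse(group == "total", "Total",
         sprintf("%s (%d-%d)",
                 ifelse(group == "common", "Common", "Rare"), from, to))
}

attribute_label <- c(std_richness = "Std. Richness", abundance = "Abundance",
                     biomass = "Biomass", c_incidence = "C. Incidence",
                     c_abundance = "C. Abundance", c_biomass = "C. Biomass")

## "25.9***" | "1.9ns" | "-" (set empty -> fraction not computed)
fmt_frac <- function(frac, p, computed, testable = TRUE) {
  ifelse(!computed, "-",
         paste0(sprintf("%.1f", 100 * frac),
                if (testable) signif_code(p) else ""))
}

#' Format an analysis report
#'
#' Renders the 18-row partition table in the conventional layout:
#' fractions as percentages to one decimal, significance stars from the
#' conditional fraction tests (`*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `ns` otherwise), and a dash for fractions that were not
#' computed because no variable of the set survived forward selection.
#'
#' @param x a `report_table` from [run_analysis()].
#' @param style `"text"` (fixed-width table with footnotes) or `"csv"`.
#' @return character vector, one element per line.
#' @export
format_report <- function(x, style = c("text", "csv")) {
  style <- match.arg(style)
  t <- x$table
  has_e <- t$n_env_selected > 0
  has_s <- t$n_spa_selected > 0
  out <- data.frame(
    attribute = attribute_label[t$attribute],
    group = group_label(t$group, t$rank_from, t$rank_to),
    topography = fmt_frac(t$topography, t$p_topography, has_e),
    shared = fmt_frac(t$shared, NA, has_e & has_s, testable = FALSE),
    space = fmt_frac(t$space, t$p_space, has_s),
    not_explained = sprintf("%.1f", 100 * t$unexplained),
    row.names = NULL)
  names(out) <- c("Attribute", "Group", "Topography (%)", "Shared (%)",
                  "Space (%)", "Not explained (%)")
  if (style == "csv") {
    con <- textConnection("lines", "w", local = TRUE)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
    return(lines)
  }
  widths <- pmax(nchar(names(out)),
                 apply(out, 2, function(col) max(nchar(col))))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  lines <- paste(mapply(pad, c(names(out)), widths), collapse = "  ")
  for (i in seq_len(nrow(out)))
    lines <- c(lines,
               paste(mapply(pad, unlist(out[i, ]), widths), collapse = "  "))
  c(lines, "",
    "*p < 0.05. **p < 0.01. ***p < 0.001. ns non-significant.",
    "- : no variable of the set survived forward selection.")
}

#' Write the report and intermediate artifacts
#'
#' @param x a `report_table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(format_report(x, "csv"), file.path(dir, "report.csv"))
  writeLines(format_report(x, "text"), file.path(dir, "report.txt"))
  utils::write.csv(split_report(x$splits$abundance),
                   file.path(dir, "split_abundance.csv"), row.names = FALSE)
  utils::write.csv(split_report(x$splits$biomass),
                   file.path(dir, "split_biomass.csv"), row.names = FALSE)
  utils::write.csv(x$pcnm$moran, file.path(dir, "pcnm_screening.csv"),
                   row.names = FALSE)
  invisible(dir)
}
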