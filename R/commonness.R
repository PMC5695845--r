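#' Rank species by total abundance or biomass
#'
#' Orders species by descending column total on the matrix basis; ties are
#' broken by species id ascending so the ranking is deterministic.
#'
#' @param m a [community_matrix()] on the `abundance` or `biomass` basis.
#' @return a `species_ranking`: list with `species_ids` (descending-total
#'   order), `totals` (same order) and `basis`.
#' @export
rank_species <- function(m) {
  basis <- matrix_basis(m)
  if (!basis %in% c("abundance", "biomass"))
    stop("ranking needs an abundance or biomass matrix")
  totals <- colSums(m)
  if (all(totals == 0)) stop("all-zero matrix: no rankable species")
  ord <- order(-totals, names(totals))
  structure(list(species_ids = names(totals)[ord],
                 totals = unname(totals[ord]),
                 basis = basis),
            class = "species_ranking")
}

#' @export
print.species_ranking <- function(x, ...) {
  cat(sprintf("species ranking (%s): %d species, totals %.4g .. %.4g\n",
              x$basis, length(x$species_ids), max(x$totals), min(x$totals)))
  invisible(x)
}

#' Knee of the rank-abundance curve
#'
#' Deterministic surrogate for the visual inflection-point judgement that
#' separates common from rare species: on the curve of log10(total) against
#' rank (positive totals only), find the rank maximizing the perpendicular
#' distance to the chord joining the first and last points.  Ties go to the
#' smallest rank.  When the curve is essentially log-linear the distances
#' are all near zero and the result is flagged as having no pronounced knee;
#' analyses meant to mirror a visually chosen cutoff should pass an explicit
#' `cutoff_rank` to [split_common_rare()].
#'
#' @param ranking a `species_ranking` from [rank_species()].
#' @return list with `cutoff_rank` (last common rank), `distance` (the
#'   maximal chord distance) and `pronounced` (logical flag).
#' @export
detect_inflection <- function(ranking) {
  tot <- ranking$totals
  pos <- which(tot > 0)
  if (length(pos) < 3L)
    stop("need at least 3 species with positive totals to locate a knee")
  x <- as.numeric(pos)
  y <- log10(tot[pos])
  x1 <- x[1L]; y1 <- y[1L]
  x2 <- x[length(x)]; y2 <- y[length(y)]
  ## perpendicular distance from (x, y) to the chord (x1,y1)-(x2,y2)
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  k <- which.max(d)  # which.max takes the first maximum: smallest rank
  list(cutoff_rank = pos[k],
       distance = d[k],
       pronounced = d[k] > sqrt(.Machine$double.eps))
}

#' Information content of a species set
#'
#' The binomial variance of the incidence matrix, `sum p_i (1 - p_i)`, where
#' `p_i` is the proportion of plots occupied by species i.  Used to equalize
#' the statistical content of the common and rare matrices before comparing
#' their variance partitions.
#'
#' @param m a [community_matrix()] (any basis; incidence is derived).
#' @param species_ids species subset (default: all columns).
#' @return dimensionless non-negative real.
#' @export
information_content <- function(m, species_ids = colnames(m)) {
  if (!length(species_ids)) stop("empty species subset")
  inc <- to_incidence(subset_matrix(m, species_ids))
  p <- colMeans(inc)
  sum(p * (1 - p))
}

#' Trim the rare set to a target information content
#'
#' Removes rare species one at a time from the abundant end of the rare set
#' (following species rank), so the retained set is always the rarest tail
#' of the ranking.  Among all removal counts k, returns the one whose
#' remaining information content is closest to `target_ic`; ties favour
#' fewer removals.  If the rare set already has less information than the
#' target, nothing is removed and the result is flagged.
#'
#' @param rare_ids rare species ids in rank order (most to least abundant).
#' @param target_ic information content of the common set.
#' @param m the [community_matrix()] the incidence frequencies come from.
#' @return list with `trimmed_rare_ids`, `removed_ids`, `ic` (achieved),
#'   `below_target` (logical flag).
#' @export
equalize_information <- function(rare_ids, target_ic, m) {
  inc <- to_incidence(subset_matrix(m, rare_ids))
  p <- colMeans(inc)
  contrib <- p * (1 - p)              # in rank order
  ic_full <- sum(contrib)
  if (ic_full < target_ic) {
    warning("rare set information content already below target; not trimming")
    return(list(trimmed_rare_ids = rare_ids, removed_ids = character(),
                ic = ic_full, below_target = TRUE))
  }
  ## remaining IC after removing the k most-abundant rare species
  ic_after <- ic_full - cumsum(c(0, contrib[-length(contrib)]))
  ic_after <- c(ic_after, 0)          # k = length(rare_ids): nothing left
  k <- which.min(abs(ic_after - target_ic)) - 1L  # first min = fewest removals
  list(trimmed_rare_ids = rare_ids[seq_along(rare_ids) > k],
       removed_ids = rare_ids[seq_len(k)],
       ic = unname(ic_after[k + 1L]),
       below_target = FALSE)
}

#' Split species into common and rare sets of equal information content
#'
#' Ranks species, places the common/rare boundary (either at an explicit
#' `cutoff_rank`, mirroring a visually chosen inflection point, or at the
#' automatic knee from [detect_inflection()]), and trims the rare set until
#' its information content matches the common set's.
#'
#' @param m a [community_matrix()] on the abundance or biomass basis.
#' @param cutoff_rank optional explicit last common rank; overrides the knee.
#' @return a `common_rare_split`: list with `cutoff_rank`, `ranking`,
#'   `common_ids`, `rare_ids`, `trimmed_rare_ids`, `ic_common`,
#'   `ic_rare_full`, `ic_rare_trimmed`, `auto_knee` metadata.
#' @export
split_common_rare <- function(m, cutoff_rank = NULL) {
  ranking <- rank_species(m)
  knee <- NULL
  if (is.null(cutoff_rank)) {
    knee <- detect_inflection(ranking)
    cutoff_rank <- knee$cutoff_rank
  }
  cutoff_rank <- as.integer(cutoff_rank)
  if (cutoff_rank < 1L || cutoff_rank >= length(ranking$species_ids))
    stop("cutoff_rank must leave at least one common and one rare species")
  common <- ranking$species_ids[seq_len(cutoff_rank)]
  rare <- ranking$species_ids[-seq_len(cutoff_rank)]
  ic_common <- information_content(m, common)
  trim <- equalize_information(rare, ic_common, m)
  structure(list(cutoff_rank = cutoff_rank,
                 ranking = ranking,
                 common_ids = common,
                 rare_ids = rare,
                 trimmed_rare_ids = trim$trimmed_rare_ids,
                 ic_common = ic_common,
                 ic_rare_full = information_content(m, rare),
                 ic_rare_trimmed = trim$ic,
                 auto_knee = knee),
            class = "common_rare_split")
}

#' @export
print.common_rare_split <- function(x, ...) {
  s <- length(x$ranking$species_ids)
  first_kept <- s - length(x$trimmed_rare_ids) + 1L
  cat(sprintf("common/rare split (%s basis)\n", x$ranking$basis))
  cat(sprintf("  common: ranks 1-%d (%d species), IC %.3f\n",
              x$cutoff_rank, length(x$common_ids), x$ic_common))
  cat(sprintf("  rare (trimmed): ranks %d-%d (%d species), IC %.3f (full %.3f)\n",
              first_kept, s, length(x$trimmed_rare_ids),
              x$ic_rare_trimmed, x$ic_rare_full))
  invisible(x)
}

#' Split report table
#'
#' One row per species with its rank, total and group membership
#' (`common`, `removed`, `rare_trimmed`).
#'
#' @param split a [split_common_rare()] result.
#' @return data.frame with columns `species_id`, `rank`, `total`, `group`.
#' @export
split_report <- function(split) {
  ids <- split$ranking$species_ids
  grp <- ifelse(ids %in% split$common_ids, "common",
                ifelse(ids %in% split$trimmed_rare_ids, "rare_trimmed",
                       "removed"))
  data.frame(species_id = ids,
             rank = seq_along(ids),
             total = split$ranking$totals,
             group = grp)
}
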