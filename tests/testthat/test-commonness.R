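ranking_of <- function(totals) {
  ids <- names(totals) %||% letters[seq_along(totals)]
  m <- community_matrix(matrix(rep(unname(totals), each = 2) / 2, 2,
                               length(totals),
                               dimnames = list(c("P1", "P2"), ids)),
                        basis = "biomass")
  rank_species(m)
}

test_that("species ranking sorts by descending total with id tie-break", {
  m <- community_matrix(matrix(c(2, 3, 4, 5, 1, 0), 2, 3,
                               dimnames = list(c("P1", "P2"),
                                               c("A", "B", "C"))),
                        "abundance")
  r <- rank_species(m)
  expect_equal(r$species_ids, c("B", "A", "C"))
  expect_equal(r$totals, c(9, 5, 1))
  # ties break by id ascending
  mt <- community_matrix(matrix(c(3, 0, 0, 3), 2, 2,
                               dimnames = list(c("P1", "P2"), c("B", "A"))),
                        "abundance")
  expect_equal(rank_species(mt)$species_ids, c("A", "B"))
  # invariant to plot permutation
  expect_equal(rank_species(community_matrix(unclass(m)[2:1, ], "abundance")),
               r)
  z <- community_matrix(matrix(0, 2, 2, dimnames = list(c("P1", "P2"),
                                                        c("A", "B"))),
                        "abundance")
  expect_error(rank_species(z), "no rankable")
})

test_that("knee detection maximizes chord distance on the log-rank curve", {
  r <- ranking_of(c(1000, 10, 9, 8, 7, 6))
  k <- detect_inflection(r)
  expect_equal(k$cutoff_rank, 2)
  expect_true(k$pronounced)
  # brute-force perpendicular-distance oracle on random curves
  set.seed(31)
  for (i in 1:20) {
    tot <- sort(rpois(12, 40) + 1, decreasing = TRUE)
    names(tot) <- sprintf("s%02d", 1:12)
    r <- ranking_of(tot)
    x <- seq_along(tot); y <- log10(r$totals)
    chord <- function(k) {
      p1 <- c(1, y[1]); p2 <- c(length(y), y[length(y)])
      abs((p2[2]-p1[2])*x[k] - (p2[1]-p1[1])*y[k] + p2[1]*p1[2] - p2[2]*p1[1]) /
        sqrt(sum((p2 - p1)^2))
    }
    expect_equal(detect_inflection(r)$cutoff_rank,
                 which.max(vapply(x, chord, numeric(1))))
  }
})

test_that("a log-linear (geometric) curve has no pronounced knee", {
  r <- ranking_of(100 * 0.5^(0:7))
  k <- detect_inflection(r)
  expect_false(k$pronounced)
  expect_equal(k$cutoff_rank, 1)  # smallest rank by the tie rule
  expect_error(detect_inflection(ranking_of(c(5, 3))), "at least 3")
})

test_that("information content is the binomial variance of incidence", {
  # 4 plots; spA in all (p = 1), spB in 2 (p = .5), spC in 1 (p = .25)
  v <- cbind(spA = c(1, 2, 1, 3), spB = c(1, 1, 0, 0), spC = c(0, 1, 0, 0))
  rownames(v) <- paste0("P", 1:4)
  m <- community_matrix(v, "abundance")
  expect_equal(information_content(m, "spA"), 0)
  expect_equal(information_content(m, "spB"), 0.25)
  expect_equal(information_content(m, c("spB", "spC")), 0.4375)
  expect_error(information_content(m, "nope"), "not in matrix")
  expect_error(information_content(m, character()), "empty")
  # additivity over disjoint subsets and the single-species bound
  expect_equal(information_content(m),
               information_content(m, c("spA", "spB")) +
                 information_content(m, "spC"))
  expect_true(all(sapply(colnames(m), function(s)
    information_content(m, s) <= 0.25)))
})

test_that("information equalization trims the abundant end of the rare set", {
  # rare contributions in rank order: 0.25, 0.25, 0.1875
  v <- cbind(r1 = c(1, 1, 0, 0), r2 = c(0, 1, 1, 0), r3 = c(0, 0, 0, 1))
  rownames(v) <- paste0("P", 1:4)
  m <- community_matrix(v, "abundance")
  eq <- equalize_information(c("r1", "r2", "r3"), target_ic = 0.4, m = m)
  expect_equal(eq$removed_ids, "r1")
  expect_equal(eq$trimmed_rare_ids, c("r2", "r3"))
  expect_equal(eq$ic, 0.4375)
  # target equal to the current content: nothing removed
  eq0 <- equalize_information(c("r1", "r2", "r3"), target_ic = 0.6875, m = m)
  expect_equal(eq0$removed_ids, character())
  # rare set already below target: unchanged with a flag
  expect_warning(
    lo <- equalize_information("r3", target_ic = 0.5, m = m),
    "below target")
  expect_true(lo$below_target)
  expect_equal(lo$trimmed_rare_ids, "r3")
})

test_that("the retained rare set is the globally best suffix", {
  set.seed(77)
  for (i in 1:25) {
    n_sp <- sample(4:12, 1)
    v <- matrix(rbinom(8 * n_sp, 1, 0.4), 8, n_sp,
                dimnames = list(paste0("P", 1:8), sprintf("r%02d", 1:n_sp)))
    keep <- colSums(v) > 0
    if (sum(keep) < 3) next
    m <- community_matrix(v[, keep, drop = FALSE], "abundance")
    ids <- colnames(m)[order(-colSums(m), colnames(m))]
    target <- runif(1, 0, information_content(m, ids))
    eq <- equalize_information(ids, target, m)
    # retained set is a suffix of the ranking
    expect_equal(eq$trimmed_rare_ids,
                 ids[seq(length(ids) - length(eq$trimmed_rare_ids) + 1,
                         length(ids))])
    # brute force over every removal count k
    ic_all <- vapply(0:length(ids), function(k) {
      if (k == length(ids)) 0
      else information_content(m, ids[seq_along(ids) > k])
    }, numeric(1))
    best <- min(abs(ic_all - target))
    expect_equal(abs(eq$ic - target), best, tolerance = 1e-12)
    # fewest removals among ties
    expect_equal(length(eq$removed_ids),
                 which(abs(ic_all - target) <= best + 1e-12)[1] - 1)
  }
})

test_that("split_common_rare honours explicit cutoffs and equalizes IC", {
  sim <- small_simulation(seed = 5, n_plots = 20, n_species = 40)
  m <- sim$community
  sp <- split_common_rare(m, cutoff_rank = 8)
  expect_equal(sp$cutoff_rank, 8)
  expect_equal(sp$common_ids, sp$ranking$species_ids[1:8])
  expect_true(all(sp$trimmed_rare_ids %in% sp$rare_ids))
  expect_lte(sp$ic_rare_trimmed, sp$ic_rare_full)
  # trimmed set is closer to the common IC than the untrimmed rare set
  expect_lte(abs(sp$ic_rare_trimmed - sp$ic_common),
             abs(sp$ic_rare_full - sp$ic_common))
  rep <- split_report(sp)
  expect_equal(nrow(rep), ncol(m))
  expect_setequal(unique(rep$group), c("common", "removed", "rare_trimmed"))
  # automatic knee path returns a valid cutoff
  sp2 <- split_common_rare(m)
  expect_true(sp2$cutoff_rank >= 1 &&
                sp2$cutoff_rank < length(sp2$ranking$species_ids))
})
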