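---
title: "Partitioning metacommunity variation between topography and space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning metacommunity variation between topography and space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapart)
```

## The statistical model

`metapart` asks how much of the variation in a community attribute is
attributable to measured environmental gradients (here: topography),
how much to spatial structure, and how much to their overlap. The
machinery is multivariate least squares throughout. For a response
matrix $Y$ (plots × species, column-centered) and predictors $X$, the
redundancy statistic is the trace $R^2$,

$$R^2 = \frac{\sum_k \lVert \hat{y}_k \rVert^2}{\sum_k \lVert y_k \rVert^2},$$

which reduces to the ordinary coefficient of determination when $Y$ has
one column — so partial multiple regression (univariate attributes) and
partial RDA (composition matrices) are literally the same code path
here. Because $R^2$ grows mechanically with the number of predictors
and shrinks with sample size, all fractions are reported on Ezekiel's
adjusted scale,

$$R^2_{adj} = 1 - (1 - R^2)\,\frac{n-1}{n-m-1},$$

which is centered on zero when the predictors are pure noise (this is
verified by simulation in the test suite). With an environmental set
$E$ and a spatial set $S$, inclusion–exclusion on adjusted $R^2$ gives
the four fractions

- $a = R^2_{adj}(E{+}S) - R^2_{adj}(S)$ — topography independent of space,
- $b = R^2_{adj}(E) + R^2_{adj}(S) - R^2_{adj}(E{+}S)$ — inseparably shared,
- $c = R^2_{adj}(E{+}S) - R^2_{adj}(E)$ — space independent of topography,
- $d = 1 - R^2_{adj}(E{+}S)$ — unexplained,

with $a+b+c+d = 1$ by construction (asserted to $10^{-10}$ on every
run). $a$ and $c$ can legitimately be slightly negative; they are
reported as computed. $b$ is not a projection onto any subspace and
admits no permutation test; $a$ and $c$ are tested conditionally
(Freedman–Lane: residuals of the reduced model are permuted and its
fitted values added back), the marginal models $a{+}b$ and $b{+}c$ by
unrestricted permutation. All permutation p-values are
$(1 + \#\{F^* \ge F\})/(1 + n_{perm})$, hence never zero.

Assumptions worth stating: the responses are modelled linearly in the
predictors; composition matrices are made amenable to this Euclidean
geometry by the Hellinger transform
($y'_{ij} = \sqrt{y_{ij}/y_{i+}}$), applied by default to the
abundance-based composition only. Whether the biomass composition
should also be transformed is genuinely open; the package exposes
`hellinger_biomass` (default `FALSE`) rather than asserting either
choice.

## From census to responses

The census module ingests one row per stem (plot, species, DBH in cm,
total height in m), keeps stems with DBH ≥ 10 cm (inclusive boundary),
and computes per-stem aboveground biomass as
$0.044\,(\mathrm{DBH}^2 \cdot H)^{0.9719}$. The output unit is treated
as kilograms, consistent with the Amazon allometry family this equation
belongs to; the unit is metadata only — no downstream computation
depends on it. Stems without a species identification are rejected at
parse time rather than silently pooled.

Six attributes are derived per species group. Standardized richness is
the residual of an OLS regression of plot richness on plot total
abundance: richness co-varies with the number of individuals sampled,
and the residual isolates the part of richness that abundance cannot
explain. Plots with zero total are kept as zero rows (dropping them
would desynchronize the spatial eigenbasis) with a logged warning.

## Common and rare species of equal information content

Species are ranked by total abundance (or biomass; ties broken by
species id so ranking is deterministic). The boundary between common
and rare species is classically chosen by eye at the inflection of the
rank–log-abundance curve. The automated surrogate finds the rank
maximizing the perpendicular distance to the chord joining the first
and last positive-total points of the $(\mathrm{rank},
\log_{10}\mathrm{total})$ curve — a standard knee heuristic (log base
10; zero totals excluded). When the curve is near log-linear every
distance is close to zero; the result is then flagged as having no
pronounced knee, and analyses meant to mirror a visually chosen
boundary should pass an explicit `cutoff_rank`.

Because a 200-species rare matrix simply carries more statistical
information than a 20-species common matrix, the rare set is trimmed to
equal information content, measured as the binomial variance of the
incidence matrix $\sum_i p_i(1-p_i)$ with $p_i$ the occupancy
proportion. Removal proceeds from the *abundant* end of the rare set,
so the retained group is always the rarest tail of the ranking; among
all removal counts the one whose remaining content is closest to the
common set's is chosen (ties favour fewer removals — "closest" rather
than "first crossing", because the goal is equal content, not a bound).
The test suite verifies by exhaustive enumeration on small instances
that this is the global minimizer. If the rare set starts below the
target the set is returned untrimmed with a flag.

## Spatial eigenfunctions

Spatial predictors are PCNM axes: principal coordinates of a truncated
Euclidean distance matrix. Distances beyond a threshold $t$ are
replaced by $4t$, and $-\tfrac{1}{2}D^{*2}$ is double-centered (Gower)
and eigendecomposed. The truncation threshold defaults to the longest
edge of the minimum spanning tree — the smallest $t$ that keeps the
plot network connected — and both $t$ and the $4t$ multiplier are
config-overridable, since different conventions exist. Eigenvector
signs are arbitrary; determinism is restored by making each column's
largest-magnitude loading positive. Eigenvalues within
$10^{-9}\,\max|\lambda|$ of zero are discarded as numerical zeros.

Axes are retained if the eigenvalue is positive *and* the axis shows
positive, significant spatial autocorrelation: Moran's $I$ above its
null expectation $-1/(n-1)$ with a one-sided permutation p-value at
most `moran_alpha`. The weight matrix is binary connectivity at the
truncation threshold — chosen for coherence with the truncation graph —
and the test uses permutations (default 999, seeded) rather than the
normal approximation because plot networks of a few dozen sites are
small. Weight scheme, permutation count and alpha are exposed as
configuration with these defaults, asserted as conventions of the
package, not of any particular study.

## Forward selection with double stopping

Candidate predictors (five topographic covariates; the retained PCNM
axes) are screened per response by permutation-based forward selection:

1. a **global gate** — if the permutation test of the full candidate
   model is not significant at `alpha`, nothing is selected (this is
   what keeps the procedure's family-wise null rejection rate near
   `alpha`; verified at $n = 46$ by 1000-dataset simulation in the
   acceptance tests);
2. iterative entry of the candidate adding the most explained variance,
   each entry tested by Freedman–Lane pseudo-F conditioned on the
   variables already selected;
3. **stopping** when the best candidate's p-value exceeds `alpha` *or*
   when the cumulative adjusted $R^2$ would exceed the full model's —
   the double stopping criterion.

The adjusted-$R^2$ ceiling deserves honesty: it is conservative. When
the non-selected candidates are pure noise, the adjusted $R^2$ of the
true subset and of the full model estimate the same quantity, and
sampling noise decides whether the last genuinely informative variable
is admitted. The test suite therefore asserts what the procedure
actually guarantees (a true variable enters first; false inclusions
are rare) rather than perfect support recovery. Selection is
bit-reproducible given a seed, and entry order is invariant to
candidate column order (exact ties break by candidate name).

Whether selection should be gated on the global test at all is not
universally agreed; the gate is the default here because it is what
controls the type-I error, and it is documented rather than optional.

## The synthetic metacommunity generator

The generator exists so that every stage — and the partition's ability
to recover the generating process — is testable without any field
data. It emulates the target study design: `n_plots = 46` plots
scattered uniformly over a `extent = 2000` m landscape, a
`n_species = 230` species pool, five topographic covariates drawn from
zero-mean Gaussian processes with exponential covariance
(`env_range = 500` m), and log-series-like base abundances
$A_s \propto \theta^s/s$ (`abundance_rank_shape = 0.99`), scaled so a
null-model plot holds `mean_stems = 110` stems on average — a typical
terra-firme density for stems ≥ 10 cm DBH. The realized rank-abundance
curve spans more than two orders of magnitude: few common, many rare
species.

Archetypes modify the log-intensity of species $s$ at plot $j$:

- **species sorting**: a Gaussian niche on the first (standardized)
  covariate, $-(e_j - \mu_s)^2 / 2\sigma_s^2$, optima spread uniformly
  over the observed gradient, breadth `niche_sd` (default 1 covariate
  SD — strong compositional turnover without starving the counts;
  substantially narrower breadths mostly thin the realized communities
  into sparse noise);
- **neutral**: a species-specific spatially autocorrelated field
  (range `spatial_range`, default 500 m) — a *phenomenological* stand-in
  for dispersal limitation and drift, not a mechanistic demographic
  model;
- **mass effect**: the `mixture_w`-weighted combination of the two
  (at `mixture_w = 1` it reproduces species sorting exactly, same
  seed);
- **null**: base abundances only.

Counts are Poisson (negative binomial when `noise > 0`). The stem-level
census is synthesized per individual: DBH from a shifted exponential
above 10 cm (mean 18 cm), height from $2.6\,\mathrm{DBH}^{0.6}$ with
10% lognormal noise. Every generator is a pure function of
(config, seed).

What the generator does **not** emulate: measurement error in the
covariates, spatially clustered plot placement along logging roads,
height–DBH allometries varying by species, patch-dynamics
(competition–colonization) regimes, or temporal turnover. Passing
recovery tests therefore demonstrates internal statistical validity —
the pipeline attributes variance to the process that generated it —
not that any particular field system matches an archetype.

## Numerical choices and degenerate inputs

- OLS everywhere via pivoted QR; no matrix inversion.
- A saturated fit can leave a residual sum of squares of $-10^{-16}$;
  residual SS is clamped at zero, making the pseudo-F $+\infty$ and its
  permutation p-value the minimal $1/(n_{perm}+1)$.
- The union design $E \cup S$ may be collinear *across* sets — shared
  information is the point of fraction $b$ — so the combined model is
  fitted on its effective rank. Rank deficiency *within* a set is an
  error naming the collinear columns.
- A conditional test whose tested set adds no rank over the
  conditioning set (e.g. identical sets) reports `NA`.
- Duplicate plot coordinates are allowed (logged); geographic lat/lon
  input is rejected with instructions to project first.
- Empty selection results propagate as zero-column predictor sets: the
  corresponding pure and shared fractions are zero and the report
  prints a dash, never a fabricated zero with a star.
- One master seed is forked per stage and per response (hash of the
  stage name), so raising the permutation count in one stage never
  perturbs another; two runs with the same config are byte-identical.

## Problem sizes in the test suite

The suite pins its heavier checks at the package's target scale:
partition identities on 1000 random instances at $n = 46$ plots with up
to 5 + 8 predictors; type-I simulations with 1000 null datasets × 199
permutations; archetype recovery with 200 replicates × 230 species per
archetype; oracle comparisons (brute-force double-centering, exhaustive
spanning-tree and trimming enumeration, nested-model partial F) on
instances small enough to enumerate. The full suite runs in about a
minute on one CPU.

## Known limitations

- Two predictor sets only; three-way partitions and hierarchical/
  commonality analysis are out of scope.
- PCNM with the classical truncation, not the general dbMEM family with
  arbitrary spatial weighting; no trend-surface detrending.
- The knee heuristic is a surrogate for expert judgement; for analyses
  meant to mirror a visually chosen split, pass the cutoff explicitly.
- Adjusted-$R^2$ fractions are comparable across predictor-set sizes
  but remain biased for strongly autocorrelated predictors; when the
  environment itself is broad-scale, part of its signal is genuinely
  ambiguous between $E$ and $S$ and lands in $b$.
- Rarefaction-based richness standardization and diversity indices are
  deliberately not provided; the residual-richness construction is the
  one attribute of that kind.
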