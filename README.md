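# metapart

Variance partitioning of metacommunity structure for common and rare
species.

## The problem

Local communities are shaped by two broad classes of processes:
environmental filtering (niche processes — species sort along gradients
such as topography) and spatial processes (dispersal limitation, mass
effects, ecological drift). A standard way to weigh them against each
other is to partition the variation of community attributes between an
environmental predictor set **E** and a spatial predictor set **S**
built from the sampling locations, and to ask how the answer differs
between the few common species and the many rare ones that make up most
of a species pool.

`metapart` implements that full workflow for stem-level forest census
data, aimed at community ecologists working with plot networks (it
applies equally to any site-by-species table, e.g. microbiome
beta-diversity):

1. **Census ingestion** — stems with DBH ≥ 10 cm, per-stem aboveground
   biomass from the allometry `AGB = 0.044 (DBH² · H)^0.9719` (DBH cm,
   height m, kg), aggregation to plots × species matrices on abundance
   and biomass bases.
2. **Common/rare split** — species ranked by total abundance (or
   biomass); the split point is the knee of the rank–log-abundance
   curve (or an explicit, visually chosen rank); the rare set is then
   trimmed from its abundant end until its information content — the
   binomial variance of the incidence matrix, `Σ pᵢ(1 − pᵢ)` — matches
   the common set's, so the two groups are compared on equal footing.
3. **Response attributes** — three univariate vectors (standardized
   richness = residuals of richness regressed on abundance, total
   abundance, total biomass) and three composition matrices (incidence,
   Hellinger-transformed abundance, biomass) for each species group:
   18 responses.
4. **Spatial eigenfunctions** — PCNM: principal coordinates of the
   truncated (longest-MST-edge) Euclidean distance matrix, screened to
   the axes with positive eigenvalues and positive, permutation-
   significant Moran's I.
5. **Forward selection** — permutation pseudo-F selection with the
   double stopping criterion (per-step alpha plus the global model's
   adjusted R² ceiling, gated by a global test), run separately on the
   topographic and spatial candidate sets for every response.
6. **Partition** — adjusted R² (Ezekiel) fractions by
   inclusion–exclusion: `a` pure topography, `b` shared, `c` pure
   space, `d` unexplained, with Freedman–Lane permutation tests of the
   testable fractions; univariate responses use partial multiple
   regression, multivariate ones partial RDA — one code path.

A synthetic metacommunity generator (species-sorting, mass-effect,
neutral and null archetypes over Gaussian-process landscapes, log-series
species pools, stem-level census synthesis) makes every stage testable
without field data.

## Worked example

Simulate a species-sorting metacommunity at the default study scale
(46 plots of 25 m × 100 m, 230-species pool) and run the full analysis
with explicit common/rare cutoffs at ranks 22 (abundance) and 35
(biomass):

```r
library(metapart)

cfg    <- scenario_config("species_sorting", seed = 7)
sim    <- simulate_metacommunity(cfg)
report <- run_analysis(sim$trees, sim$plots,
                       analysis_config(seed = 8, cutoff_abundance = 22,
                                       cutoff_biomass = 35))

report$splits$abundance
#> common/rare split (abundance basis)
#>   common: ranks 1-22 (22 species), IC 4.485
#>   rare (trimmed): ranks 58-166 (109 species), IC 4.534 (full 9.731)

report
#> Attribute      Group          Topography (%)  Shared (%)  Space (%)  Not explained (%)
#> Std. Richness  Total          -               -           -          100.0
#> ...
#> Abundance      Total          34.0**          26.9        -1.0ns     40.1
#> Abundance      Common (1-22)  38.6**          30.7        -0.3ns     31.0
#> Abundance      Rare (58-166)  -               -           -          100.0
#> ...
#> C. Abundance   Total          19.3**          5.6         -0.3ns     75.4
#> C. Abundance   Common (1-22)  41.3**          -           -          58.7
#> C. Abundance   Rare (58-166)  2.5**           -           -          97.5
#> ...
#> *p < 0.05. **p < 0.01. ***p < 0.001. ns non-significant.
#> - : no variable of the set survived forward selection.
```

Reading the `Abundance / Total` row: after forward selection,
topography alone explains 34.0% of the variance in per-plot total
abundance (adjusted R², significant at p < 0.01 by the conditional
permutation test), 26.9% is shared between topography and space, the
pure spatial fraction is −1.0% (adjusted fractions can be slightly
negative) and 40.1% remains unexplained. Rows with `-` had no variable
survive forward selection for that predictor set — here the expected
outcome for rare species under a species-sorting regime with this much
sampling noise. The split report shows the equalization at work: the
raw rare set (ranks 23–166) carries information content 9.73; dropping
rare ranks 23–57 brings it to 4.53, matching the common set's 4.49.

The underlying objects are ordinary R structures: `report$table` is the
18-row data.frame of fractions and p-values, `report$pcnm$moran` the
eigenvector screening table, `report$selections` the per-response
forward-selection traces. `write_report(report, dir)` writes
`report.csv`, `report.txt` and the intermediate tables.

A thin command-line front end is included:

```sh
Rscript inst/scripts/metapart.R simulate --seed 1 --out study/
Rscript inst/scripts/metapart.R pcnm    --plots study/plots.csv --out study/
Rscript inst/scripts/metapart.R analyze --trees study/trees.csv \
        --plots study/plots.csv --seed 1 --out study/
```

## Package layout

- `R/census.R`, `R/community-matrix.R` — ingestion, allometry, matrices
- `R/commonness.R` — ranking, knee detection, information-content split
- `R/attributes.R` — the 18 response attributes, Hellinger transform
- `R/spatial.R` — PCNM, Moran's I screening
- `R/selection.R` — pseudo-F, Freedman–Lane permutations, forward
  selection
- `R/partition.R` — adjusted R², two-set variance partitioning
- `R/synth.R` — scenario configs and generators
- `R/pipeline.R` — orchestration, report formatting
- `vignettes/metacommunity-partitioning.Rmd` — the methods vignette
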