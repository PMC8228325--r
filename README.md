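# synaptomito

Analysis toolkit for studying how synaptic mitochondria respond to altered
metabotropic glutamate receptor 5 (mGluR5) signalling, built around two
complementary data types: label-free DIA/SWATH proteomics of synaptosome
preparations (wild-type vs knockout, or drug vs vehicle), and
electron-microscopy morphometry of pre- and post-synaptic mitochondria.
Downstream, protein sets are interrogated against mitochondrial
annotations, single-cell cell-type references, and a receptor-transcript
co-expression screen.

Every stage ships with a synthetic-data generator that plants known ground
truth (effect sizes, outliers, correlated genes, cell-type markers), so
the whole pipeline is testable without access to any deposited dataset.

## What it implements

**Quantification** (`filter_peptides`, `rollup_proteins`,
`cyclic_loess_normalize`, `replicate_cv`). Peptides are kept when their
identification Q-value is ≤ 10⁻³ in at least *group size − 1* samples of
at least half of the groups; proteins need ≥ 2 surviving peptides.
Protein abundance is log₂ of summed raw peptide intensities, normalized by
fast cyclic loess (10 iterations).

**Differential expression** (`modt_fit`). Empirical-Bayes moderated
t-statistics written from first principles. Per protein *g*, the pooled
two-group variance s²_g (df_g = n₁+n₂−2) is shrunk toward a prior (d₀,
s₀²) estimated by method of moments on log variances:

    s²_post = (d₀·s₀² + df_g·s²_g) / (d₀ + df_g)
    t_g     = log2FC_g / sqrt(s²_post·(1/n₁ + 1/n₂)),   df = d₀ + df_g

Regulation is called at unadjusted p < 0.01 (deliberately no
multiple-testing correction, so that the annotation-level analyses see a
richer protein list). The limma implementation is used only as an
independent cross-check in the test suite.

**Mitochondrial distribution analysis** (`randomized_selection_test`,
`category_summary`, `hypergeometric_ora`). Tests whether the fold-change
distribution of an annotated set (e.g. "known mitochondrial") differs
from randomized protein selections (100 iterations, two-sample KS against
the pooled draws), summarizes fold-changes per functional category
(OXPHOS, carrier, dynamics, ...), and runs hypergeometric
over-representation with BH correction.

**Morphometry** (`shape_metrics`, `proximity_filter`, `robust_outliers`,
`nested_genotype_test`, `mito_presence_test`). Elongation index
P²/(4πA) (= 1/circularity), a 500-nm rule restricting mitochondria to the
synaptic contact zone, ROUT-style robust outlier removal (1% FDR), and
genotype inference by a random-intercept mixed model `y ~ genotype +
(1 | animal)` with conservative between-animal degrees of freedom —
avoiding pseudoreplication across mitochondria from the same animal.

**Cell-type enrichment and co-expression** (`build_specificity`,
`bootstrap_enrichment`, `build_profiles`, `spearman_screen`).
Expression-weighted cell-type enrichment: a gene's specificity for a cell
type is its share of across-type mean CPM expression; a target set's
summed specificity is compared against 10,000 size-matched random draws
from a declared background. The co-expression screen builds per-cell-type
profiles (CPM → log₁₀(x+1) → mean over nonzero values → per-type median
normalization) and Spearman-correlates every gene with a target gene
(e.g. *Grm5*), with BH-FDR control at 0.05.

## Worked example

```r
library(synaptomito)

# a 6 vs 6 synthetic SWATH experiment with a +0.2 log2 effect planted on
# the mitochondrial stratum (25% of 400 proteins)
sim <- simulate_peptides(peptide_sim_config(
  n_proteins = 400, frac_mito = 0.25,
  effect_log2 = 0.2, effect_set = "mito", seed = 42))
pm  <- cyclic_loess_normalize(rollup_proteins(
  filter_peptides(sim$peptides, sim$design)))
fit <- modt_fit(pm, sim$design, "WT", "KO")
fit
#> Moderated t contrast KO - WT: 400 proteins
#>   prior: d0 = 12.43, s0^2 = 0.004462
#>   regulated at p < 0.01: 81 up, 14 down
```

The prior degrees of freedom (12.4) say the across-protein variance
distribution is worth about twelve extra replicates per protein. All 81
up calls are planted mitochondrial proteins (81 of the 100 planted
recovered). The handful of down calls among unchanged proteins is the
footprint of normalization: cyclic loess centres each sample while a
quarter of the proteome genuinely shifts up, nudging the remainder
slightly down — the package reports it rather than hiding it, and the
annotation-level analyses are robust to it.

The single-command pipeline runs every stage on synthetic data:

```r
report <- run_pipeline(pipeline_config(seed = 7))
report
#> Synthetic synaptosome pipeline report
#>   seed 7, parameter hash ba2e61ba
#>   peptides kept: 2025 of 2025; proteins quantified: 400
#>   median CV: WT 4.2%, KO 4.4%
#>   regulated at p < 0.01: 88 up, 23 down (100% of up are mito)
#>   randomized-selection test: D = 0.993, p = 1.1e-64
#>   nested post area (log): p = 0.0588; elongation: p = 0.121
#>   mito-containing synapses: KO 35%, WT 26% (t p = 0.045)
#>   co-expression screen: 42 significant at FDR < 0.05
```

Here the planted mitochondrial up-regulation dominates the up calls and
separates decisively from randomized selections, while the planted −20%
postsynaptic area effect lands near the detection limit of a 6+6-animal
design — the morphometry acceptance tests quantify coverage and power
over hundreds of replicates rather than a single draw.

## Package layout

- `R/sim-*.R` — synthetic-data generators with planted truth
- `R/quantify.R`, `R/diffexpr.R` — peptide filtering to moderated t
- `R/mitotest.R`, `R/celltype.R`, `R/coexpr.R` — set-level analyses
- `R/morphometry.R` — EM shape metrics and nested inference
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/synaptomito-methods.Rmd` — models, assumptions, design notes
- `inst/extdata/mito_categories_synthetic.gmt` — synthetic functional
  category fixture in GMT format
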