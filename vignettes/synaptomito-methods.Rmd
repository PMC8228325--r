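---
title: "Models and methods behind synaptomito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptomito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptomito)
```

This vignette explains the statistical models the package implements, the
assumptions behind each, the parameters a user may want to change, and
the design decisions taken where the methodology left genuine choices.
Nothing here states an empirical result beyond what the test suite and
`scripts/acceptance.R` compute themselves.

## The scientific setting

Synaptosomes — biochemically isolated nerve terminals — carry the
synaptic proteome together with synaptic mitochondria. Comparing
synaptosome preparations between genotypes (e.g. a receptor knockout) or
treatments (e.g. acute pharmacological inhibition of mGluR5) by
label-free DIA/SWATH mass spectrometry yields a peptide-level table:
intensity and identification confidence (Q-value) per peptide per run.
In parallel, electron microscopy provides per-synapse measurements of
mitochondrial profiles (area, perimeter, distance to the synaptic
contact), nested within animals. The package implements the full desk
analysis for both arms, plus the annotation-level and cell-type-level
analyses that connect them.

## Peptide filtering and protein quantification

A peptide-sample measurement "passes" when its Q-value is at or below
`q_max` (default $10^{-3}$). A group *qualifies* for a peptide when at
least `group size − allowed_outliers_per_group` of its samples pass
(default: all but one); the peptide is retained when at least
$\lceil G/2 \rceil$ of the $G$ groups qualify. With two groups this means
one qualifying group suffices — intentionally, so that a protein
confidently measured in only one condition (a knocked-out gene product,
say) is not discarded. Proteins then need at least `min_peptides = 2`
surviving peptides.

Protein abundance is $\log_2$ of the summed raw peptide intensities
(`rollup_proteins`; the mean-of-logs alternative is exposed as an
option). Summing weights peptides by intensity, which makes the roll-up
robust to weak peptides but means replicate CVs at the protein level sit
*below* the per-peptide CV whenever several peptides contribute
comparably — a point the quantify tests check against a closed-form
single-peptide bound rather than against a fixed percentage.

Normalization is fast cyclic loess (10 iterations, span 0.7, degree 1),
delegated to the standard limma implementation behind the package's own
interface: per iteration and sample, the log-ratio against the mean
profile (M) is smoothed against average abundance (A) and subtracted.
Constant offsets and smooth monotone intensity-dependent biases are
removed; rank structure within a sample is essentially preserved and the
grand mean is stable to well under 0.01 log2.

## Moderated t-statistics

The empirical-Bayes machinery is implemented from first principles (the
limma implementation appears only as an independent oracle in the test
suite). The model: per-protein residual variances $s_g^2$ on $d_g$
degrees of freedom are draws from a scaled inverse-$\chi^2$ prior with
parameters $(d_0, s_0^2)$. On the log scale,
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ has mean $\log s_0^2 +
\psi(d_0/2) - \log(d_0/2)$ and variance $\psi'(d_g/2) + \psi'(d_0/2)$,
so the method of moments solves

$$\psi'(d_0/2) = \operatorname{var}(e_g) - \overline{\psi'(d_g/2)}$$

by Newton inversion of the trigamma function (`trigamma_inverse`). When
the empirical spread of log-variances does not exceed what sampling
explains, $d_0 = \infty$ and every protein receives the common variance
$s_0^2 = \exp(\bar e)$. The posterior variance is the df-weighted blend
$s^2_{post} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$; the moderated t has
$d_0 + d_g$ degrees of freedom. Two limits anchor the implementation:
$d_0 = 0$ reproduces the ordinary pooled t exactly, and $d_0 = \infty$
ranks proteins purely by fold-change (equal group sizes).

Regulation is called at unadjusted $p < 0.01$, with no multiple-testing
correction — a deliberate choice to pass a richer protein list to the
set-level analyses, which aggregate over annotations instead of
interpreting single proteins. Proteins with measurements in only one
group are flagged (`absent_in`) and given a fold-change against the
global minimum observed abundance; this detection-floor convention is
explicit because no principled variance exists for such proteins, and
they carry no t-statistic.

Acquisition-block labels are carried through the design table but not
fitted as covariates; the contrast is a plain two-group comparison, and
block-aware fitting is left to the user via the exported group-summary
interface.

## The randomized-selection distribution test

To ask whether mitochondrial proteins *as a class* respond differently
from the rest of the quantified proteome, the fold-change distribution of
the annotated set is compared with randomized protein selections: 100
random sets of the same size, drawn without replacement from the
*non-target* quantified proteins, pooled, and compared by two-sample
Kolmogorov–Smirnov D.

Two numerical choices matter and were measured, not assumed:

* **Drawing from the complement.** If random sets are drawn from all
  quantified proteins, the pool shares observations with the target and
  the KS p-value becomes markedly conservative (its null distribution is
  visibly non-uniform in simulation). Drawing from the complement makes
  target and pool disjoint random subsets of an exchangeable collection —
  the setting in which the two-sample KS test is calibrated.
* **Effective sample size.** The pooled 100 draws resample the same
  complement values, so they carry the information of *one*
  complement-sized sample. Feeding the pooled count (100 × set size) to
  the standard KS p-value overstates precision and is anti-conservative;
  the package computes the Kolmogorov tail at effective sizes
  (n_target, n_complement). Under null simulations this p-value is
  uniform.

The per-iteration D statistics are also returned so users can inspect the
randomization spread. A dip statistic for bimodality per se is not
included; the KS comparison answers "is the distribution different",
which is the question the randomization design poses, and the
per-category summaries (`category_summary`, with the conventional ±0.1
log2 guide lines) localize *where* the mass moved.

## Morphometry

The elongation index is $P^2/(4\pi A)$, the reciprocal of circularity:
exactly 1 for a circle, larger for elongated or convoluted profiles, and
bounded below by 1 through the isoperimetric inequality — which the code
enforces as a data-consistency check (violations indicate unit errors or
inconsistent tracing). Mitochondria farther than 500 nm from the active
zone / postsynaptic density are not counted as synaptic; their synapse
rows are kept so presence fractions stay correct.

Outlier removal follows the ROUT idea reduced to a location model, since
each response here is a univariate distribution: residuals from the
median, a robust scale from the 68.27th percentile of absolute residuals
with an $n/(n-1)$ small-sample correction (one fitted parameter),
per-point t-tail p-values, and step-down flagging from the largest
residual inward at FDR `q` (default 1%). The exact internals of the
proprietary original are not public; this reimplementation keeps its
calibration property (≤ a couple of false flags per hundred clean
normal observations) and its sensitivity to gross contamination, both of
which the tests verify. Outliers are assessed per genotype and response,
before the proximity filter — the fixed pipeline order is outlier
removal → proximity filter → shape metrics → nested inference.

Genotype inference respects the animal → measurement hierarchy with the
random-intercept model $y = \beta_0 + \beta_1\,\text{genotype} +
a_{animal} + \varepsilon$, fitted by REML via lme4. Multiple
mitochondrial profiles per synapse are treated as measurements nested in
animal (not synapse); synapse-level clustering is far weaker than
animal-level clustering in this design and the animal intercept is what
prevents pseudoreplication. Because REML itself provides no p-value, the
Wald t for $\beta_1$ is referred to a t distribution with conservative
between-animal degrees of freedom $n_{animals} - 2$ — the df a
per-animal-means analysis would have. A singular fit (between-animal
variance at zero) falls back to pooled OLS, flagged, with the same
animal-level df. Area and perimeter are right-skewed; `log_scale = TRUE`
analyzes log measurements, under which the generator's lognormal model is
exactly specified and effects read as log ratios. The fraction of
synapses containing a mitochondrion is compared by a Student t test on
per-animal fractions — the animal is the experimental unit.

## Cell-type enrichment and the co-expression screen

Specificity of gene $g$ for cell type $c$ is
$s_{g,c} = \mu_{g,c} / \sum_{c'} \mu_{g,c'}$ where $\mu$ is the mean
counts-per-million over the type's cells (CPM first, so sequencing depth
does not masquerade as specificity). Rows sum to one; genes never
expressed are excluded, as are user-listed uninformative cell types.
Enrichment of a target set compares its summed specificity per type
against `n_boot = 10000` random sets of the same size drawn from a
declared background (for mitochondrial questions: all quantified
mitochondrial proteins). Random sets are size-matched only — no
expression-level matching — following the standard expression-weighted
enrichment baseline. The bootstrap p-value carries a plus-one correction
so it is never exactly zero; 10,000 draws stabilize p to about $10^{-4}$.

The co-expression screen builds per-cell-type profiles as CPM →
$\log_{10}(x+1)$ → per-gene per-type mean over *nonzero* values → each
type column divided by its median. Two notes: the pseudo-count applies to
CPM (not raw counts), and "median normalization" is applied per cell
type. The latter choice is recorded for the sake of intermediate outputs
only — Spearman correlation downstream is invariant to any monotone
per-column scaling, so it cannot affect the screen. Genes undetected in a
type get a missing entry there (the nonzero-mean convention) and are
handled pairwise-complete with a minimum of three shared types. P-values
use the t approximation to the Spearman null; the genome-wide list is
BH-adjusted and called at FDR < 0.05, optionally partitioned into
mitochondrial vs non-mitochondrial genes.

## The synthetic-data generators

The generators exist so every stage can be tested against planted truth.

* `simulate_peptides` builds log2 peptide intensities as protein baseline
  (N(20, 1.5²)) + peptide offset (N(0,1)) + per-sample shift + planted
  group effect + optional intensity-dependent bias + residual noise, with
  independent Bernoulli Q-value pass/fail per measurement (the filter
  only sees pass/fail combinatorics, so the search-engine mechanism
  behind real Q-values is not modelled). Defaults mirror a 6 vs 6
  two-group synaptosome design with a +0.2 log2 effect available for the
  mitochondrial stratum. The bias is a scaled tanh of the protein's
  centred log-abundance applied to alternate samples within each group:
  group-balanced (so it cannot masquerade as an effect), and defined at
  the protein level because a peptide-level bias leaves a
  protein-specific residual after roll-up that no abundance-based smooth
  could remove — the planted artifact matches what normalization is
  designed to fix, which is what the normalization test needs to verify.
* `simulate_morphometry` plants genotype-by-compartment lognormal areas
  and truncated-normal elongation indices with per-animal random
  intercepts, six animals per genotype and ~35 scored synapses per animal
  (≈ 200 per genotype), mito presence probabilities of 0.36/0.42,
  distances uniform on 0–600 nm so the 500-nm rule bites, and perimeter
  derived as $P = \sqrt{4\pi A E}$ so the planted elongation is exactly
  recoverable.
* `simulate_sc_counts` draws negative-binomial counts with planted
  marker genes, a target gene with a strictly decreasing cell-type
  profile, and genes whose true profiles are strictly monotone transforms
  of the target's (powers for positive, reflected powers for negative) —
  giving rank correlation ±1 at the level of true means. Counts are
  negative-binomial rather than an empirical single-cell distribution;
  that is sufficient for the rank-based screen and proportion-based
  specificity the package computes, but it does not emulate dropout
  structure, doublets, or ambient contamination, so passing tests say
  nothing about those artifacts in real atlases.

What the generators deliberately do *not* model: real missingness
structure in DIA data (exposed only as the `q_fail_rate` Bernoulli knob),
spectra or retention-time structure, image segmentation error, and
batch/acquisition-order effects beyond a per-sample shift.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale: 400–2000 proteins,
200–500 simulation replicates for coverage/type-I checks, 10,000
bootstrap draws for enrichment, a 2000-gene × 800-cell single-cell
matrix for the screen — sizes at which every check completes in seconds
to about a minute while Monte-Carlo error stays well inside the asserted
margins. All generators and resampling procedures accept seeds and are
bit-reproducible; the pipeline derives per-stage seeds deterministically
from one master seed, and `run_pipeline` output is identical across
repeated runs with the same configuration.

## Known limitations

* The moderated-t module fits two-group contrasts only; multi-factor
  designs and covariate adjustment are out of scope.
* The ROUT-style procedure is a location-model reimplementation, not a
  re-derivation of the proprietary nonlinear-regression original.
* The mixed-model p-value convention (Wald t, animal-level df) is one of
  several defensible choices; with six animals per group it is
  conservative relative to Satterthwaite-type approximations.
* Annotations are supplied as GMT files; no live database retrieval is
  performed, and the shipped category file is a synthetic fixture for
  demonstration, not a curated resource.
* Over-representation uses hypergeometric + BH; it does not reproduce
  the multiple-testing machinery of any particular web service.
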