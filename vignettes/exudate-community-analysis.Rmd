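---
title: "Presence/absence community analysis of untargeted root-exudate metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence community analysis of untargeted root-exudate metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

`exumet` implements a community-style analysis of untargeted LC-MS feature
tables from multi-species root-exudate sampling. The guiding design is a
phytometer experiment: standardized individuals of ten common grassland
species (five forbs, five grasses, among them two congeneric *Galium*
species) planted into managed grassland plots across three regions, their
root exudates profiled by reversed-phase LC-MS in negative mode, together
with water controls, plant functional traits, local-neighborhood cover
records and per-plot land-use components. Sampling is unbalanced (plot
access and plant mortality), which matters for several statistics below.

All community statistics operate on a **presence/absence matrix**: the
scientific currency is the *number* of exuded compounds, not their
intensity. Aligned untargeted intensities are only semi-quantitative across
compounds, so binarization is a deliberate modelling decision, not a
simplification.

## Pipeline stages and the choices behind them

### Feature filtering

Two filters precede every statistic, in a fixed order:

1. **Blank filter.** A feature detected in at least `blank_fraction`
   (default 0.5) of the water-control samples is removed as a contaminant.
   The boundary is *inclusive*: with four blanks, two detections remove the
   feature. Blanks are pooled across regions by default; a stratified
   per-region mode exists (`by_region = TRUE`) but is not the default
   because contamination sources (solvents, tubing) are shared across a
   measurement campaign.
2. **Singleton filter.** Features occurring at most once across all
   *exudate* samples are removed; a single detection cannot support any
   community statement. Blanks are excluded from this count because they
   are a different sample population (configurable via `exudates_only`).

Presence means intensity **strictly** above `presence_threshold`
(default 0): aligned feature tables encode absence as exact zero. Each
filter appends a provenance record (parameters plus the removed feature
ids), so the final matrix documents its own history.

### Chemical richness

Per-sample richness is the binary row sum. Species differences are tested
with a one-way ANOVA on the *sample-level* richness values (a
summary-level mode aggregating to per-species-by-plot medians is available
through `richness_summary(response = "summary")` for designs with strong
pseudo-replication). Two degenerate limits have defined contracts: zero
between-group variance reports F = 0, p = 1; zero within-group variance
with distinct means reports F = Inf, p = 0.

The all-pairs post hoc uses the **Scheffé criterion**: pair (i, j) is
significant iff

$$|m_i - m_j| > \sqrt{(k-1)\,F_{\alpha;\,k-1,\,N-k}\;MSE\;(1/n_i + 1/n_j)},$$

which is valid for arbitrary contrasts and therefore never more liberal
than an unadjusted t-test. Letters come from the insert-and-absorb
compact-letter-display algorithm; groups are lettered in descending order
of their means so the display is deterministic. Two groups share a letter
exactly when their contrast is non-significant.

### Species specificity

For every compound and every focal species the screen asks whether the
compound is *more frequent* in the focal species than in the remaining
community. Conditional on the total occurrence count
$T = k_{focal} + k_{other}$, exchangeability across samples puts each
occurrence in the focal group with probability
$p_0 = n_{focal}/(n_{focal}+n_{other})$, and the reported p-value is the
exact upper binomial tail $P(X \ge k_{focal})$, $X \sim \mathrm{Bin}(T, p_0)$.
"Specific at confidence 0.95" means p < 0.05.

Two properties of this construction are worth stating plainly:

* It is **conservative** under the exchangeable null. The true conditional
  law of $k_{focal}$ given $T$ when occurrences are scattered over a finite
  sample set is hypergeometric, whose variance is smaller than the
  binomial's by the finite-population factor $(N-T)/(N-1)$. The realized
  per-test false-positive rate therefore sits below the nominal 0.05 —
  acceptable for a screen whose findings feed a downstream identification
  effort, where false positives are the expensive error.
* No multiple-testing correction is applied by default, mirroring the plain
  per-test criterion; `adjust = "BH"` switches the screen to
  Benjamini–Hochberg-adjusted p-values.

A feature qualifying for several species is attributed to the species with
the smallest p-value, ties broken by species label order, so per-species
counts are disjoint. Genus groups (the pooled congeners against the
remaining eight species) are screened identically. Shared-compound counts
consider only features occurring at least twice overall; a feature is
shared between growth forms when present in at least one sample of each.

### Ordination and clustering

The ordination stack is implemented in-package on top of dense linear
algebra, with `vegan` used as an independent cross-check in the test suite:

* **PCA** by SVD of the centered matrix; eigenvalue $s_i^2/(n-1)$, site
  scores $U\,\mathrm{diag}(s)$.
* **RDA** fits the centered response on the centered predictors with a
  pseudoinverse projection (SVD-based, rank revealed by pruning singular
  values below $10^{-9}$ of the predictor's largest) and decomposes the
  fitted matrix. Species enter as full one-hot indicators rather than
  treatment contrasts — the projection only depends on the column space,
  and one-hot coding avoids an arbitrary reference level. Axis
  proportions are relative to the total variance of centered Y, so the
  constrained proportion is the multivariate R².
* **Partial RDA** residualizes both Y and X on the conditioning matrix and
  reports the conditioned variance separately; conditioned + constrained +
  unconstrained variance equals the total by construction. Rank pruning of
  the residualized predictors is referenced against the *pre-residualization*
  predictor scale, so conditioning a matrix on itself cleanly yields a
  zero constrained fraction instead of numerical noise.
* **DCA** for the neighborhood community: correspondence analysis by SVD of
  the standardized residual matrix, with axes beyond the first detrended by
  segments (default 26): the axis-1 ordering is cut into equal-width
  segments and the row-weighted within-segment mean of the higher axis is
  subtracted. Axis 1 is the plain CA axis. Nonlinear rescaling is *not*
  implemented: the axes are used as numeric predictors downstream, where
  rescaling (which is poorly standardized across implementations) changes
  nothing structurally.
* **Hierarchical clustering** with Euclidean distance — on a binary matrix
  the square root of the Hamming distance — and complete linkage, the
  documented defaults of the classical distance/clustering routines.
  The agglomeration is in-package (vectorized O(n³)); merge heights are
  non-decreasing under complete linkage, and the dendrogram object is
  `hclust`-compatible, so `cutree`, `cophenetic` and Newick export via
  `ape` all apply.

### Trait–exudate correlation (Procrustes)

Both matrices are first ordinated by PCA; the **symmetric Procrustes**
analysis centers both score configurations, scales each to unit sum of
squares, and finds the rotation minimizing the residual sum of squares
$m^2$; the correlation is $\sqrt{1-m^2}$. The number of retained PCA axes
is configurable (`procrustes_axes`); the default uses every axis with a
nonzero eigenvalue, which is the most conservative choice in the sense
that it discards nothing. The permutation test (`protest`) shuffles the
rows of the second configuration and uses the add-one convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1+B)$, which makes the
Monte-Carlo test exactly valid at every B. The default B = 999 gives a
minimum attainable p of 0.001.

### Variance partitioning

Explained variance over 1–4 predictor sets (e.g. Species, Plot, Traits,
LNH) uses the **Ezekiel-adjusted R²**,

$$R^2_{adj} = 1 - (1-R^2)\frac{n-1}{n-p-1},$$

with p the rank of the centered predictor matrix. Every non-empty union of
sets is fitted, and unique/shared fractions follow by solving the
inclusion–exclusion system; fractions plus the residual sum to one
*exactly*. Adjusted fractions can be **negative** under unbalanced designs
and correlated predictor sets — these are conventionally read as zero.
`partition_layout3()` arranges a three-set partition into the conventional
eight-column report row (three unique, three pairwise-shared, triple,
residual). Plot is encoded as plot-identity indicators (not environmental
covariates): it is meant to absorb everything locational.

### Land-use intensity

Per plot and year, $LUI = F_i/F_r + M_i/M_r + G_i/G_r$ — fertilization
(kg N ha⁻¹ yr⁻¹), mowing frequency (yr⁻¹) and grazing intensity, each
standardized by its mean over the plot-years *within the site (region)* —
then averaged over the covered years (default 2006–2014 in the generator).
A plot sitting at the regional reference in all three components scores
exactly 3. Zero reference means are an error, not a silent NaN.

### MS/MS compound classes

Spectra are reduced to fragments with intensity strictly above 1000,
normalized to the base peak, and fragments with normalized intensity
strictly above 0.1 are eligible for fragment-rule matching; all surviving
fragments contribute neutral losses (precursor − fragment, positives
only). Rules match within ±0.005 Da by default (Q-ToF-scale accuracy,
configurable per rule). The shipped rule table is a compact,
chemistry-derived stand-in — sugar losses (hexose 162.0528, deoxyhexose,
pentose, glucuronyl) marking glycosylation, SO₃ (79.9568) and HPO₃
(79.9663) marking sulfation and phosphorylation (distinguishable at the
default tolerance: they differ by 0.0095 Da), malonyl/water/CO₂ losses,
and hydroxycinnamic-acid and flavonoid fragment ions — with every target
mass computed from monoisotopic atomic masses at build time. Users with a
curated in-house table load it as a TSV with the same columns. Labels
aggregate per spectrum (modifiers such as glycosylated/sulfated/
phosphorylated co-occur freely with class labels); a spectrum matching
nothing is counted `unclassified`.

## The synthetic study generator

Every input the pipeline consumes can be generated with planted ground
truth, so the full stack is testable without any instrument data.

* **Design**: 10 species in two growth forms, 46 plots in three regions,
  per-species sample counts 38/41/37/39/28/40/40/48/37/41 (total 389),
  12 water controls. The imbalance is part of the study conditions: it is
  what produces negative adjusted-R² fractions downstream.
* **Occupancy model**: presence is Bernoulli per sample with a logistic
  link, $\mathrm{logit}(p) = \mathrm{logit}(occ) + \delta_{plot}$, with
  per-plot shifts $\delta \sim N(0, 0.5)$. Feature classes: shared
  (occupancy drawn from 0.30–0.90), species-specific (occupancy 0.8 in the
  focal species, 0.02 elsewhere; 534 planted across forbs, 91 across
  grasses), genus-specific (150 for the congener pair), blank contaminants
  (present in ≥ half the blanks by construction, occupancy 0.9 with
  top-up, plus 0.25 in exudates) and singletons (exactly one occurrence).
  The defaults plant 270 shared features.
* **Intensities** are log-normal given presence. The analysis binarizes,
  so only positivity matters; no attempt is made to model
  intensity–occupancy coupling.
* **Traits** decompose as species mean + plot shift + Gaussian noise; the
  species effect size controls the recoverable trait–exudate Procrustes
  correlation.
* **Neighborhood covers** are plot-structured (sparse plot composition ×
  log-normal sample scatter), so DCA axes cluster by plot.
* **Spectra** are built from the rule table itself: each planted label
  contributes its diagnostic fragment or neutral loss; noise peaks
  straddle the absolute intensity gate.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about instrument data: retention-time/mass structure,
adducts and isotopologues, intensity-dependent detection, correlated
co-occurrence among real compounds of one biosynthetic pathway, missing
trait measurements, or spatial autocorrelation beyond the plot level.
Recovery rates on synthetic data are upper bounds, not forecasts.

## Numerical conventions

* Singular values below $10^{-9}$ of the leading one are treated as zero
  (rank pruning in PCA/RDA).
* Degenerate ANOVA limits: F = 0/p = 1 and F = Inf/p = 0 as above; with
  zero MSE the Scheffé rule degenerates to "different means are
  significant".
* Specificity ties are broken by species label order; letter columns are
  ordered by the highest-ranked (largest-mean) member before lettering.
* Permutation p-values always use the add-one convention; every stochastic
  step requires a seed, and generator functions restore the caller's RNG
  state.
* Fractions in variance partitioning are solved from the full
  inclusion–exclusion linear system rather than hand-written formulas, so
  the sum-to-one identity holds to solver precision (~1e-14).

## Problem sizes in the shipped validation

The test suite validates against independent oracles at deliberately small
sizes (explicit hat-matrix RDA on 15×8 problems; O(n³) clustering on 10
samples; direct pmf summation up to T = 50) and runs Monte-Carlo
calibrations at moderate ones (10,000-feature null screens, 1000-replicate
ANOVA calibration, 200-replicate protest uniformity at n = 50, B = 199).
The end-to-end reproducibility check runs the full 389-sample study twice
and compares every output byte for byte. These sizes were chosen to make
each statistical assertion sharp (3 SE bands) while keeping the whole
suite comfortably interactive.

## Known limitations

* The specificity null is a modelling choice (conditional binomial);
  alternative nulls (hypergeometric, occupancy-model-based) would be less
  conservative. The screen's counts depend on it.
* DCA omits nonlinear rescaling; axis scores are suitable as predictors,
  but segment counts other than the default are the user's responsibility
  when comparing to other software.
* The Procrustes analysis inherits whatever the PCA retains; with
  presence/absence data the leading axes can be dominated by richness
  differences.
* The shipped MS/MS rule table is a minimal stand-in; serious class
  annotation requires a curated fragment/loss database.
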