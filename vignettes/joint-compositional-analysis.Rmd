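---
title: "Joint compositional analysis of paired microbiome and metabolome cohorts"
author: "crossOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint compositional analysis of paired microbiome and metabolome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossOmics)
```

## The analysis problem

Designed animal cohorts that pair 16S amplicon sequencing with untargeted
LC-MS/MS metabolomics — for example, mice on a high-fat high-cholesterol
(HFHC) diet with or without intermittent hypoxia/hypercapnia (IHC), sampled
repeatedly over ten weeks — pose three linked statistical problems:

1. **Compositionality.** Sequencing counts and peak areas carry no absolute
   scale; only within-sample ratios are interpretable.
2. **Sparsity.** Amplicon tables are mostly zeros, and a zero is censoring
   (not detected at this depth), not a measured absence.
3. **Pairing.** The scientific question is usually not "which taxa change"
   or "which metabolites change" in isolation, but which microbial and
   chemical changes move *together* across the same samples.

crossOmics implements one coherent path through these problems: the robust
centered log-ratio (rclr) transformation, low-rank matrix completion of
the transformed tables, a joint factorization across omics tables with
shared sample scores, cross-omic feature correlations from the fitted
model, log-ratio biomarkers, and the supporting group statistics
(PERMANOVA, pairwise Mann-Whitney, PLS-DA with VIP selection, and
linear mixed-effects trends). A synthetic paired-cohort generator with
planted ground truth makes every stage testable without any external data.

## The rclr transformation and why zeros stay missing

For sample $i$ with positive entries $x_{ij} > 0$,

$$\mathrm{rclr}(x)_{ij} = \ln x_{ij} - \frac{1}{|O_i|}\sum_{k \in O_i} \ln x_{ik},$$

where $O_i$ is the set of features observed (positive) in sample $i$.
Zeros are marked unobserved and excluded from the geometric mean. Two
properties matter:

* **Scale invariance.** Multiplying a sample's row by any constant leaves
  its rclr values unchanged (exactly, to machine precision), so sequencing
  effort and injection amount cancel.
* **No imputation.** Pseudocounts distort low-abundance ratios; the rclr
  defers the handling of missingness to the low-rank completion step. A
  pseudocount flag exists for sensitivity analyses only and is off by
  default.

Every sample must retain at least one positive entry; an all-zero sample is
a hard error naming the sample.

## Low-rank completion of the observed entries

`optspaceComplete()` fits $X \approx U S V^{\top}$ using only observed
entries, in the OptSpace style:

1. **Spectral initialization.** Unobserved entries are set to 0, the matrix
   is rescaled by the inverse observed fraction, and the top-$r$ SVD gives
   the starting $U$; $V$ starts from the projection of the data onto $U$.
   Degree trimming of over-dense rows/columns is implemented behind a flag
   and off by default — at the scale of a designed cohort (hundreds of
   samples) observation counts are homogeneous enough that trimming is a
   no-op.
2. **Gradient descent with retraction.** $U$ and the per-table $V$ take
   gradient steps and are re-orthonormalized by QR. A backtracking line
   search halves the step (up to 20 times) until the loss decreases, so the
   observed-entry objective is monotone non-increasing by construction; the
   test suite asserts this with $10^{-10}$ slack. Backtracking trials are
   evaluated with the current core $S$; the accepted step then re-solves
   $S$ exactly by least squares, which can only lower the loss further, so
   monotonicity survives the shortcut.
3. **Core re-solution and rotation consistency.** Given orthonormal $U,V$,
   the $r \times r$ core that minimizes the observed squared error is a
   linear least-squares problem, solved in closed form when the table is
   fully observed ($S = U^{\top} X V$) and via the normal equations on the
   observed entries otherwise. After each accepted step, the SVD of the
   concatenated core rows re-expresses $U$ and the shared singular values
   without changing the fit.

Convergence is declared when the relative loss change falls below `tol`
(default $10^{-6}$) or when no decreasing step exists. On a fully observed
matrix the procedure reproduces the rank-$r$ truncated SVD's fit error to
$10^{-6}$ relative — the oracle check in the test suite. Sign
indeterminacy is resolved by making the largest-magnitude entry of each
column of $U$ positive, so results are deterministic and row-permutation
equivariant.

Defaults: rank 3, 200 iterations, tolerance $10^{-6}$. Rank 3 suits
ordination (two to three displayed axes); it is a default, not an estimate
of any dataset's true rank.

## RPCA ordination and joint factorization

`rpca()` is completion applied to the rclr matrix: sample scores are
$U S$, sample distances are Euclidean distances between score rows (an
Aitchison-type distance — per-sample count scaling does not move any
sample), and feature loadings serve as differential ranks.

`jointFactorize()` extends this to $M$ tables over the same samples with a
*shared* $U$ and per-table $V_m, S_m$, minimizing

$$L = \sum_m w_m \cdot \frac{1}{|\Omega_m|} \sum_{(i,j) \in \Omega_m}
      \left(X_m - U S_m V_m^{\top}\right)_{ij}^2,$$

with equal weights by default (a weight vector is exposed). The shared
basis and shared singular values are recomputed from the concatenated
cores at every iteration, keeping the rotation consistent across tables.
With a single table the procedure reduces exactly to `rpca()` (same code
path), which the tests verify via Procrustes alignment.

### Cross-validation of the reconstruction

Samples are assigned at random to training (80%) and test (20%) sets;
five seeded splits are run by default and reported per split.
Minimization uses training samples only. Each test sample is then
projected into the trained space by least-squares regression of its
observed rclr entries onto $V_m S_m^{\top}$ — with one refinement: the
projection is fit on a random half of the sample's observed entries and
the reconstruction error is computed on the *other* half. Without this
entry-level holdout the projection fits $r$ free parameters per sample on
the very entries being scored, and the reported test error decreases
mechanically with rank; with it, the test error is minimized at (or next
to) the true rank on synthetic paired data, which is the behaviour a
model-selection diagnostic must have.

### Cross-omic correlations and the rank of the integration stage

`crossCorrelations()` computes Pearson (optionally Spearman) correlations
between the reconstructed feature profiles $U S_m V_m^{\top}$ of two
tables. Features with zero loading reconstruct as constants and are
assigned correlation 0.

The integration stage defaults to rank 5 rather than the ordination
default of 3. The reason is geometric: feature profiles live in the
$r$-dimensional span of the fitted axes, and when $r$ barely exceeds the
dominant structure of the data almost any two features are near-collinear,
making extreme correlations uninformative. A modest surplus of axes lets
genuinely coupled feature pairs stand out from generically correlated
ones. One irreducible caveat is documented here because it bounds what
correlation magnitudes can mean: the rclr is defined only up to the
per-sample centering constant, and each table's centering injects a small
table-specific offset (on the order of the mean loading, about 0.1–0.2
natural-log units in the bundled generator) into every feature's factor
representation. Correlations between features of *different* tables
therefore saturate slightly below 1 even for noiseless planted
relationships.

### Feature filtering before integration

`selectFeaturesByLoading()` keeps the top and bottom fraction (default
10% per tail) of features ranked by an ordination loading, mirroring the
practice of integrating only differentially abundant features;
user-supplied id lists are equally accepted by subsetting the tables.

## Log-ratio biomarkers

`featureSetLogRatio()` computes, per sample, the natural log of the summed
abundance of one feature set over another — for microbes, typically all
ASVs of the Muribaculaceae family over all ASVs of the Akkermansiaceae
family. The statistic depends only on within-sample proportions. Samples
where either sum is zero have no defined ratio; they are excluded and
listed in a dropped-sample ledger that accompanies every output (the
drop-and-report rule, rather than any zero replacement).
`loadingRankLogRatio()` builds the sets from the top-$k$ and bottom-$k$
features of a loading vector; ties at the cut are an error unless
deterministic tie-breaking by feature id is requested.

## Group statistics

**PERMANOVA.** The pseudo-F statistic is computed from squared distances,

$$F = \frac{(SS_T - SS_W)/(k-1)}{SS_W/(n-k)}, \qquad
SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2,$$

and its significance by label permutation with
$p = (\#\{F_{\pi} \ge F\} + 1)/(B + 1)$. A complete-enumeration flag
evaluates every distinct label arrangement for small $n$; the tests verify
exact agreement with an independent brute-force enumeration for all
two-group splits of $n \le 8$, equality of the statistic with
`vegan::adonis2`, and nominal type-I error over 1000 null simulations. The
calibration simulations use 199 permutations per dataset: $200 \times
0.05$ is an integer, so rejecting at $p \le 0.05$ is an exact-level test,
and the simulation stays fast.

**Pairwise Mann-Whitney.** Exact two-sided p-values when both groups have
at most 8 observations and there are no ties (verified against brute-force
enumeration); the normal approximation with tie and continuity correction
otherwise. Bonferroni correction multiplies by the number of pairs and
caps at 1. Estimation is delegated to `stats::wilcox.test`; the package
contributes the pairing, the exact/approximate switching rule and the
adjusted table.

**Log-ratio regression.** Pearson r, two-sided p, and the least-squares
line between two log-ratio series on the samples retained in both —
the scatter that relates a microbial family ratio to a metabolite-set
ratio sample by sample.

**Mixed-effects trend.** `lmeTrend()` fits
`log_ratio ~ host_age * group + (1 | host_subject_id)` by delegation to
`lmerTest::lmer`. This is deliberately a thin wrapper — random-intercept
estimation is a solved problem — and a singular fit is reported as a flag,
not an error.

## PLS-DA with VIP selection

`fitPlsda()` implements NIPALS PLS1 against a centered $\pm 1$ class code
on the rclr matrix with unobserved entries set to 0 — the row-centered
neutral value. This 0-fill is a documented divergence from the
completion-based unsupervised path: a supervised discriminant model needs
a complete design matrix, and filling with the neutral value biases the
model towards *not* using censored entries. Columns are centered and (by
default) unit-variance scaled.

Variable importance in projection for feature $j$ over $A$ components:

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_{a=1}^{A} SSY_a\, w_{aj}^2}
                                    {\sum_{a=1}^{A} SSY_a}},$$

with $SSY_a = c_a^2 \, t_a^{\top} t_a$ and unit-norm weight vectors, so
$\mathrm{mean}(\mathrm{VIP}^2) = 1$ identically — asserted on every fit in
the tests. Features with VIP above 1 (configurable) are selected, and
`significantFeatureLogRatio()` assigns each selected feature to the class
with the higher mean rclr value to form a two-set log ratio.

The classification error rate (CER) pools held-out predictions over a
stratified k-fold cross-validation (default 5 folds, seeded), predicting
by nearest class centroid in score space — chosen because CER needs *a*
prediction rule and this is the simplest one expressible in the fitted
scores. Its known weakness is also worth stating: later
components are not scaled by their relevance to the class code, so a
high-variance irrelevant component can dominate the Euclidean distance
when the class signal is weak. The separable fixtures in the test suite
have dominant class signal, where the rule is exact. Fold assignment is
the only seed-dependent part; the full-data fit is deterministic given the
data. With `autoNcomp = TRUE` the component count is chosen from {1, 2, 3}
by smallest CV CER; CER aggregation is pooled (not averaged per fold),
so every held-out sample contributes equally.

## The synthetic paired cohort

`simulateCohort()` generates the study conditions every test runs under:
three arms (RC-Air, HFHC-Air, HFHC-IHC) of 8 mice sampled at 20 timepoints
from host age 10 to 19.5 weeks; 150 microbial features and 250
metabolites; expected library size 12,000 with lognormal spread
(`sdlog = 0.3`), so rarefaction at the conventional 10,200 reads drops a
visible fraction of samples and exercises the drop-and-log path; 30%
zero-inflation; 2 shared latent factors.

Counts are multinomial with log-linear (softmax) composition:

$$\eta_{if} = a_f + u_i^{\top} w_f + e_i \, d_f + b_{s(i)f},$$

where $u_i$ are the sample's latent scores (sd 1), $w_f$ the feature
loadings, $e_i$ the group effect ramp, $d_f \in \{-1, 0, +1\}$ the planted
direction, and $b$ per-subject intercepts (sd 0.3, the overdispersion
mechanism). The effect ramps linearly from 0 at baseline to `effectSize`
(default 2 natural-log units) at the final timepoint, with multiplier 0
for RC-Air, 0.6 for HFHC-Air (diet only) and 1 for HFHC-IHC (diet plus
exposure) — an order-of-magnitude family shift by study end, the size of
swing reported for Muribaculaceae/Akkermansiaceae in this model system.
Metabolite log-intensities use the *same* latent scores with their own
loadings, effects and Gaussian noise (sd 0.5). A multinomial with
subject-level random intercepts was preferred over a Dirichlet-multinomial
as the simplest structure that produces sparsity, compositionality and
repeated-measures dependence at once.

Three structures are planted and recorded in the returned truth object:

* **Opposing families.** A sixth of the microbes are Muribaculaceae-like
  (effect direction $-1$), a sixth Akkermansiaceae-like ($+1$); matching
  RC- and HFHC-IHC-associated metabolite classes get the same treatment.
* **A shared community-state factor.** The families and metabolite classes
  load on latent axis 1 with opposite signs (magnitude 0.5), so the
  cross-omic family/class log-ratio correlation is carried by the shared
  factors as well as by the effect ramp. This value balances two
  documented contracts: it is large enough that strengthening the latent
  factors measurably strengthens the cross-omic ratio correlation, and
  small enough that the family ratio still separates the exposure groups
  cleanly at study end.
* **Noiseless microbe-metabolite pairs.** Five metabolites are exact
  affine functions of the full log abundance of five designated microbes —
  the statistical signature of a metabolite produced by a single taxon.
  The pair microbes are abundant (+2 intercept), consistently detected (no
  zero-inflation) and strongly loaded (latent loading norm 3): given the
  centering offset discussed above, a rare or weakly loaded pair member
  would be unidentifiable in principle, and the planted pairs exist
  precisely to be identifiable.

What the generator does **not** emulate: phylogenetic structure and
taxonomy, temporal autocorrelation of the latent scores beyond the
subject intercept, chemical relationships between metabolites (adducts,
in-source fragments), batch and injection-order effects, and
depth-dependent taxon detection beyond uniform zero-inflation. Passing
tests therefore demonstrate correctness of the algorithms under a
compositional, sparse, low-rank, repeated-measures model — not
performance on any particular real dataset.

Reproducibility: all randomness flows from one master seed split into
named streams (latent scores, loadings, intercepts, subject effects,
dropout, depths, counts, noise), so one seed reproduces the tables byte
for byte and changing, say, the depth regime leaves the latent structure
untouched (the paired-seed compositionality test relies on this).

## The pipeline

`runPipeline()` chains the stages into the full workflow: rarefaction
(default depth 10,200) → rclr → RPCA ordination and distances → PERMANOVA
on group labels → family log ratio with pairwise Mann-Whitney at the last
two timepoints and the mixed-effects age trend → PLS-DA on the rclr
metabolome (first timepoint excluded, since all animals share the baseline
diet there) with the VIP-based metabolite log ratio → loading-based
feature filtering → joint factorization with CV → cross-omic correlations
→ the microbiome-versus-metabolome log-ratio regression. The default
PLS-DA comparison is RC-Air versus HFHC-IHC, the stratified contrast
whose significant-feature ratio feeds the final regression.

Two structural choices deserve a note. First, the metabolome analyses run
on all metabolome samples: rarefaction failures remove samples from the
*sequencing* analyses only, and the two tables are aligned on shared
samples just before the joint factorization (the log-ratio regression
intersects its two series by construction). Second, every output is
written with deterministic formatting and the provenance JSON contains
versions, parameters, derived stage seeds and all dropped-sample ledgers
— rerunning an identical configuration reproduces every artifact bit for
bit, which the tests check by hashing.

The package is a library: the exported functions and `runPipeline()` with
a YAML configuration are the interfaces, and each pipeline stage is
available as its own documented function.

## Problem sizes and runtime choices in the test suite

The test suite runs the full default cohort (480 samples) where a claim
is about the default conditions — subspace recovery, planted-pair
detection, the family-ratio AUROC — and scaled-down cohorts (3 × 4 mice,
6–7 timepoints, 60–80 features) for calibration loops that repeat the
whole analysis dozens of times (type-I error of the generator, power of
the pairwise tests, latent-strength monotonicity). Rank sweeps use 60
samples and 40–50 features per table. PERMANOVA calibration uses 199
permutations (exact level at $\alpha = 0.05$, as above) over 1000 null
datasets in the acceptance suite and 400 in the unit suite. These sizes
are the package's own choices for a fast, convincing default run; all of
them scale up by changing the corresponding arguments.

## Known limitations

* The completion objective is non-convex; the spectral initialization is
  standard and works well at these scales, but pathological masks (nearly
  empty rows/columns) are rejected rather than handled.
* Cross-omic correlations inherit the rclr centering ambiguity discussed
  above; their magnitudes near 1 should be read comparatively (which pairs
  are most coupled), not absolutely.
* PLS-DA is two-class by design, matching the pairwise comparisons it
  implements; no multiclass, orthogonal or sparse variants.
* `lmeTrend()` inherits all estimation caveats of random-intercept models
  on short series; singular fits are flagged, not resolved.
* The PERMANOVA is the one-way design on a single grouping factor; no
  strata, covariates, or dispersion diagnostics (PERMDISP) are provided.
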