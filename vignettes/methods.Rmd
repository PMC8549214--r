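---
title: "Methods: integrated multi-omics and network pharmacology for syndrome differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated multi-omics and network pharmacology for syndrome differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the synthetic-data design
and the numerical choices behind `syndromics`. The package addresses a
recurring design in integrative TCM research: a cohort of patients with one
disease but two clinically distinguished syndromes (here labelled CCQS and
QSBS) plus healthy controls (HC), profiled by serum proteomics and by
untargeted and targeted metabolomics, and analyzed alongside a
network-pharmacology characterization of the formulae prescribed for each
syndrome. The scientific question is whether syndrome-specific molecular
alterations coincide with the targets of syndrome-specific formulae.

## Differential proteins

Intensities are modelled on the log2 scale. For each protein, the case
group (a syndrome) is compared with HC by a two-sample Student *t*-test
with pooled variance — the equal-variance form is the default because it is
the standard reading of "Student's t-test"; Welch is available via
`var_equal = FALSE`. The fold change is computed on raw-scale group means
and folded to be at least 1, with direction recorded relative to the case
group. A protein is differential when **FC > 1.1 and p < 0.05**, both
strict. No multiplicity correction enters the call (BH q-values are
reported informatively): at a few hundred features with raw p < 0.05 the
uncorrected convention is what the fold-change filter is there to
discipline, and the empirical-FDR checks below quantify exactly what that
combination buys.

Two conventions were genuinely open and are therefore configurable:

* **Fold-change scale.** Raw-scale means (default) versus geometric
  (log-scale) means, `fc_scale = "raw"/"log"`. Raw means are the common
  volcano-plot convention for intensity data.
* **Imputation.** The dropout-filling method is rarely reported in
  practice; the default is feature-wise half-minimum, a conservative choice
  consistent with intensity-dependent dropout. `policy = "min"` is also
  provided. Imputed values never exceed the observed feature minimum.

Cohort baseline statistics follow the clinical-table convention: one-way
ANOVA for continuous variables — computed from (n, mean, sd) triples via
the between/within sum-of-squares decomposition, which is exactly
equivalent to `aov()` on raw data — and Pearson χ² homogeneity tests
without continuity correction for categorical variables. The package ships
a reference baseline table (`load_cohort_reference()`) with three groups of
30/44/37 participants; at these counts the uncorrected χ² is the
appropriate generic test for 3×2 tables.

## OPLS-DA, VIP and Q²

The metabolomics track uses projections to latent structures. Features are
centered and unit-variance scaled by default (`scale = "uv"`); UV scaling
is the metabolomics default because it makes VIP comparable across features
of very different intensity; Pareto scaling is available behind a flag.

`fit_plsda()` implements NIPALS PLS1 on the centered 0/1 class vector.
`fit_oplsda()` implements the Trygg–Wold orthogonal correction: per
orthogonal round, with `w ∝ X'y` normalized, `t = Xw`, `p = X't/(t't)`,
the class-orthogonal loading direction is `w_o = p − (w'p)w` (normalized),
its score `t_o = Xw_o`, and `X` is deflated by `t_o p_o'`. The predictive
component is then extracted from the deflated matrix. With `n_ortho = 0`
the procedure reduces exactly to one-component PLS-DA — a reduction the
test suite asserts. One orthogonal component is the default since the
component count is rarely reported and one is the usual choice for
two-class serum data. Orthogonal scores are uncorrelated with the centered
class vector by construction (checked to 1e-8).

**VIP** is computed over the predictive component(s) only — the O-PLS
convention — giving `mean(VIP²) = 1` exactly; the threshold VIP > 1 is
strict. **Q²** comes from stratified ten-fold cross-validation with the
entire fitting pipeline (centering, scaling, orthogonal deflation) refit
inside each training fold; `Q² = 1 − PRESS/SS` with SS the total sum of
squares of the centered class vector. Fold assignment is seeded, and folds
are reduced with a warning when a class has fewer members than folds.

The univariate track is the two-sided Mann–Whitney U test (exact for small
tie-free groups, normal approximation with tie and continuity correction
otherwise) with BH correction across features. Differential-metabolite
calls combine the two tracks: VIP > 1 **and** q < 0.05 for untargeted
data, VIP > 1 **and** raw p < 0.05 for targeted data — the targeted panel
is two orders of magnitude smaller, which is why FDR control moves from
the q-value to the raw p-value there.

## Network pharmacology

Compound activity is source-specific: TCMSP-style records pass with oral
bioavailability **OB ≥ 30 %** and drug-likeness **DL ≥ 0.18** (inclusive,
mirroring the "≥" convention), ETCM-style records with druglikeness
grading good or moderate, and pharmacopeia quality markers (Q-markers)
unconditionally. A compound duplicated across sources is active if any
source rule admits it.

A syndrome's **signature targets** are the triple intersection of its three
formulae's putative target sets; the two syndromes' signatures are then
partitioned into common and syndrome-specific parts. Disease similarity is
Jaccard on gene sets (JIg) and variant sets (JIv) with strict thresholds
JIg > 0.2 and JIv > 0.05 combined **conjunctively** — the stricter reading
when two thresholds are listed without a connective; `combine = "or"` is
available. ATC drug categories are assigned by case-insensitive
longest-prefix match over the configured prefixes (C, A10, A08, B01 by
default); drugs matching no prefix are excluded from the overlap analysis.

## Graph analytics

Gene prioritization uses Zhou-style label propagation with the
symmetrically normalized adjacency `S = D^(−1/2) W D^(−1/2)` and restart
parameter α = 0.5: iterate `F ← αSF + (1−α)Y` to a sup-norm tolerance of
1e-9 (cap 1000 iterations). This emulates the ranking behaviour of
functional-association platforms that score all genes around an input
list. The fixed point equals the closed form `(1−α)(I−αS)⁻¹Y`; the test
suite checks iterative/direct agreement to 1e-6 on random graphs up to 50
nodes. Because the operator is symmetric with spectral radius ≤ 1, scores
are non-negative, every seed retains at least its restart mass `(1−α)`,
and `‖F‖₂ ≤ ‖Y‖₂`; note that the *L1* mass is not conserved under this
normalization (only the random-walk variant conserves it), which is why
the invariants are stated in these terms. Top-k expansion (k = 10 by
default) breaks ties by score descending then node id ascending, so
results are reproducible.

Integrated metabolite–gene subnetworks are induced on matched seed
molecules plus **bridge** nodes adjacent to at least two matched seeds;
isolated matched seeds are dropped and each node is annotated with its
origin (DM, DP, signature target, bridge). The ≥2-seed bridge rule is an
explicit surrogate for first-order network construction in metabolomics
platforms: it keeps connecting molecules while preventing degree-1
hairballs; `min_seed_neighbors = 1` restores plain first-order
neighborhoods.

## Enrichment and annotation clustering

Over-representation uses the hypergeometric upper tail
`P(X ≥ k)` for an overlap of `k` between a query of `n` universe items and
a term of `K` members in a universe of `N` — identical to the one-sided
Fisher exact test, which the suite verifies over random configurations.
The default universe is every identifier annotated to at least one loaded
set: the platforms' proprietary backgrounds cannot be reproduced, so the
background is explicit and overridable. Joint gene+metabolite queries are
pooled into a single combined-query test over the combined universe
(namespaces must be disjoint); Fisher-style merging of per-kind tests was
considered and rejected as harder to test for no added value at this
scale. Report percentages are `100·k/n` rounded to two decimals, with `n`
the input list size.

Disease-term clustering follows the functional-annotation-clustering
idiom: pairwise Cohen's kappa between term membership profiles over the
pooled item set, then greedy seed-and-merge grouping. The "high"
stringency preset maps to κ ≥ 0.85, a minimum of 3 qualifying partners to
seed a group, and a 0.5 multiple-linkage fraction (groups merge when they
share at least half of the smaller group's members); these three values
are declared surrogates for the platform preset and are individually
configurable. Terms left ungrouped become singleton clusters. The cluster
enrichment score is `−log10` of the geometric mean of member p-values —
equivalently the mean of `−log10 p` — and a singleton's score is its own
`−log10 p`. When chance agreement Pe equals 1 (two terms annotating
everything or nothing), kappa is defined as 0 with a warning rather than
0/0.

## Biomarker panels

Panels are fit by IRLS logistic regression on standardized markers
(tolerance 1e-8, 100 iterations). Marker lists are *inputs*: the package
deliberately performs no marker selection, because published panels are
typically curated from the specific DP/DM lists without a stated
algorithm. Zero-variance markers get coefficient 0 and are flagged.
Complete separation — diverging coefficients or boundary fitted
probabilities — triggers a ridge refit (penalty 1e-6 on non-intercept
terms) and a flag; with a handful of strongly planted markers on ~74
samples, separation is the expected regime, and the ridge fit preserves
the ranking (hence the AUC) while keeping coefficients finite.

AUC is the normalized Mann–Whitney U statistic (ties 0.5); the ROC curve
from the threshold sweep integrates (trapezoid) to the same value to
machine precision, and both routes are asserted against each other and
against an independent ROC implementation. Cross-syndrome evaluation
freezes the training standardization vectors, which is what makes "apply
panel A to cohort B" well defined. Apparent (resubstitution) AUC is
reported, matching common practice at this cohort size; no resampling CI
is computed.

## The synthetic study and its ground truth

`syn_config()` defaults encode the emulated study: 44/37/30 samples
(CCQS/QSBS/HC), 388 quantified proteins (of 470 identified), 1000
untargeted features, 306 targeted metabolites, 11 pooled-standard
replicates, and planted differential counts 17/16/7 (proteins,
specific/specific/shared) and 90/115/110 (untargeted metabolites), so the
planted syndrome totals are 24/23 DPs and 200/225 DMs with the published
overlap structure. Choices the study design leaves open were fixed once:

* **Dynamic range.** Feature log2 means are uniform on [10, 30] (~6
  decades of raw intensity), so CV and missingness behave as in serum DIA
  data.
* **Biological noise.** Per-feature log2 SD is 0.2 for proteins and 0.5
  for metabolites (each jittered ±30 % across features). The protein value
  corresponds to ~15 % intensity CV, the precision regime in which a
  1.1-fold filter on 44-vs-30 group means is an effective second gate
  against null features passing raw p < 0.05; metabolite noise is set
  higher to reflect the larger biological variability of serum metabolite
  pools, with the multivariate+FDR-validated calling rule carrying the
  error control there.
* **Standards.** Standard replicates carry pure multiplicative noise with
  CV 0.05, which puts ≳95 % of per-feature CVs below the 0.10 QC line at
  n = 11.
* **Missingness.** Cell-level missing-not-at-random dropout: each
  proteomics cohort cell is censored with probability
  `plogis(−(log2 x − L)/0.5)`, a soft detection limit with `L` solved so
  the expected overall rate is 2 % — the quantified-protein matrix
  emulates a table already filtered for quantifiability, hence the low
  rate. Censoring at a common limit keeps null features symmetric between
  groups, which is what makes half-minimum imputation safe; feature-level
  dropout models were rejected because they manufacture fold changes in
  null features. Metabolomics tables are complete, as targeted assays and
  aligned untargeted peak tables usually are post-processing.
* **Untargeted feature count.** The pre-filtering feature count is not a
  published quantity; 1000 is a realistic order for a dual-column serum
  acquisition after alignment.
* **Effect size.** Planted features shift by 0.5 log2 units, a modest
  ~1.4-fold change; directions are sampled 30 % up / 70 % down for
  proteins (serum DPs in this setting skew downward) and 50/50 for
  metabolites.

The knowledge base mirrors the published formula structure: six formulae
(three per syndrome) with per-formula herb counts 7/5/5/2/11/3 over 26
distinct herbs — herbs recur across the formulae of one syndrome, never
across a full triple, so the signature intersections remain controlled.
Compound attributes straddle the activity thresholds; targets are arranged
so each syndrome triple shares a planted core (60 and 50 genes overlapping
in 40) while per-formula extras come from disjoint pools, making the
signature sets exactly recoverable. Pathway collections carry one planted
signal pathway per syndrome, named identically across the gene, metabolite
and joint collections and built from syndrome-specific planted molecules
only, so it should surface in that syndrome's views alone. Disease
gene/variant sets are constructed at controlled Jaccard indices on both
sides of the similarity thresholds, and drug targets tie ATC categories to
signature partitions in a block pattern (common↔C, F1-specific↔A10,
F2-specific↔A08/B01). All generation is a deterministic function of the
configuration seed, with the RNG kind pinned.

**What the generator does not emulate:** raw spectra, chromatographic
drift, batch effects beyond the standard-sample design, correlated
feature blocks (features are independent given their group), identifier
ambiguity across knowledge sources, and annotation incompleteness.
Passing tests therefore demonstrate that the statistical machinery recovers
planted structure under the stated noise model — not that the pipeline is
robust to correlated features or to knowledge-base error, which real data
would add.

## Problem sizes and determinism

The test suite and the acceptance script run the full synthetic study at
its default size (388 proteins × 122 samples; 1000 + 306 metabolite
features × 111 samples; a 600-gene knowledge base), with recovery
properties aggregated over 10 generator seeds and permutation nulls over
20 label shuffles — sizes chosen so the whole suite completes in a few
minutes on one core while keeping every binomial tolerance comfortable.
Every stochastic step (generation, fold assignment, permutations) is
seeded explicitly; `run_pipeline()` on a fixed configuration reproduces
its JSON report byte for byte, and the report echoes all thresholds and
the seed for provenance.

## Known limitations

* The equal-variance t-test and raw-scale FC are conventions, not
  optimality claims; Welch and log-scale FC are one flag away.
* VIP from a single predictive component is the O-PLS convention; a
  variant including orthogonal components is deliberately not the default.
* The annotation-clustering preset values are surrogates for a platform
  preset whose exact parameters are not public.
* Enrichment p-values depend on the loaded annotation universe; they are
  not comparable to platform results computed against proprietary
  backgrounds.
* Apparent AUC overstates out-of-sample discrimination; the cross-syndrome
  comparison is the package's specificity check, not a validation study.
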