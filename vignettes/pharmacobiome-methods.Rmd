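---
title: "Methods: drug-mimicry screening of microbiome-associated host gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-mimicry screening of microbiome-associated host gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacobiome)
```

## The model

The screen asks a single question in three statistical steps: does a microbe
or microbial metabolite push host gene expression in the same direction as a
known drug?

**Step 1 — association.** For a feature $f$ (taxon abundance or metabolite
level) and a gene $g$ measured on the same samples, we estimate the Spearman
rank correlation: Pearson correlation of midranks, with the two-sided p-value
from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. Spearman
is the right default because host–microbiome dose–response relationships are
plausibly monotone but rarely linear; the estimate is exactly invariant under
strictly increasing transforms of either variable, so normalization choices
upstream (log scales, quantile transforms) cannot change the result.

For metabolites, community state is a classic confounder: a
*Lactobacillus*-dominant community simultaneously shifts many metabolite
levels and the epithelial transcriptome, so a naive metabolite–gene
correlation largely reflects dominance. We therefore use the partial Spearman
correlation: midrank-transform $x$, $y$ and each covariate column, project the
ranked $x$ and $y$ onto the orthogonal complement of $[1, Z_{\text{rank}}]$ by
least squares, and correlate the residuals, with $n-2-k$ degrees of freedom
for $k$ covariates. With no covariates this reduces — bitwise, by construction
— to the plain estimator. The covariate may be a binary dominance indicator or
a continuous dominant-taxon abundance; both are supported and neither is
privileged (the rank transform makes the distinction mild).

**Step 2 — signatures.** P-values are Benjamini–Hochberg adjusted and genes at
$q \le \alpha$ (default 0.05) form the feature's up set ($\rho > 0$) and down
set ($\rho < 0$). A gene with $\rho = 0$ exactly has no direction and joins
neither set. The BH family is, by default, *per feature across its genes*:
each feature's gene list is constructed as its own multiple-testing problem,
which matches how per-feature gene lists are used downstream and keeps a
feature's list invariant to which other features were profiled. A single
global family is available (`adjust_scope = "global"`) for analysts who prefer
grid-wide FDR semantics; the choice is reported in the output, not hidden.

**Step 3 — directional overlap.** Each feature signature is compared with
each drug signature by Fisher's exact test, up against up and down against
down, over a shared gene universe. The two-sided p-value follows the
minimum-likelihood convention of `stats::fisher.test` (all tables with the
same margins whose point probability is at most that of the observed table,
with a $1 + 10^{-7}$ relative tolerance); a one-sided `greater` alternative is
available since mimicry is enrichment-shaped in spirit. The odds ratio
reported is the sample ratio $(k \cdot d)/(b \cdot c)$ with $x/0 = \infty$ and
$0/0$ flagged as undefined, not the conditional MLE — it is a descriptive
effect size, the inference lives in the exact p-value. Q-values are BH within
each direction across the full feature-by-drug grid (the family a
per-direction heatmap visually compares), configurable to per-drug,
per-feature, or global families. Cross-direction (anti-mimicry, or signature
reversal) comparisons are implemented but off by default: the screen's
definition is concordant mimicry.

**The universe.** The single most result-sensitive choice in any overlap
screen is the background gene set. The default is the *intersection* of the
feature-signature universe (genes tested for correlation) and the drug-catalog
universe: overlap is only observable among genes measurable on both
platforms, and counting unmeasurable genes as "absent from both sets" inflates
the $d$ cell and the apparent significance. Union and explicit-list policies
exist for sensitivity analysis; the policy used is attached to every result
table.

## Reporting and clustering

The screen emits a tidy table (one row per feature, drug and direction:
contingency counts, odds ratio, raw p, Q, capped $-\log_{10} Q$) plus
features-by-drugs $-\log_{10}(Q)$ matrices. $Q = 0$ maps to the cap (default
16, i.e. $Q = 10^{-16}$) so matrices stay finite and serializable; the cap is
a display convention, ranking always uses the uncapped Q. Missing grid cells
(features skipped for empty signatures) enter the matrix as 0 — "no evidence
of similarity" is the semantic zero of this scale.

Drugs (or features) are grouped by agglomerative complete-linkage clustering
on Euclidean distances between their matrix profiles. The linkage is written
in-package rather than delegated because the contract requires a fully
deterministic merge order: among tied pairs, the pair with the lowest
lexicographic pair of smallest original item indices merges first. On tie-free
data the merges and heights coincide with `stats::hclust` (this is asserted in
the test suite); `stats::dist` and `stats::cutree` do the distance and
tree-cutting work. Clustering operates on the $-\log_{10}(Q)$ matrix as
plotted — not raw p-values, not odds ratios — so the dendrogram explains the
figure it annotates.

Ranked mimic tables sort, within drug or within feature and direction, by
ascending Q, then descending odds ratio, then lexicographic identifier: a
total, reproducible order.

## Culture metabolomics calls

For cultured-strain supernatant vs uninoculated-medium profiles the package
deliberately uses the simplest defensible rule: the mean $\log_2$ fold-change
with pseudocount $\varepsilon$ = half the smallest nonzero intensity in the
profile, called produced at $\ge$ +1, consumed at $\le$ −1 (two-fold,
symmetric), unchanged otherwise. No inferential test is attempted at n = 3
replicates; the rule is exactly antisymmetric under swapping the arms, and the
threshold is a visible parameter rather than a hidden convention. This
classifier is this package's own explicit simplification of
production/consumption calling, not a reimplementation of any published rule.

## The synthetic cohort generator

Real cohorts of this kind are controlled-access, so validation runs on
generated cohorts with planted truth. The generator emulates:

* tens of samples, thousands of genes, ~51 taxa, ~99 metabolites, 35 drugs —
  the default `generator_config()` is 90 samples, 2000 genes, 51 taxa,
  99 metabolites, 35 drugs in 7 mechanism classes of 5;
* a Bernoulli(0.5) dominance covariate, with the first taxon's
  logistic-normal latent abundance shifted by ±2 with dominance state;
* planted monotone feature→gene effects: the gene adds
  $\text{sign} \cdot \text{effect} \cdot z$, where $z$ is the unit-variance
  transform of the feature under a link drawn from {identity, square root,
  log}. Monotone nonlinear links are used on purpose: a linear-only generator
  would secretly flatter Pearson-equivalent analyses, and the rank premise of
  the method should be the thing being exercised. Default effect size 1.5
  against unit noise gives a rank correlation around 0.8 when the link
  spreads the feature's values, lower for the identity link on skewed
  abundances — both regimes are represented;
* confounded metabolite–gene pairs (default: 2 of the 5 planted metabolites):
  dominance drives the metabolite (on its log scale) and its genes with the
  same coefficient and *no* direct link. At coefficient 1.5 the induced
  marginal metabolite–gene correlation is about 0.36, which ordinary Spearman
  flags essentially always at n = 100 while partial Spearman given the
  dominance covariate stays at its nominal level — this separation is the
  point of the design;
* drug mechanism classes sharing a class-core gene set (150 of 200 genes per
  direction), each anchored class core containing half of its anchor
  feature's planted genes, plus drug-private noise genes; and mimicry pairs
  (one drug per class, default overlap fraction 0.5 of the anchor feature's
  planted sets, drawn independently of the core's half). The union of core
  and mimicry draws makes the mimicking drug overlap its feature by roughly
  three quarters — strictly stronger than its classmates — while class cells
  and mimicry cells both saturate the $-\log_{10} Q$ cap, so same-class
  columns cluster tightly and mimicry still wins on uncapped Q.

One seed governs everything; per-matrix sub-streams are derived from it
deterministically, and the same seed reproduces cohort and catalog bit for
bit.

What the generator does **not** emulate: real taxon covariance structure and
compositional constraints beyond non-negativity and unit row sums, L1000
measurement noise, batch structure, missing-data patterns of merged clinical
assays, or probe-to-gene collapsing (the pipeline accepts gene-level
matrices; collapsing is upstream). Passing tests on synthetic cohorts
therefore demonstrate the statistical machinery — calibration, confounder
control, recovery, determinism — not performance on any particular clinical
dataset.

## Numerical choices and degenerate inputs

* Midranks everywhere; ties never depend on input order.
* $|\rho| \ge 1 - 10^{-12}$ maps to $p = 0$; $\rho$ is clamped to $[-1, 1]$
  against floating drift.
* Exact permutation p-values for the plain Spearman are available for
  $n \le 9$ (`exact = TRUE`); beyond that the t approximation is the
  estimator, matching the default behavior of `cor.test` in the presence of
  ties.
* Missing cells are excluded pairwise (listwise when covariates are
  involved), tracked per record as `n_used`, with a minimum of 5 complete
  pairs by default (never below 3). Nothing is imputed, ever.
* Constant features or genes (and variables fully explained by covariates,
  whose rank residuals are numerically zero at sd $< 10^{-12}$) produce no
  records and are counted in one warning.
* Complete-data inputs take a vectorized rank-residualize-correlate path;
  inputs with missing cells fall back to per-pair computation. The two paths
  agree to $10^{-12}$ on shared records (tested).
* Rank-deficient covariate matrices are an error, not a silent drop.
* Boundary ties in ranked-profile cuts break lexicographically by gene
  identifier; catalog filters are pure and idempotent and refuse to return an
  empty catalog (naming the criterion that emptied it).

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at sizes chosen to give
the checks real statistical teeth while staying desk-scale: oracle
equivalence on 200 random exact-test instances (universes up to 40), 100
random BH vectors (lengths 1 to 10,000), 100 random correlation cases per
estimator; the confounded design at 2000 replicates of n = 100; end-to-end
recovery, null calibration, and mechanism-class clustering on 20 seeds each
at the full default cohort dimensions (2000 genes rather than a
microarray-scale 23,000 — supported, but needless for validating
rank-and-overlap machinery whose behavior is per-gene).

## Known limitations

* The screen is set-overlap mimicry only; weighted connectivity scores
  (KS-style GSEA statistics) are out of scope by design.
* Exact-test conservatism: under sparse overlaps the null distribution of p
  is discrete and the realized false-positive rate runs below nominal, which
  the calibration checks accept as one-sided bounds.
* Partial Spearman removes *linear-in-ranks* covariate contributions;
  pathological confounding that is non-monotone in the covariate is outside
  its guarantee.
* The cohort interface assumes gene-level expression; probe collapsing,
  normalization and batch correction are upstream responsibilities.
* The command-line surface is R itself: the exported functions and
  `scripts/acceptance.R` are the intended entry points, and every exchange
  format (TSV matrices, paired GMT, metadata sidecars, tidy result TSV) has
  a reader and writer so the pipeline can be scripted stage by stage.
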