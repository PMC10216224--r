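---
title: "Methods: age trajectories in visceral fat and the adipose-liver connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age trajectories in visceral fat and the adipose-liver connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscage)
```

# Scope and data model

`viscage` analyses bulk RNA-seq counts from a cohort structured as
sex × six ordered age decades (20–29 … 70–79), in two tissues: visceral
adipose tissue (the *source*, whose secretome is of interest) and liver
(the *target*, which receives that secretome through the portal
circulation). Counts enter as gene × sample integer matrices with strict
validation (unique upper-cased symbols, unique sample ids, non-negative
integers, no missing values; duplicate gene rows collapse by summation).
The 20–29 group is the fixed reference for every differential contrast,
so it must be present whenever differential expression is run.

# Expression scales

Three scales serve three purposes:

* **log₁₀(CPM + 1)** for differential testing. The pseudo-count is a
  package decision: it maps zero counts to exactly zero, preserves
  within-sample ordering, and keeps the transform defined on sparse
  genes. Fold changes are taken from group-mean differences on this
  scale, rescaled to log₂ by the constant log₂10; for well-expressed
  genes this is the usual log fold change, for very low counts the
  pseudo-count shrinks it toward zero (a conservative bias we accept).
* **TMM-scaled CPM** for trajectory comparison. `tmm_factors()`
  implements the trimmed mean of M-values with the method's canonical
  constants: reference sample = the one whose upper quartile of nonzero
  CPM is closest to the mean upper quartile; M and A computed over genes
  nonzero in both sample and reference; 30 % two-sided trim on M, 5 % on
  A; precision weights = inverse asymptotic binomial variance; factors
  rescaled to geometric mean 1. If fewer than 10 genes survive trimming
  the factor falls back to 1 with a warning. The implementation is
  cross-checked in the tests against an independent naive re-derivation
  and against `edgeR::calcNormFactors` (2 % tolerance).
* **TPM** for absolute expression thresholds in the connectome. Gene
  lengths are user-supplied (the simulator emits them); columns sum to
  10⁶ by construction.

# Moderated differential expression

Each non-reference age group is compared with the 20–29 reference, per
sex, as a two-group comparison: the cohort design has no further
covariates that the package models (hormonal status and BMI are known
unmeasured factors; see Limitations), so the full linear-model machinery
is unnecessary and the test is implemented directly.

Per gene, the pooled variance s² on d = n₁ + n₂ − 2 df is shrunk toward
an empirically fitted prior: s² is modelled as s₀²·F(d, d₀), and (d₀, s₀²)
are obtained by matching the mean and variance of log s² to that
distribution's digamma/trigamma moments, inverting the trigamma function
by monotone root-finding (`uniroot` on a bracketed interval; the function
is strictly decreasing). Two numerical edge cases are defined explicitly:

* If the empirical spread of log s² does not exceed the χ² sampling
  contribution, the prior is degenerate: d₀ = ∞ and every posterior
  variance equals the pooled mean variance (the MLE under a point-mass
  prior). This also covers the all-variances-identical case.
* Genes with zero variance in both groups and zero mean difference get
  t = 0, p = 1 rather than being dropped; moderation gives them positive
  posterior variance otherwise.

The moderated t uses posterior variance (d₀s₀² + d s²)/(d₀ + d) on
d₀ + d df. With d₀ = 0 this is *exactly* the ordinary pooled t (verified
in the tests on 1000 random datasets); with d₀ → ∞ the statistic tends to
the prior-variance z-like form. BH-FDR is applied within each contrast
separately — not pooled across contrasts — matching the
one-table-per-comparison convention of web differential-expression
front-ends. Significance requires FDR < 0.05 *and* linear fold change
≥ 2 in either direction (|log₂FC| ≥ 1); both thresholds are exposed in
`de_config()`. Contrast groups with fewer than 2 samples are skipped with
a warning.

The SASP profile (`sasp_profile()`) reports every panel gene present in
the data whether or not it is significant, starring genes with FDR < 0.05
in at least one contrast; panel genes absent from the matrix are omitted
with a warning.

# Trajectory clustering and AUC ratios

Union DEGs (significant in ≥ 1 contrast, either sex) are summarized as
6-point mean trajectories (group means over samples, sexes pooled) and
row-z-scored before clustering. The z-score uses the population
(n-denominator) sd over the six group means; constant trajectories are
undefined and dropped with a warning.

`kmeans_cluster()` runs Euclidean k-means with K = 11 (a configuration
default, not selected by the package), greedy k-means++ seeding and 50
restarts, keeping the best within-cluster sum of squares; restarts ending
with an empty cluster are counted as failed. Labels are relabelled
deterministically — descending size, ties broken by the lexicographically
smallest member gene — so runs are comparable. Determinism is only
guaranteed for a fixed seed.

"Gradient" clusters are the reproducible operationalization of
visually-monotone trajectory clusters: a cluster is a gradient cluster
iff the Spearman correlation of its centroid with the age-group index
satisfies |ρ| ≥ 0.9 (threshold exposed). With six points, ρ = ±0.94 is
the largest non-unit value, so the rule demands strict monotonicity up to
a single local tie-scale wiggle.

For each gradient cluster and sex, member-gene trajectories are min–max
normalized to [0, 1] (a constant trajectory maps to the midpoint ½),
averaged arithmetically, and integrated by the trapezoid rule over the
unit-spaced ordinal age axis 0…5. Midpoint ages are deliberately not
used: the male/female AUC *ratio* cancels any common axis scaling, and
the ordinal axis avoids pretending to know within-decade structure. A
cluster with no genes expressed in one sex yields a missing AUC and
ratio.

# Cell-type signature scores and trends

The score is a deliberately simple, documented surrogate for trained
deconvolution machinery: per sample, all G genes are ranked ascending and
mapped to normalized ranks (rank − 1)/G; a signature's score is the mean
normalized rank of its members minus ½. It is invariant to any monotone
per-sample transformation (hence to the expression scale), has null
expectation −1/(2G) ≈ 0, and is maximal when the signature occupies the
top of the sample's expression ranking. It does *not* estimate absolute
cell fractions, apply spillover compensation between correlated
signatures, or use trained reference profiles — trends across age within
one signature are the supported use, cross-signature level comparisons
are not. Signatures with fewer than 3 genes present are skipped.

The trend test is the classical post-ANOVA linear contrast: coefficients
are centered equally spaced indices of the usable groups (≥ 2 samples
each; ≥ 3 groups required), t = Σcⱼx̄ⱼ / √(MSE·Σcⱼ²/nⱼ) on N − k df. It is
exact under within-group normality; the suite verifies the 5 % type-I
level within [0.035, 0.065] over 1000 null replicates.

# Over-representation analysis

`ora()` is a local hypergeometric upper-tail test per gene set with
BH-FDR across the collection and score = −log₁₀FDR. The universe defaults
to a user-supplied background (typically all genes in the expression
matrix); web enrichment services use their own internal backgrounds, so
p-values from such services are not expected to match numerically — the
semantics (FDR < 0.05 reporting with log-scores) are what the package
reproduces. No combined z-score route and no ranked (GSEA-style) mode are
provided.

# Network centrality

Eigenvector centrality is computed per connected component (≥ 2 nodes) of
the induced subgraph by power iteration on the weighted adjacency matrix,
tolerance 10⁻¹⁰, ≤ 10 000 iterations, non-negative entries, max-normalized
per component. A diagonal shift of half the maximum row sum is added
before iterating: it leaves eigenvectors unchanged but makes the Perron
eigenvalue strictly dominant, so bipartite components (stars, chains)
converge instead of oscillating; because the shift is proportional to the
weight scale, centrality stays invariant under uniform weight rescaling.
Isolated nodes score 0; ranks break ties by gene symbol.

# Connectome construction

Four ligand filters, all inclusive, mirror the biology of a secreted
signal acting across the portal axis: expressed in the source tissue
(≥ 25 TPM in ≥ 25 % of samples), annotated as secreted to blood (genes
absent from the annotation default to not-secreted; the blood requirement
encodes the curation rule that the protein must reach circulation, and
can be relaxed to any-secreted via `require_blood_secretion = FALSE`),
member of a gradient cluster (the age-responsive secretome), and at least
one interaction partner passing the same expression filter in the target
tissue. Receptors face only the target expression filter plus being
listed as a partner. Raising either threshold can only remove edges
(verified over a 5 × 5 grid in the tests), and every emitted edge is
re-validated against the raw inputs inside `build_connectome()` before
return. Interaction provenance is entirely the user's: the package
performs no interaction prediction and queries no database.

# The simulator: what it emulates and what it does not

`simulate_study()` generates the whole study at the cohort shape of the
targeted design: 241 male / 114 female adipose samples and 161 / 65 liver
samples across the six decades (small youngest and oldest bins, largest
at 50–59), 6000 genes, negative binomial counts (var = μ + φμ², φ = 0.1,
a typical bulk RNA-seq dispersion), and library sizes uniform in 8–12 M.
Expected CPM baselines are log-normal; planted genes are boosted so that
effects are testable at realistic depths.

Planted structure:

* **Eleven trajectory templates** (`trajectory_templates()`): three
  decreasing with distinct kinetics, one increasing, seven non-monotone
  (peaks, troughs, zigzag), 40 genes each, scaled to a 2-log₂ (4-fold)
  maximum deviation from the youngest group. Templates were chosen to be
  mutually separated on the row-z-score scale the clustering consumes, so
  that the planted recovery experiments probe the clustering rather than
  template ambiguity.
* **Delayed female onset**: female group means follow the template one
  age group later than male ones, emulating the later appearance of
  female expression changes; amplitudes are sex-equal. This makes
  decreasing clusters reach their floor earlier in males, hence
  male/female AUC ratios below 1.
* **SASP panel**: 20 genes from the increasing template.
* **Cell-type mixing trends**: four cell types with log₂-per-decade
  marker slopes (−0.30 adipocyte, −0.25 preadipocyte, +0.30 fibroblast,
  +0.20 T cell), 15 markers each, emitted as the signature GMT.
* **Connectome truth**: 6 ligands (spread over the four monotone
  templates) wired to 8 liver-expressed receptors, plus 5 decoy ligands
  each violating exactly one filter — below-threshold expression, not
  secreted, secreted-but-not-blood, non-gradient cluster, and a
  target-silent receptor. Role genes are pinned to exact expected TPM
  (1000 for qualifying, 5 and 1 for the low/silent decoys) so filter
  margins do not depend on the gene count.
* **Network**: within-template chains plus random extra edges (weights
  0.5–1) and weak random background edges (0.1–0.5).

Deliberately *not* modelled: batch effects, GC/length bias beyond the
static per-gene length, isoform structure, correlated genes within
samples beyond template co-movement, dropout, and any covariate
structure. Passing tests on this generator therefore demonstrate that the
pipeline's inference is correct under its own distributional assumptions
— not that those assumptions hold in any particular real cohort.

# Problem sizes and seeds

The calibration experiments use 5000-gene, 10 vs 10 two-group designs (20
null seeds; one 200-gene planted-effect run), 20 000 variances for prior
recovery, 20 seeds × 440 genes for template recovery, and 1000 replicates
for the trend-test level — sizes at which Monte-Carlo error is well below
the tested tolerances while the whole suite stays fast. All randomness is
seeded; the end-to-end pipeline is byte-identical across repeated runs
with the same seed.

# Known limitations

* Fold changes inherit the CPM pseudo-count's shrinkage at very low
  counts.
* The moderated test handles exactly the two-group-per-contrast design;
  no covariate adjustment (the motivating cohort lacks the necessary
  clinical covariates anyway).
* The signature score supports within-signature trends only (see above).
* K = 11 and the |ρ| ≥ 0.9 gradient rule are conventions, exposed as
  parameters, not data-driven choices; the package does not select K.
* Headline counts from any real cohort additionally depend on frozen
  external database versions (secretome annotation, interaction tables,
  gene sets), which enter only as user-supplied files here.
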