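---
title: "Random gene-set survival bias: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random gene-set survival bias: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randbias)
```

## The phenomenon and the statistic

In a cohort with expression for *M* genes and survival follow-up for
*n* samples, a randomly chosen gene set should carry no information
about survival: summarizing it into one score per sample, splitting the
cohort in half at the median score, and comparing the halves with a
log-rank test should give a p-value that is uniform on (0, 1). In many
real cohorts it does not — random sets are "significant" far more often
than 5% (positive random bias), or conspicuously less often (negative
random bias). Either pattern indicates structure in the data that any
supervised signature search will pick up whether or not its genes are
causally relevant, which is why the analysis is worth running before
hunting for prognostic genes.

`randbias` measures the effect exactly as sketched above:

* **Scoring.** The per-sample score is the sample weight on the first
  right singular vector of the gene-centered submatrix
  (`pc1_scores()`). Rows are centered but not variance-scaled: the
  singular value decomposition is taken on covariance, not correlation,
  and scaling is deliberately left off by default because the input is
  assumed to be on a roughly homoscedastic (log) scale. The score's
  sign is arbitrary; the median split is sign-invariant, so this does
  not matter downstream.
* **Splitting.** `median_split()` puts samples strictly below the
  median score in one group and strictly above in the other; samples
  exactly at the median are assigned in stable input order, filling the
  low group to ceiling(n/2) first. The rule is deterministic so
  repeated runs are bit-identical. With continuous scores and even *n*
  (the usual case), negating the scores merely swaps the two labels;
  with odd *n* the single at-median sample changes sides under
  negation, an unavoidable one-sample asymmetry of any deterministic
  tie rule.
* **The empirical null.** Rather than comparing p-values to a uniform
  reference, `null_pvalues()` builds the null from the data itself:
  *b* uniformly random partitions into groups of ceiling(n/2) and
  floor(n/2) — the same group sizes the median split produces — each
  scored by the log-rank test. This absorbs whatever sparse follow-up,
  heavy censoring, and tied event times do to the log-rank null. One
  null sample serves every set size, because it depends only on the
  survival data.
* **The proportion and its test.** The threshold *r* is the 5th
  percentile of the null p-values, computed with the linear
  interpolation (type 7) rule — fixed and recorded so thresholds are
  reproducible — and the proportion of gene-set p-values strictly below
  *r* is the headline quantity. Its two-sided significance uses the
  two-proportion central-limit statistic with the number of random
  draws *b* as the sample size on both sides. (The CLT applies to the
  *b* resampling draws behind each proportion, not to the cohort's
  sample count; with the proportions estimated from *b* draws each,
  this is the only coherent reading.)

The defaults mirror the study design the analysis comes from: set sizes
2^0..2^10 with 64 as the reporting size, *b* = 5000 at full scale, and
0.05 as the significance level throughout, with no multiplicity
correction across datasets.

## The synthetic cohort generator

Every downstream claim is exercised on synthetic cohorts from
`generate_cohort()`, whose three structures encode the competing
explanations of random bias:

* `null` — expression iid Normal(0, noise_sd²), survival independent of
  expression. This is the calibration condition: the proportion of
  significant sets should be 5%.
* `global_signature` — a latent per-sample score *z* ~ N(0, 1) loads a
  fraction of genes (default 0.3) with Gaussian loadings (SD 1) and
  multiplies the hazard through exp(β·z) (default β = 1). This is the
  proliferation-meta-gene explanation of positive bias; the most
  strongly loaded signature gene is recorded in the truth block as the
  natural anchor, playing the role PCNA plays for the proliferation
  program.
* `subclasses` — discrete classes drawn from a mixing vector; a
  fraction of genes (default 0.3) receives class-specific mean shifts
  of magnitude `de_effect·noise_sd` (default 2) with the high/low class
  pattern randomized per gene — never all-equal, so the class signal is
  diffuse and no single gene is a perfect marker; hazards are
  class-specific. Equal per-class hazards produce negative bias
  (consistent splits that do not differ in survival); unequal hazards
  produce positive bias that sub-classification removes.

Survival is exponential with an independent exponential censoring
clock, chosen for its closed-form event fraction
hazard/(hazard + censoring): the defaults (0.01 and 0.003 per day)
give roughly 23% censoring, and the calibration target for random
assignments uses a lighter 0.001 (~9%). The truth block (latent score,
class labels, signal-gene indices, loadings) is stored inside the
cohort rather than recomputed, so recovery tests cannot drift from what
was generated.

What the generator does *not* emulate: negative-binomial RNA-seq count
noise (Gaussian noise suffices to exercise statistics that only see
ranks, covariances and medians), batch effects, gene–gene correlation
beyond the planted structures, and non-proportional hazards. Passing
tests therefore demonstrate the machinery's behavior under the stated
mechanisms, not robustness to every feature of real TCGA-like data.

## Proliferation adjustment

`proliferation_score()` is the median expression over a signature gene
list (mean-of-middle-two for even counts), and `adjust_expression()`
replaces each gene by its residual from an ordinary least-squares fit
on that score, computed in closed form for all genes at once; residuals
are orthogonal to the centered score by construction and the operation
is idempotent. Published proliferation lists are external artifacts, so
the package also offers `derive_signature_from_anchor()` — the top 1%
of genes by Pearson correlation with an anchor gene — as an in-dataset
stand-in; which signature was used is always recorded in provenance,
and scores are always computed from *unadjusted* expression to avoid
circularity. Adjustment succeeds exactly when the score tracks the
latent survival-linked factor, which in turn requires an anchor that
loads strongly on it; a weakly loaded anchor yields a signature of
noise genes and no bias reduction, which is a faithful rendition of why
a platform-mismatched proliferation list can fail on new data.

## Half-split consistency

`consistency_analysis()` asks whether the *same* random sets are
significant in two random halves of the cohort (fair coin per sample,
degenerate halves redrawn and counted). Per-half significance uses the
raw log-rank p against a fixed nominal 0.05 — the empirical-null
machinery is deliberately not used here, because the comparison is
between halves of the same cohort, not against a calibration
reference. All splits × sets are pooled into a single 2×2 table
(significant in A × significant in B) tested one-sided for enrichment
of doubly significant sets; the odds ratio reported is the sample
odds ratio ad/bc. Replication is informative only in the regime where
set-to-set variation exists: when a signature is so pervasive that
essentially every set is significant in every half, the table
degenerates and split-level variation in event richness dominates — the
analysis is a tool for the intermediate regime the field actually
reports (per-half rates of 10–50%).

## Graph-based sub-classification

`cluster_dataset()` chains a k-nearest-neighbor graph under Spearman
correlation distance (1 − ρ, average ranks for ties; neighbor ties
broken by ascending sample index), edge weighting, and Louvain
modularity maximization at resolution 1. Edge construction follows the
shared-nearest-neighbor tradition: candidate edges connect pairs where
either member lists the other among its k neighbors (a literal
all-pairs weighting would produce a dense n² graph and defeat the
purpose of the kNN sparsification); each candidate edge is weighted by
−log10 of the upper hypergeometric tail of the two neighbor lists'
overlap (universe: the n − 2 other samples), capped at 300. One-sided
enrichment is used because only over-represented overlap indicates
similarity. Edges with zero overlap are dropped unless the pair are
mutual nearest neighbors, in which case the edge is kept with a small
positive floor weight (1e-6) so the kNN backbone stays intact while
contributing negligible modularity mass. The reported modularity is
always re-evaluated directly from the modularity formula on the stored
graph, independently of the optimizer.

The default k is 30, reduced to floor(n/3) for small cohorts. The
partition is insensitive to k across the customary range (k ≈ 15–45 at
n = 300 gives near-identical partitions); very small k (≈5) fragments
the graph into many micro-communities and should be avoided —
"insensitive to k" does not extend to degenerate neighborhood sizes.

Per-cluster re-analysis recomputes the empirical null on each cluster's
own survival: the null depends on the survival distribution and the
size of the analyzed group, so inheriting the pooled null would make
per-cluster proportions uninterpretable. Clusters below 10 samples are
skipped. Size-matched random subsamples, analyzed identically, serve as
the control for the pure loss of statistical power that any
down-sampling causes.

## Numerical and scale choices

* Input expression defaults to a log2(x + 1) transform on load; the
  downstream SVD and correlations are variance-sensitive and RSEM-scale
  abundances span orders of magnitude. The flag is recorded in every
  result.
* The log-rank test handles tied event times with the standard
  hypergeometric variance correction, and is implemented as a
  vectorized pass with the survival-dependent quantities precomputed
  once per dataset, because a single analysis calls it ~10^4–10^5
  times.
* Zero-variance genes inside a drawn set are dropped; a fully
  degenerate draw (or an all-tied score vector) is redrawn and counted,
  so exactly *b* valid p-values are always produced.
* Significance counting uses the strict inequality p < r; with
  continuous p-values ties are measure-zero, and strictness makes the
  self-comparison case (P = R) well-defined at ≤ 0.05.
* All stochastic functions take integer seeds; stage seeds are derived
  from one master seed, and the RNG state of the calling session is
  always restored.

Test and calibration problem sizes are chosen to exercise the asymptotic
claims at desk scale: calibration cohorts of 300 samples × 2000 genes
with 1000–2000 resampling draws; mechanism suites of 10–20 seeds at
b = 500. These sizes put the binomial 3σ bands well inside the effect
sizes being detected while keeping a full run in minutes.

## Known limitations

* The forced equal-sized median split interacts with unbalanced
  subclasses: when two survival-identical classes of unequal size
  (binomial mixing makes exact balance rare) dominate every random
  set's first principal component, each draw splits the cohort into
  nearly the same two groups, but the handful of majority-class samples
  forced across the boundary differ from draw to draw. This jitters the
  log-rank p-value substantially around the partition's central value
  even though the partition agreement across draws is ~97%. The
  negative-bias signature — a deficit of small p-values — is robust to
  this jitter; the sharper claim that the within-cohort p-values
  collapse to a near-point mass is not attained at realistic cohort
  sizes, and the test suite documents this as an open discrepancy
  rather than relaxing the check.
* The two-proportion Z treats the empirical-null threshold as fixed at
  its estimate; the extra variance of the estimated 5th percentile
  makes the statistic slightly anti-conservative at small *b*. At the
  default *b* this is visible only in the far tails.
* The consistency odds ratio is undefined (0/0) when a margin of the
  pooled table is empty — the saturated-signal regime discussed above.
* Anchor-derived proliferation signatures are in-dataset constructs;
  they stand in for externally validated lists and are flagged as such
  in provenance, but they cannot distinguish proliferation from any
  other pervasive survival-linked program containing the anchor.
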