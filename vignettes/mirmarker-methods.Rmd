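---
title: "Models and methods behind miRmarker"
author: "miRmarker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miRmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRmarker)
```

miRmarker packages a serum-miRNA biomarker discovery workflow — count
preprocessing, negative-binomial differential expression over a
multi-cohort contrast scheme, candidate selection by DEM intersections,
mutual-information network reconstruction with DPI pruning, Louvain
community detection, comparative-Ct qPCR validation, and target
enrichment. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## The count model and the synthetic cohort

The central object is a `MirnaExperiment` (a `SummarizedExperiment`
holding a miRNA × sample matrix of UMI counts with `group` and `site`
annotations). The generator draws

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij} = s_j\, q_i\, 2^{\beta_{ig(j)}},\ \alpha_i\right)$$

with log-normal baseline means $q_i$ (defaults
$\log q_i \sim N(\log 20, 1.5^2)$, giving the heavy-tailed expression
distribution typical of serum small-RNA libraries), log-normal size
factors $s_j$ (SD 0.4 on the log scale; the depth model is a free choice,
as sequencing depth carries no biological signal here), NB dispersion
$\alpha_i$ (constant 0.2 by default, or gamma-distributed), and planted
group effects $\beta$ in log2 units. The default design emulates a
165-sample multi-site discovery cohort: dnPD (61, site GOE), CTR (58 GOE
and 19 UNIBO) and CENT (27 UNIBO), with 2500 miRNAs.

Two design choices deserve comment:

* **Co-expression blocks via a Gaussian copula.** Block members share an
  exchangeable latent layer $z = \sqrt{\rho}\,u_b + \sqrt{1-\rho}\,e$,
  mapped through each miRNA's NB quantile function. This plants rank
  dependence — exactly what a mutual-information estimator on copula
  scores detects — while leaving every marginal count law untouched, so
  differential expression and normalization behave identically with and
  without blocks. The latent correlation $\rho_b$ translates to a
  pairwise Spearman of roughly $(6/\pi)\arcsin(\rho_b/2)$ minus a small
  attenuation from count ties (about 0.77 observed at $\rho_b = 0.8$).
* **Balanced planted effects (`deBalanced`).** When all planted effects
  share one sign, median-of-ratios normalization absorbs part of the
  effect (the reference medians shift; with 10% one-sided DE we measured
  a bias of 0.06–0.09 log2 units even on high-count miRNAs). Balanced
  designs — half up-, half down-regulated, as real serum studies show —
  keep the normalization assumption (most features null around the
  median) valid. One-sided planting remains available precisely to study
  that failure mode.

Read records (`simulateReadRecords`) emit, per cell with count $c$, $c$
records carrying the miRNA's pseudo-sequence and $c$ distinct fixed-width
base-36 UMIs, each replicated $1 + \mathrm{Poisson}(r)$ times. UMI
collapse therefore inverts generation exactly at every duplication rate —
the identity the preprocessing tests assert.

What the generator does **not** emulate: age/sex covariate effects,
batch effects beyond scalar depth, dispersion–mean trends, adapter or
alignment artifacts, and zero-inflation beyond what the NB produces.
Passing tests demonstrate correctness of the algorithms under the stated
model, not robustness to those unmodelled features of real data.

## Preprocessing

The expressed filter keeps rows with a positive count in at least one
sample. Size factors use the median-of-ratios estimator with the
standard convention that rows containing any zero are excluded from the
geometric-mean reference; a pseudo-reference fallback (row geometric
means over positive entries) is available behind
`pseudoReference = TRUE` for sparse matrices. Rows whose id starts with
`"spike"` are treated as spike-ins and ignored by normalization. No
global rescaling is applied, matching the convention of the reference
implementation the tests cross-check against; consequently scaling one
sample's column by $c$ scales the factor *ratios* by $c$ while the row
geometric means absorb a common $c^{1/m}$.

PCA quality control runs on $\log_2(\text{normalized} + 1)$ restricted to
the most variable rows. This replaces a variance-stabilizing transform:
the PCA here is a diagnostic for group separation and outliers, not an
inferential step, and the log transform is adequate for that purpose.

## Differential expression

Dispersions are method-of-moments estimates,
$\hat\alpha_i = \max\big((v_i - m_i)/m_i^2,\ 10^{-8}\big)$, from the
pooled within-group variance of normalized counts, re-estimated per
contrast after site restriction. The per-miRNA model is the NB GLM with
log link and size-factor offsets, intercept plus test indicator, fitted
by IRLS at fixed $\hat\alpha_i$ (vectorized across miRNAs; coefficients
capped at $|b| = 20$ on the natural-log scale, with capped fits flagged
non-converged and reported with missing p). The Wald $z = \hat\beta /
\mathrm{se}(\hat\beta)$ is referred to the standard normal, two-sided;
BH adjustment runs over the non-missing p-values only.

Deliberate simplifications relative to full-featured DE packages: no
dispersion shrinkage toward a trend, no independent filtering, no outlier
refitting, no fold-change shrinkage, no covariate adjustment. The tests
quantify what this buys and costs under the generator's conditions: type-I
error 0.053–0.058 at nominal 0.05 ($n = 30$/group, $\alpha = 0.1$),
near-uniform null p (KS < 0.02 at 5000 miRNAs), magnitude recovery of a
planted unit log2FC within 0.03, empirical FDR of DEM calling about
0.05–0.08 at nominal 0.05 — mildly anticonservative, the known cost of
plugging a moment dispersion estimate into a normal-reference Wald test
at moderate $n$.

Contrasts carry per-side site restrictions (`testSite` / `refSite`)
because multi-site designs need them: a reference restricted to one
collection site (CTR at UNIBO) compared against a test group collected
elsewhere cannot be expressed by filtering the whole contrast to one
site. Pooled references (e.g. CTR + CENT) take the union of the groups'
samples. Normalization is shared (pooled over the full matrix) across
contrasts by default — the alternative, per-contrast re-normalization,
is available by subsetting the experiment first.

## Candidate selection

Exclusive intersections decompose the union of the DEM sets into the
members belonging to exactly one family of contrasts; their sizes always
partition the union (asserted per run). Significance of each exclusive
row is Monte-Carlo: sets of the observed sizes are redrawn uniformly
from a universe of the declared size, and $p = (1 + \#\{\text{sim} \ge
\text{obs}\})/(B+1)$. The choice of this null is a declared convention —
for two-set families the hypergeometric tail of the pairwise overlap is
computed alongside as the exact reference, and the tests require
agreement in regime (strong overlap → both tiny; null overlap → both
moderate). Candidates come from (i) the `topK` most significant
multi-contrast rows, and (ii) per contrast, the `nUnique`
smallest-adjusted-p DEMs exclusive to it (ties by |log2FC|, then id),
plus manual literature additions; everything is gated by the average
normalized expression floor (default 5 counts, the qPCR platform
recommendation). Manual ids absent from the matrix are kept but flagged,
since they cannot be expression-checked.

## Network reconstruction

Mutual information is computed on normal-scores (rank copula) transformed
$\log_2$ counts: heavy-tailed count marginals would otherwise dominate a
kernel density estimate, and MI is invariant under monotone marginal
transforms, so the copula scale is the natural one. Two estimators are
exposed:

* `kernel` — leave-one-out Gaussian-kernel resubstitution,
  $\hat I = \tfrac1n \sum_k \log\big(\hat f_{XY}(x_k,y_k) / (\hat
  f_X(x_k)\hat f_Y(y_k))\big)$, at bandwidth $h = 1.5\,n^{-1/5}$ on the
  unit-variance scores, debiased by Richardson bandwidth extrapolation
  $2\hat I(h) - \hat I(\sqrt2 h)$ (cancelling the $O(h^2)$ smoothing
  term) and clipped at 0. The bandwidth constant sits at the flat part of
  the bias–variance trade-off under extrapolation: measured worst-case
  error against the bivariate-Gaussian closed form
  $-\tfrac12\ln(1-\rho^2)$ is about 0.04 nats at $n = 2000$ over
  $\rho \in \{0, 0.3, 0.6, 0.9\}$.
* `gaussian_copula` — the closed form $-\tfrac12\ln(1-\hat\rho^2)$ with
  $\hat\rho$ the normal-scores correlation; exact for Gaussian-copula
  dependence (which the generator plants), much faster on large matrices,
  and the default in the pipeline runner.

The independence threshold is, by default, the $(1-\alpha)$ quantile
($\alpha = 0.05$) of MI values computed on row-wise independently
permuted data (10 permutations × 1000 sampled pairs); a fixed threshold
is available for exact reproducibility. DPI pruning marks, in every
triangle, the edge strictly weaker than both partners scaled by
$(1-\tau)$, $\tau = 0.15$, evaluated on original MI values, and removes
all marked edges simultaneously — so the result is independent of scan
order and ties keep both edges. Equivalence with a brute-force
all-triangle oracle is asserted on random matrices. MI is reported in
nats throughout.

## Communities and integration

Louvain greedy modularity optimization (igraph backend) runs at
resolution $\gamma = 1$ by default with 10 randomized restarts, keeping
the partition with the highest weighted modularity
$Q = \sum_c \left[ w_c/W - \gamma\,(s_c/2W)^2 \right]$ (our own
implementation of the formula, cross-checked against igraph's). Restarts
matter on small graphs, where a single greedy pass can stop in a shallow
local optimum; on graphs of up to 8 nodes the tests compare against the
exhaustive best partition over all set partitions. Node degrees are
reported weighted (incident MI sum) and unweighted (edge count), each
placed against its own community's distribution using
linear-interpolation quantiles: strictly above Q3, between median and Q3
(inclusive), below median. DEM–community integration reports overlap
counts, hypergeometric enrichment (universe = network nodes; a
supplementary output beyond plain maximum overlap), and the
maximum-overlap community with ties broken toward the smaller community,
then the lower id.

## Comparative-Ct quantification

Replicates aggregate by arithmetic mean with a QC flag when the range
exceeds 0.5 cycles. $\Delta Ct$ subtracts the arithmetic mean of the
endogenous-control Cts (equivalently the geometric mean of control
expression — the vendor convention); it is invariant to sample-wide Ct
shifts, which is what makes the method robust to global efficiency
offsets. $\Delta\Delta Ct$ is the test-minus-reference difference of
group means, $RQ = 2^{-\Delta\Delta Ct}$, assuming amplification
efficiency 2.0 exactly. Group testing is Student's t on per-sample
$\Delta Ct$ (Welch behind a flag), BH across targets, and the
significance rule $(RQ > 2 \text{ or } RQ < 0.5)$ *and* adjusted
$p < 0.05$ — both gates must pass, so a strongly significant 1.7-fold
change is reported non-significant, exactly as the rule prints.
Normalizer ranking orders candidates by Ct stability (SD across samples)
with distance from a usable-range midpoint (default Ct 25) as
tie-breaker; a group-confounded candidate ranks below a globally stable
one because its between-group shift inflates the overall SD.

## Enrichment

Target enrichment is a one-sided hypergeometric test per gene: population
= distinct miRNAs of the (optionally strong-evidence-filtered)
interaction table, draws = the query list intersected with that
population, hits gated by a minimum interaction count (default 2) and BH
FDR (default 0.05). The universe choice — the supplied table itself — is
deliberate: web tools' internal universes are not reproducible. Evidence
vocabulary is normalized case-insensitively to
strong / weak / non-functional. Gene-set enrichment applies the same
tail against a declared gene universe; the miRNA-augmented-pathway view
is reduced to a table (pathway, gene, repressing miRNAs from the list).
For small populations the tails are asserted equal to explicit
enumeration of the hypergeometric support.

## Numerical conventions and degenerate inputs

* Constant expression vectors have MI defined as 0 (with a warning);
  duplicated profiles get the maximal finite MI via
  $\hat\rho^2 \le 1 - 10^{-12}$.
* All-zero count rows are reported with missing p and excluded from the
  BH denominator.
* Quantiles everywhere use R's default linear interpolation (type 7).
* BH adjustment delegates to `stats::p.adjust` on the non-missing
  entries; the test suite keeps an independent step-up implementation as
  the oracle.
* Seeds: every stochastic stage takes an explicit seed and restores the
  caller's RNG state; `runDiscovery` derives stage seeds from the global
  one, making end-to-end runs bit-reproducible.

## Problem sizes used in the checks

The test and acceptance runs use cohorts of 30–60 samples per group and
80–5000 miRNAs: large enough that calibration statements (type-I error,
KS distance, FDR, ARI) have narrow Monte-Carlo spread, small enough to
run in minutes on one CPU. The full-scale default design (2500 miRNAs ×
165 samples) is exercised end to end by the acceptance script's
expressed-count check.

## Known limitations

* The DE module is a transparent approximation to shrinkage-based
  packages; at very small $n$ or extreme dispersions its Wald test is
  anticonservative. Checks against DESeq2 are part of the test suite for
  the regimes where the two should agree.
* The kernel MI estimator is quadratic in the cohort size per pair; for
  matrices beyond a few hundred miRNAs use the Gaussian-copula estimator
  (exact under the generator's dependence model).
* The Monte-Carlo intersection p-values assume independent uniform sets;
  correlated contrasts (sharing reference samples) violate that null,
  which is why those p-values are used for ranking, not inference.
* Quartile placement labels depend on the quantile convention; the
  interpolation choice is stated above and fixed.
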