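---
title: "dreambench: models, nulls and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dreambench: models, nulls and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dreambench scores blind reverse-engineering submissions against withheld
gold standards. Every score in the package is a p-value story: a metric is
computed, a null model says how that metric behaves for random
submissions, and the reported score is `-log10` of a geometric mean of
p-values, so one unit of score is one order of magnitude of significance.
This vignette documents the models, the tunable parameters, and the
numerical decisions, in enough detail that a maintainer can defend or
change them.

## Assignment scoring: exact enumeration

An assignment challenge asks teams to identify M measured signals among S
candidate molecular species, injectively. The sample space of random
tables has size S!/(S−M)! (840 for S = 7, M = 4). `match_distribution()`
computes, in closed form by inclusion–exclusion over forced agreements,

N_m = Σ_{j≥m} (−1)^{j−m} C(j, m) C(M, j) (S−j)!/(S−M)!,

the number of tables agreeing with a fixed reference in exactly m cells;
by symmetry the reference does not matter (the test suite checks this
against brute-force enumeration over random references). A submission
with m correct assignments gets the exact tail p = P(matches ≥ m).
Enumeration is refused above S = 12: challenge catalogs are tiny and no
approximation is warranted.

Community questions ("what is the chance k of n independent teams hit the
same cell?") use the upper binomial tail with per-team success
q(s) = (S−s)!/(S−M)! ÷ S!/(S−M)!, the probability that a random table
reproduces s specified cells. Independence of teams is the null being
tested, not an assumption about reality: a small p is evidence of shared
signal in the community.

## Response scoring: normalized squared error

Withheld measurement cells are scored by
Σᵢ (xᵢ − pᵢ)² / (σ²_tech + (cv·xᵢ)²). Two decisions needed to be made
where the source text is ambiguous between standard deviations and
variances:

* the denominator is read as a variance, the sum of a squared technical
  floor and a squared biological term; with the defaults σ_tech = 300
  (fluorescence units, the detector's sensitivity floor) and cv = 0.8
  (dimensionless coefficient of variation), both exposed as
  `error_model()` parameters;
* the *measured* value xᵢ, not the prediction, parameterizes the
  biological term, matching "product of the coefficient of variation and
  the measurement".

Values below the noise floor are not clipped before scoring, and detector
saturation (the ~29000 ceiling) is not modeled.

The null model re-fills each withheld cell by drawing, with replacement,
from the observed values of the same analyte column, so random
predictions live on each analyte's own dynamic range. The p-value is the
lower tail (small error is good): a smoothed empirical fraction
(r+1)/(n+1) by default, or the stretched-exponential fit (below) when
extrapolation beyond the simulated range is needed.

## Expression scoring: Spearman profiles

Rank-matrix predictions (each column a permutation of 1..G, rank 1 = most
induced) are scored per time profile (length-G vectors) and per gene
profile (length-T vectors) by Spearman's ρ with average ranks for ties.
P-values are one-sided upper tails — predicting the reversed ordering is
scored as bad, a choice the source leaves open. For profile lengths
n ≤ 9 the null is exact: the distribution of Σd² over all n! permutations
is enumerated once and cached (40,320 permutations for n = 8; the suite
verifies the mass sums to 1). For larger n the t approximation
t = ρ√((n−2)/(1−ρ²)) with n−2 df is used, except at the boundary |ρ| = 1
where the approximation diverges and the exact tail 1/n! (or 1) applies.
Per-axis p-values are condensed by geometric mean, and the overall score
is −log10 √(p_time · p_gene), strictly decreasing in each p.

Per-gene difficulty is the geometric mean of a gene's gene-profile
p-values across teams; it ranks genes from community-easy to
community-hard without any per-team tuning.

## Network scoring: AUROC, AUPR and truncated lists

A ranked list over the R = N(N−1) candidate directed edges is swept at
every depth k. AUROC is the trapezoid of TPR against FPR from the origin,
which on full lists equals the Mann–Whitney concordant-pair count exactly
(property-tested). AUPR is *average precision* — the mean of TP(k)/k over
positive-retrieval events — rather than a trapezoid in (recall,
precision) space. Average precision was chosen because it remains exact
under expected-value completion of truncated lists; the trapezoid
alternative is noted and deliberately not implemented.

Truncated lists are completed analytically: the unsubmitted edges are
conceptually appended in uniformly random order, and every count beyond
the truncation depth k_t is replaced by its expectation. With P_r
unsubmitted positives and N_r unsubmitted negatives, expected TP grows by
P_r/(P_r+N_r) per step; for AUPR the precision at a tail rank k is
conditioned on a positive landing there,
E[TP(k) | positive at k] = TP(k_t) + 1 + (k−k_t−1)(P_r−1)/(P_r+N_r−1).
Because the linear expected tail makes the ROC trapezoid equal the exact
expected AUROC, the deterministic completion and the Monte-Carlo mean
over random tails agree; the acceptance suite checks this at 10⁵ tail
shuffles (tolerance 0.005) and on exactly enumerable cases (expected
AUROC = AUPR = 0.75 for the two-positive/two-negative worked examples).
Scores are therefore reproducible: no actual random appending ever
happens.

Null distributions come from uniformly random orderings; only the
positions of the P positives matter, so each replicate is a P-subset draw
with closed-form metrics — cheap enough for 10⁵ replicates on a 100-node
universe. P-values use the smoothed empirical fraction inside the sample
range and the fitted tail outside it. If the tail fit cannot be built
(too few usable histogram bins, common for heavily skewed AUPR nulls at
small replicate counts) the empirical fraction is used with a warning
rather than failing the pipeline.

## The stretched-exponential null fit

Empirical metric histograms are summarized by
f(x) = h·exp(−(b_side·|x−x₀|)^c_side) with independent (b, c) on each
side of the mode. Choices:

* the argument form (b·|x−x₀|)^c among algebraically equivalent
  parameterizations;
* histogram bins by Freedman–Diaconis (minimum 10), overridable;
* x₀ is the modal bin midpoint and h the modal density; each side is then
  fitted by least squares on log-density over its non-empty bins
  (port-algorithm `nls`, started from the log–log linearization), with
  empty bins ignored rather than pseudo-counted;
* at least 3 non-empty bins per side are required, and samples smaller
  than 1000 are refused — tail extrapolation from less data is not
  meaningful;
* tail masses use the incomplete-gamma closed form
  ∫_d^∞ exp(−(bt)^c) dt = Γ(1/c)/(bc) · Q(1/c, (bd)^c); the suite
  cross-checks against adaptive quadrature at 10⁻⁶ and verifies the
  normalized density integrates to 1;
* p-values are floored at the smallest positive double and flagged
  `below_precision` instead of returning 0 (rendered as an asterisk
  convention by the CLI).

Calibration rather than value-matching validates the defaults: Gaussian
samples recover c ≈ 2 (±0.3) and give p within a factor 3 of 0.01 at
their empirical 99th percentile; Laplace samples recover c ≈ 1.

## Null-mutant z-score inference

For each ordered pair, z(A→B) standardizes B's expression in the
A-knockout strain by B's mean and standard deviation across the strain
panel. Decisions: the sample standard deviation (divisor n−1) is the
default, with a `population` option; the panel is the wild type plus the
knockout strains — knockdown strains and trajectories are excluded unless
`include_knockdowns = TRUE`, reading "all strains" as the panel the
method actually uses. A target with zero variance scores 0 for all its
regulators (ranked last) with a warning. Ranking is by |z| descending
with a lexicographic (source, target) tie-break, so output is
deterministic and full-length.

## Consensus and community analytics

The rank-sum consensus assigns every edge the sum of its ranks across
lists and re-ranks ascending. Truncated lists contribute the *average*
unfilled position (k_t+1+R)/2 for omitted edges — deterministic, unlike
the seeded random completion used for identifiability thresholding, where
the analysis protocol explicitly randomizes. Identifiability counts, per
gold edge, the teams including it in their top 2P entries (P = number of
gold edges); random-community references are simulated for comparison,
and the two-sample KS test (exact by enumeration of label assignments for
m+n ≤ 12, asymptotic Kolmogorov tail otherwise) compares distributions.

Systematic false positives are the top 1% of negatives by team votes;
vote ties straddling the boundary are all included (recorded in the
output) rather than broken arbitrarily. Negatives are classified as
*shortcut* (a directed path of length ≥ 2 connects the pair — any longer
chain counts, not just length 2) and/or *co-regulated* (a shared
regulator exists); the flags are computed independently and their overlap
reported, rather than requiring path absence for co-regulation. The 2×2
systematic/rare × special/generic table sums to the total number of
negatives and is tested by Fisher's exact test, two-sided by the
point-probability method (summing all tables with the observed margins no
more probable than the observed one).

## The simulator: what it emulates, and what it does not

The simulator exists to generate fixtures with the challenge's *strain
conventions*, not to reproduce the original thermodynamic generative
model. Dynamics are additive saturating activation/repression with
linear decay: dxᵢ/dt = basalᵢ + Σ_j w_ij·H(x_j) − λxᵢ with Hill terms
H(x) = x^h/(K^h + x^h) (activators) or its complement (repressors).
Defaults: λ = 1, K = 0.5, h = 2, weights uniform on [0.5, 1.5], 80% of
edges activating (evaluation is unsigned), basal 0.1 for regulated genes
and 1 for unregulated ones, giving a dynamic range of order 1.

Networks are acyclic by construction (random topological order,
regulators earliest, gamma-weighted out-degrees for heterogeneity), so
steady states are solved *exactly* in topological order — the residual
max|dx/dt| at any reported equilibrium is at machine precision, checked
against a 10⁻⁸ gate. Knockouts clamp a gene to zero and re-equilibrate
(the clamp is persistent — the plausible alternative, zeroing once
without clamping, would let the gene re-accumulate); knockdowns clamp to
half the wild-type level. Trajectories integrate the wild-type system by
RK4 from random initial states. Gaussian noise of sd `noise_sd`
(default 0.05, about 5% of the dynamic range; the source only says "a
small amount") is added independently to every reported value.

What a green test does **not** establish: the simulator has no feedback
loops, no mRNA/protein layers, no saturation ceilings, and Boolean-like
knockout responses — real expression data are harsher in every respect.
Passing fixtures demonstrates that the *scoring machinery* is correct and
that the z-score baseline behaves as designed on data matching its
assumptions, not that any method would perform comparably on biological
data. The team-dependent numbers of the original contests (score tables,
inter-team correlations, placement of the z-score baseline) require the
original submissions and are explicitly out of reach at desk scale; the
package substitutes property-based checks — perfect recovery on noiseless
star networks, median AUROC > 0.8 at 10% noise, consensus robustness to
random members, oracle equivalence for the small tests.

## Degenerate inputs and tie-breaks, collected

* Constant rank vectors: Spearman ρ undefined — error, never NA.
* Constant null samples: degenerate — error.
* Zero-variance z-score targets: score 0, warning.
* Equal-confidence prediction rows: file order is the ranking.
* Equal |z| or equal rank sums: lexicographic (source, target).
* Vote ties at the systematic-FP boundary: all included, count reported.
* p-values never return exactly 0 or exactly 1 from tail fits.
* Every reader validates totally; malformed input raises a typed
  condition (`dreambench_validation_error`), never a silent repair.

## Known limitations

* Exact assignment enumeration stops at S = 12 by design.
* The exact Spearman null stops at n = 9 (the t approximation takes over).
* The KS exact branch stops at m+n = 12; beyond that the asymptotic tail
  is used even for moderate samples.
* AUPR is average precision; trapezoidal AUPR from other toolkits will
  differ slightly on the same input.
* No signed or undirected network evaluation modes, and no partial
  credit for reversed edges.
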