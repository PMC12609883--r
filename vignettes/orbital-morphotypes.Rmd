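---
title: "Orbital morphotypes: model, derivation and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbital morphotypes: model, derivation and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitype)
```

## The problem

The bony orbit is summarized here by three linear dimensions measured on CT
models: depth (D, anteroposterior), height (H, rim to rim) and width (W,
mediolateral), all in millimetres. Across a reference cohort these
dimensions fall into three recurring shape classes — **A (Tall & Broad)**,
**B (Deep & Broad)** and **C (Compact)** — each about a third of the
population. The classes matter surgically: when both orbits are damaged and
the mirror-image reference is unavailable, a morphotype assignment supplies
expected proportions for reconstruction planning. Even millimetre-scale
dimension differences correspond to visible changes in globe position, so
the classification has to be quantitatively careful.

`orbitype` implements three layers: a generative model of such cohorts, the
fixed published decision rules, and the derivation pipeline that produces
rules of that kind from labelled or unlabelled data.

## The generative model

Each orbit belongs to a type $k \in \{A, B, C\}$ drawn from prevalences
$\pi = (0.335, 0.302, 0.362)/0.999$ (the printed percentages sum to 99.9%
and are renormalized). Conditional on the type, each dimension is drawn
independently from a normal distribution $\mathcal N(\mu_{k,d},
\sigma_{k,d}^2)$ truncated to the published observed range $[a_{k,d},
b_{k,d}]$. The nine $(\mu, \sigma, a, b)$ quadruples are the package
defaults in `morphotype_parameters()`.

Two modelling points deserve emphasis:

* **Truncation shifts moments.** The truncated mean is
  $\mu + \sigma\,\frac{\phi(\alpha)-\phi(\beta)}{\Phi(\beta)-\Phi(\alpha)}$
  with $\alpha,\beta$ the standardized bounds; where the published range is
  asymmetric around the mean (most extreme: type C width, range
  [26.5, 37.2] around 34.22, truncated mean ≈ 34.09) the simulated group
  mean is *not* the tabulated mean. `truncnorm_moments()` gives the exact
  moments; the test suite checks the generator against an independent
  quadrature oracle rather than against the tabulated values.
* **Independence within type is an assumption.** Within-type correlations
  between D, H and W are not published, so the default draws them
  independently. `simulate_cohort(correlation = ...)` accepts per-type
  correlation matrices (sampled by joint rejection on the box through a
  Gaussian copula) for sensitivity analyses; all reference results in this
  package use the identity default. Tolerances on reproduced
  classification accuracies are set with this assumption in mind — real
  orbits with positively correlated dimensions would separate slightly
  differently.

Rejection sampling is used for the truncation because it is exact and
simple; with the default parameters each box holds ≳ 95% of the parent
mass, so the expected number of parent draws per accepted value is below
1.06.

Covariates are layered on afterwards. Sex is Bernoulli (63.3% male). Age is
truncated-normal (44.6 ± 18.1 years on [8, 88]) and rank-coupled to width
through a Gaussian copula whose correlation parameter is the exact solution
$r = 2\sin(\pi\rho_s/6)$ of the bivariate-normal Spearman relation, so the
induced Spearman correlation matches the target (default −0.11, the weak
age-related narrowing seen in the reference cohort). Additive male shifts
for depth and width default to 0 mm because no per-sex means are published;
they exist so users can emulate the reported sex dimorphism (male orbits
deeper and wider) at a magnitude of their choosing. Setting all covariate
effects to zero provably decouples dimensions from covariates.

The default cohort size is 499, the reference cohort's orbit count. (The
published per-type counts 163 + 147 + 176 sum to 486 and the ANOVA degrees
of freedom match 486; the fate of the remaining 13 orbits is not explained.
The generator targets the printed prevalences and leaves `n` free.)

## The indices and decision rules

The proportional indices are per-orbit ratios: DI = D/W, WI = W/H,
HI = H/W, so HI·WI = 1 identically. Whether a tabulated index mean is the
mean of per-orbit ratios or the ratio of group means is ambiguous at 2
decimal places; the package computes per-orbit ratios at full precision and
rounds only for display, half away from zero (`round_half_up()`). The
worked-example checks use only cells where both conventions agree after
rounding (DI for type A, WI and HI for type B).

The full rule is a two-level threshold cascade: H > 34.35 mm → A, else
D > 41.65 mm → B, else C. The published text uses strict ">" for the A and
B branches, so boundary values fall through to the lower branch — a record
exactly on both thresholds is type C. Width "supports" borderline cases in
the publication, but the two printed width thresholds overlap (W >
34.45 → B yet W ≤ 36.25 → C both cover 34.45–36.25). Since the primary
rules already partition the space, width support is implemented as a
non-overriding annotation on borderline records only (within 0.5 mm of
either threshold — the publication gives no numeric definition of
borderline): W > 36.25 leans B, W ≤ 34.45 leans C, no lean in between.
These lean directions are chosen to be mutually exclusive; the annotation
never changes the label.

The depth-only fallback uses two cut points D1 = 40.75 and D2 = 41.95 mm.
The interval-to-type mapping is not printed; it is fixed here by ascending
type-mean depth (C 38.56 < A 40.1 < B 43.52), i.e. D ≤ D1 → C,
D1 < D ≤ D2 → A, D > D2 → B. This mapping also reproduces the published
observation that B and C are distinguished more reliably than A, which
occupies the narrow middle band.

## The derivation pipeline

`orbit_kmeans()` standardizes each dimension to zero mean and unit sd
(denominator $n-1$) and runs Lloyd iterations with k-means++ seeding, 10
restarts by default, keeping the lowest within-cluster sum of squares. The
objective is asserted non-increasing at every iteration, and an emptied
cluster is re-seeded at the point farthest from its assigned centroid.
Restart count, iteration cap (300) and seed are exposed because none are
published. Clustering uses the three raw dimensions by default;
`include_indices = TRUE` adds the standardized indices, since it is not
recorded whether the original clustering included them.

`name_clusters()` maps clusters to types anatomically: greatest mean raw
height → A, then greatest mean raw depth among the rest → B, remainder → C.
Ties are broken by cluster index with a warning.

`orbit_lda()` is Gaussian linear discriminant analysis from first
principles: class means, pooled within-class covariance (denominator
$n - k$), proportional priors (priors are not published; class-size priors
are the conventional default), and linear scores $\delta_k(x) = x^\top
\Sigma^{-1}\mu_k - \frac12 \mu_k^\top \Sigma^{-1}\mu_k + \log\pi_k$. The
test suite verifies predictions against both a brute-force Gaussian
posterior oracle and the MASS reference implementation.
`cv_lda()` stratifies folds by class (the publication says only "5-fold"),
with a seeded fold assignment.

`derive_rule_cutoffs()` re-derives the threshold cascade under the
published structure — root split on H, child split on D — by exhaustive
search over midpoints of consecutive sorted unique values, maximizing
training accuracy with ties broken toward the smaller threshold. The
structure is constrained deliberately: an unconstrained impurity-grown tree
could choose different variables and would not be comparable to the
published rule form.

`optimize_depth_cutoffs()` searches all ordered midpoint pairs $d_1 < d_2$
for the C/A/B interval rule. With depths sorted, the best lower cut for
each upper cut is a running prefix maximum, so the search is $O(n\log n)$
rather than $O(n^2)$ — the test suite pins it to a brute-force pair
enumeration. Confidence intervals are percentile bootstrap over record
resamples (B = 1000 by default; the publication states bootstrap CIs
without method or replicate count). Resamples that lose a class or drop
below three distinct depths fall back to the point estimate. The objective
is raw accuracy by default ("optimized cut-off" is not otherwise
specified); balanced accuracy is available.

## Group statistics

ANOVA, Kruskal–Wallis, Mann–Whitney, Spearman and Welch tests are delegated
to base R (`aov`, `kruskal.test`, `wilcox.test`, `cor.test`, `t.test`); the
package adds the effect sizes and policy. η² is SSB/(SSB+SSW).
Rank-biserial is $r_{rb} = 2U/(n_1 n_2) - 1$, positive when the first group
is stochastically larger. Mann–Whitney uses exact enumeration when
$n_1 n_2 \le 400$ without ties, otherwise the tie-corrected normal
approximation. Pairwise post hoc comparisons use Bonferroni-corrected Welch
tests rather than Tukey HSD: the studentized-range distribution is not
implemented here, Bonferroni is also used in the reference analysis for the
age comparisons, and no exact post hoc p-values are being reproduced.

`mixture_eta2()` computes the analytic η² of the mixture in two
conventions. With `moments = "printed"` the tabulated mean/SD are used
directly as group moments — the right reading when a table reports
empirical moments of observed (hence already truncated) data; this route
reproduces the published η² of 0.475/0.515/0.404 for D/H/W to within 0.01
(analytic 0.472/0.512/0.403). With `moments = "truncated"` the group
moments are those of the truncated normals actually sampled; this route
matches large-n simulated cohorts to within 0.005 and is the one the
simulation cross-checks use. The distinction exists because truncation
shrinks within-group variance, raising η² of the generator's output above
the printed-moment value (to ≈ 0.50/0.55/0.46).

## Problem sizes and tolerances

The reproduction checks run at sizes chosen to keep Monte Carlo error well
inside the stated tolerances: classifier accuracies on one cohort of
100,000 orbits (binomial SE ≈ 0.15 percentage points), the derivation
pipeline on 20 replicate cohorts of n = 499 (the reference size), moment
checks at 50,000–100,000 with 4-SE bands, and the ANOVA type-I calibration
over 4,000 null datasets. Accuracy tolerances (±4 points on the full rule,
±3 on depth-only, ±2.5 on CV accuracy, ±0.02 on type-B recall) are
dominated not by MC error but by the independence assumption discussed
above.

## Known limitations

* Within-type dimension correlations are assumed zero by default; the
  published full-rule accuracy (82.1%) is reproduced about 1.5–2 points low
  (≈ 80.3%), consistent with that assumption, and well inside the stated
  band.
* Synthetic cohorts inherit none of the measurement process: no
  inter-observer error, no modality differences (CBCT vs FBCT), no
  left–right pairing within patients (records are independent orbits).
  Passing reproduction checks therefore validates the statistical
  machinery, not the measurement protocol.
* Per-sex and per-age-group distribution parameters are not published, so
  the sex/age statistics are demonstrated on user-set effect sizes rather
  than reproduced.
* The depth-only cut-point *estimates* depend on the optimization criterion,
  which is not published; only the accuracy of the printed cut points is
  treated as a reproducible quantity.
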