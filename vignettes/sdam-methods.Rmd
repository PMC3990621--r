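---
title: "Measuring mental representation structure and putting performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mental representation structure and putting performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mentalrep)
```

## The measurement model

`mentalrep` analyses two levels of motor learning at once: the covert level
of how a movement is represented in long-term memory, and the overt level
of outcome performance. Both rest on simple, explicit models.

### From binary judgments to distances

The splitting task yields, per participant and test day, an $N \times N$
binary decision matrix $D$: row $a$ holds the judgments "is concept $p$
related to anchor $a$ during movement execution?" for every probe $p \ne
a$. The working assumption is that two concepts which are close in memory
are related *to the same other concepts* — their judgment profiles agree.
For a pair $(i, j)$ we therefore correlate rows $i$ and $j$ of $D$
restricted to the $m = N - 2$ probe columns both rows share (columns $i$
and $j$ themselves are excluded so that neither profile judges the other
member of the pair), and map the correlation to

$$d_{ij} = \sqrt{2m\,(1 - r_{ij})},$$

which is exactly the Euclidean distance between the two z-standardised
profiles of length $m$. It is strictly decreasing in $r$, $d(1) = 0$, and
$d(-1) = \sqrt{4m} \approx 7.48$ for $m = 14$. The shared-column count $m$
is an explicit argument of the scaling functions because other splitting
implementations use $m = N$ or $m = N - 1$; results are convention-dependent
and the critical value below is only meaningful relative to one convention.

Two numerical corner cases needed decisions:

* **Zero-variance profiles.** A participant may judge every shared probe
  identically for one anchor. Pearson's $r$ is then undefined. If *both*
  restricted rows are constant *and equal*, the profiles agree perfectly and
  we set $r = 1$; this is not an edge case but the generic situation for a
  two-concept cluster whose members relate to nothing else (their mutual
  columns are the excluded ones, leaving two equal all-zero profiles), and
  treating it as "no information" would make two-concept clusters
  unrecoverable even from noise-free data. Every other zero-variance pair
  genuinely carries no signal and gets $r = 0$ with a warning, so that group
  averaging stays defined.
* **Group averaging.** Mean-group structures average the per-participant
  correlation matrices entrywise on Fisher's $z$ scale (clamped to $|r| \le
  1 - 10^{-6}$ so perfect agreement does not transform to infinity), then
  back-transform, and only then map to distances. Averaging on the $z$ scale
  is variance-stabilised; averaging raw distances would weight disagreement
  asymmetrically. Whether historical mean-group dendrograms averaged
  correlations or distances is not documented, so the linear alternative is
  selectable (`average = "linear"`), and a side effect of the clamp is that
  a group in perfect agreement has within-cluster distances of about
  $\sqrt{2m \cdot 10^{-6}} \approx 0.005$ rather than exactly zero —
  negligible against any realistic cut height.

### From distances to cluster solutions

Dendrograms are built by unweighted average linkage (UPGMA): the merge
height of two clusters is the mean of all pairwise leaf distances between
them. UPGMA heights are non-decreasing, so the tree has no inversions, and
ties are broken by the lexicographically smallest pair of cluster indices
(clusters indexed by their smallest leaf) for bit-identical results across
platforms. The linkage variant is itself a convention: sources describe
"hierarchical cluster analysis" without naming the rule, and average linkage
is the one used throughout the SDA-M literature; other rules are outside
the tested contract.

The flat cluster solution cuts the tree at a critical value $d_{crit}$:
concepts linked **strictly below** $d_{crit}$ form a cluster, everything
else stays a singleton. The strict inequality implements "linked below this
value"; a merge at exactly the critical value does not form a cluster.
$d_{crit} = 3.41$ is the conventional value for a 16-concept set at
$\alpha = .05$; its derivation belongs to the original instrument and is
not re-derived here — under this package's scaling it corresponds to
$r_{crit} = 1 - 3.41^2 / (2m) \approx 0.585$, which is why the value only
transfers between implementations that share the scaling convention. For
synthetic cohorts the package also offers a data-driven policy,
`d_crit_midpoint()`: the off-diagonal distances are split by the exact 1-D
two-means partition and the cut is the midpoint of the two class means,
i.e. the point between the within- and between-cluster modes of a bimodal
distance distribution. It is deterministic and never sees the planted
labels.

### Comparing cluster solutions

Similarity to the movement-phase reference partition (preparation
{1–4}, backswing {5–7}, forward swing {8,9}, impact {10–13}, attenuation
{14–16} for the default putt catalog) is measured by the Hubert–Arabie
Adjusted Rand Index computed from the block-overlap contingency table.
Concepts outside any cluster enter as singleton blocks; that convention is
validated by reproducing published worked examples exactly at two decimals
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).
Reported ARIs are rounded half away from zero to 2 dp, matching how such
tables are conventionally printed.

Whether two solutions are *structurally* the same is classified by an
invariance measure $\lambda$ with the conventional threshold 0.68
(invariant iff $\lambda \ge 0.68$). The measure implemented here is a
documented substitute — the original formulation is in instrument-specific
literature that defines only the threshold semantics publicly. Over the
non-singleton blocks $A_i$ of one solution and $B_j$ of the other,
$\sigma_{ij} = |A_i \cap B_j| / \sqrt{|A_i||B_j|}$ and

$$\lambda = \frac{\sum_i \max_j \sigma_{ij} + \sum_j \max_i \sigma_{ij}}{p + q},$$

with $p$, $q$ the non-singleton block counts; if neither solution has a
non-singleton block $\lambda = 1$, if exactly one has none $\lambda = 0$.
This keeps $\lambda \in [0, 1]$, symmetric, and equal to 1 exactly on
structurally identical solutions, and it is isolated behind one function so
the original measure can be substituted without touching callers.

### Outcome performance

Putt outcomes are signed 2-D offsets from the target centre in cm
($x$ lateral, $y$ along the target line — the CSV contract fixes the axis
convention because error scores are reported per axis convention).
Accuracy is mean radial error, consistency is bivariate variable error:

$$MRE = \frac{1}{k}\sum_i \sqrt{x_i^2 + y_i^2}, \qquad
BVE = \sqrt{\frac{1}{k}\sum_i \left[(x_i - \bar x)^2 + (y_i - \bar
y)^2\right]}.$$

BVE uses the $1/k$ divisor — the literal "mean squared distance from the
centroid" — with $1/(k-1)$ selectable. Scores are computed per participant
× test day over all putts of that day (pooling the three blocks); per-block
scoring is available via the `by` argument, since descriptions of such
designs do not always pin this down. Missing trials are tolerated and
counted, not imputed.

Group contrasts use the Holm–Bonferroni step-down: the $k$-th smallest of
$m$ p-values is tested against $\alpha / (m - k + 1)$, stopping at the
first failure. The family is all six pairwise contrasts among four groups
per dependent variable — inferred from the printed threshold ladder
.008/.010/.013/.017, which is exactly ranks 1–4 of $m = 6$ at
$\alpha = .05$ (with thresholds rounded half away from zero to 3 dp;
round-half-even would print .012 at rank 3). Cohen's $d$ uses the pooled
standard deviation. Omnibus covariate-adjusted models (MANCOVA/ANCOVA) are
deliberately not implemented: they need the raw covariates of a concrete
study, and the per-participant summary table exports cleanly to dedicated
statistical software.

## What the synthetic cohorts emulate — and what they do not

The generator exists so that every stage of the pipeline is testable
without access to raw study data.

* **Judgments** are independent Bernoulli draws per ordered (anchor, probe)
  pair: probability `p_within` if the pair shares a block of the planted
  partition, `p_between` otherwise. The demo schedule starts every group
  unstructured (`p_within = p_between = 0.15` at pre-test) and lets
  structure emerge at group-specific rates, most strongly for the groups
  that practise mentally (combined and mental practice reach
  `p_within ≈ 0.8` post-test, physical practice 0.4–0.5, control ≤ 0.3,
  with `p_between` near 0.1). These values are chosen to emulate the
  qualitative finding such designs test — mental practice promotes concept
  formation — without fitting any published group means.
* **Putts** are bivariate normal with isotropic per-axis dispersion
  $\sigma_t = \sigma_{min} + (\sigma_0 - \sigma_{min})e^{-\kappa_g t}$ and
  bias $\mu_t = \mu_0 e^{-\rho_g t}$, where $t$ counts completed practice
  days (0 at pre-test, 3 at post- and retention-test: nothing decays over
  the retention interval itself). Defaults: $\sigma_0 = 35$ cm per axis
  (a novice putting to a 3 m target), floor $\sigma_{min} = 12$ cm, initial
  bias 15 cm of overshoot, and learning rates $\kappa$ = 0.45 (combined),
  0.40 (physical), 0.25 (mental), 0.08 (control, which learns a little from
  test-day putts alone), satisfying the predicted ordering
  CP ≥ PP ≥ MP ≥ NP. The exponential-with-floor curve is the simplest
  monotone improvement model. For isotropic Gaussian scatter the closed
  forms $E[MRE] = \sigma\sqrt{\pi/2}$ (zero bias) and population
  $BVE = \sigma\sqrt{2}$ anchor the metric tests.

What passing tests on these cohorts show is that the pipeline recovers
planted structure at realistic noise (mean ARI ≥ 0.9 against the planted
phase partition at `p_within = .9`, `p_between = .1`, 13 participants) and
reproduces the qualitative group ordering. What they do **not** show:
real splitting-task judgments are not independent across pairs (participants
are consistent within an anchor and drift over a session), real putt errors
are anisotropic (depth error usually exceeds lateral error) and
non-stationary within a block, and real learning curves differ between
individuals. No generator parameter was fitted to published group means;
figure-read values are treated as out of bounds as calibration targets.

## Problem sizes and determinism

The shipped test suite runs the brute-force cross-checks at the scale where
exhaustive oracles are exact and fast: ARI against pair counting on 500
random partition pairs ($n \le 10$), UPGMA against an $O(n^3)$ re-derivation
on 200 random matrices ($n \le 8$), Holm against prefix enumeration, planted
recovery over 50 replicate cohorts of 13 participants, and the Gaussian
closed forms at $k = 10^5$ draws. Every generator is a pure function of
(configuration, seed); `run_analysis()` plus `write_report()` is
byte-deterministic for fixed inputs, which the suite asserts on the JSON
report.

## Known limitations

* The invariance $\lambda$ is a substitute measure (see above); only its
  threshold semantics, boundary behaviour and symmetry are guaranteed to
  match the original.
* $d_{crit} = 3.41$ is taken as given for the 16-concept instrument; the
  package does not re-derive critical values for other $N$ or $\alpha$.
* SDA-M's factor-analytic step (dimensional analysis) is not implemented;
  the pipeline covers scaling, clustering and invariance/similarity
  comparison.
* The pairwise contrast helper uses Welch t-tests on the summary scores; it
  is a descriptive convenience, not a replacement for covariate-adjusted
  inference on real cohorts.
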