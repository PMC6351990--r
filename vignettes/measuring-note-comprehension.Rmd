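---
title: "Measuring EHR note comprehension with a fixed-guessing 3PL model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EHR note comprehension with a fixed-guessing 3PL model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comprehIRT)
```

## The measurement problem

Patients reading their own electronic health record (EHR) notes meet
medical jargon that general health-literacy screeners do not probe. A
targeted instrument asks multiple-choice questions about note snippets and
scores respondents on a latent comprehension trait, so that arms of a
randomized study — say a baseline with no reading aid, a passive reference
website, and an active tool that defines jargon in place — can be compared
on ability rather than only on percent correct. Ability is the more
informative score because it weights *which* items were solved, not just
how many.

comprehIRT implements this measurement chain: the item response model,
ability scoring, item calibration and bank filtering, a synthetic study
generator, and the downstream comparison statistics.

## The response model

Each dichotomous response follows a single-factor three-parameter logistic
(3PL) model,

$$p_i(\theta) \;=\; c_i + (1 - c_i)\,
\frac{1}{1 + e^{-a_i(\theta - b_i)}},$$

with discrimination $a_i > 0$ (units: logits per SD of the trait),
difficulty $b_i$ on the trait scale, and guessing floor $c_i \in [0, 1)$.
The trait $\theta$ is standardized: the calibration prior pins it to
N(0, 1), so $\theta = -1$ reads "one standard deviation below the average
respondent". A response pattern's likelihood is the product of $p_i$ or
$q_i = 1 - p_i$ over scored items; missing responses are excluded from the
product (ignorable missingness), never imputed.

**The guessing parameter is fixed, not estimated.** Four-option multiple
choice motivates the default $c = 0.25$; it is configurable per bank and
per calibration. One documented wrinkle: the familiar statement "a
respondent whose ability equals the item difficulty has a 50% chance of
answering correctly" is exact only at $c = 0$ (the 2PL reading); under a
3PL the probability at $\theta = b$ is $(1 + c)/2$. Both conventions are
supported — `probCorrect` simply evaluates whatever $c$ the bank carries —
and the discrepancy is documented rather than resolved, since the
instrument this design follows states difficulty semantics in the 2PL
reading while fitting with a fixed guessing parameter.

## Ability estimation

`estimateAbilityMLE` maximises the pattern log likelihood over a bounded
interval, default $[-4, 4]$ (±4 SD of a standard-normal trait), with
optimizer tolerance $10^{-6}$. The standard error is
$1/\sqrt{I(\hat\theta)}$ from *expected* (Fisher) information summed over
the scored items,
$I_i(\theta) = a_i^2 (q_i/p_i)\,\big((p_i - c_i)/(1 - c_i)\big)^2$; expected
rather than observed curvature is the stabler choice for short tests, and
whether the original analysis used one or the other is unknowable from the
published account, so the package commits to the expected form.

All-correct and all-incorrect patterns have no interior maximum. They are
flagged (`boundary_flag`) and handled by a configured fallback: by default
expected-a-posteriori (EAP) scoring under an N(0, 1) prior, which keeps
every respondent's estimate finite and comparable; clamping to the
interval endpoint is available instead. `estimateAbilityEAP` integrates on
an equally spaced quadrature grid spanning the prior mean ±4 SD with
normal-density weights — 61 nodes by default, which matches a 2000-point
Riemann-sum oracle to better than $10^{-3}$ in the test suite.

## Item calibration and bank filtering

`calibrateItems` fits $(a_i, b_i)$ for every item by marginal maximum
likelihood with the Bock–Aitkin EM scheme: the E-step computes each
respondent's posterior weights over 41 equally spaced N(0, 1) quadrature
nodes on $[-4, 4]$; the M-step maximises the expected complete-data log
likelihood per item by bounded quasi-Newton ascent with analytic
gradients (at most 50 inner iterations, bounds $a \in [0.01, 5]$,
$b \in [-5, 5]$ to keep quasi-degenerate items finite). Iteration stops
when the marginal log-likelihood gain drops below `tol` (default
$10^{-5}$); the trace is monotone non-decreasing up to $10^{-8}$ slack,
and that invariant is asserted by the result class itself. Because the
latent scale is pinned by the prior, recovered difficulties land on the
generating scale without post-hoc rescaling (the suite checks a
$b$-recovery regression slope in $[0.8, 1.2]$ at $n = 1000$).

Instrument construction histories of the form "a large authored bank, a
subset administered, a final short test retained" rarely publish the exact
retention rule. `filterItemBank` therefore applies transparent, fully
audited threshold rules — retain items with $\hat a \ge$ `a_min` (default
0.5), $|\hat b| \le$ `b_max` (default 3), and no degeneracy flag — as a
configurable surrogate; every removal records which rule fired. Items
answered identically by all respondents are flagged degenerate during
calibration rather than crashing the fit.

## What the synthetic generator emulates — and what it does not

`simulateStudy` reproduces the statistical structure of a three-arm
crowdsourced comprehension study:

- **Item bank**: 55 scored items; difficulties drawn from a normal
  truncated to $[-2.2, 0.7]$, centred at $-1.0$ with SD 0.8, so most items
  are easy — the profile of an instrument designed to be most informative
  at low ability; discriminations log-normal with median 1.2 (SD of log,
  0.25); guessing fixed at 0.25. All configurable.
- **Arms**: sizes 41/29/27 with latent ability means $-0.065$, $0.138$,
  $0.477$. Arm effects are modelled as shifts of the latent ability mean,
  matching the measurement model in which an aid manifests as higher
  estimated $\theta$ — not as item-level easiness changes. The within-arm
  SD is 1.0 by convention (the trait scale); no published value exists for
  it.
- **Demographics**: gender, age band, ethnicity, education and occupation
  are sampled independently from the study-wide category frequencies (53/97
  male, 71/97 White, and so on). Independence is the default; an optional
  `theta_shifts` hook adds category-specific latent shifts so that
  demographic-effect recovery can be exercised without asserting any
  particular published magnitude.
- **Quality control**: 3 attention-check items; each QC response is wrong
  independently with probability `careless_rate` (default 0.02 — small but
  nonzero so the removal path is always exercised). A respondent failing
  any check is removed, and the filter is idempotent.

Deliberate non-features: respondents are exchangeable within arm (no
worker-platform approval ratings, timing, or repeated participation);
demographics do not correlate with each other; responses are conditionally
independent given $\theta$ (no speededness, fatigue or local dependence);
and QC errors are independent per entry rather than clustered in careless
individuals. Passing tests on this generator therefore demonstrate that
the *pipeline* recovers what the model assumes — not that real crowdworker
data satisfy those assumptions.

## Comparison statistics

`compareArms` reports per-arm means, quartiles and Tukey box statistics
(whiskers at 1.5 interquartile ranges, outliers listed separately in the
min/max columns) for both raw scores and abilities, with Welch two-sample
t tests of each treatment arm against baseline. P values are per
comparison and unadjusted by default — matching the reporting convention
of small multi-arm studies with two planned contrasts — with Bonferroni
and Holm switches available. Identical constant scores across arms yield a
null comparison ($t = 0$, $p = 1$) rather than an error.

`fitScoreRegression` is ordinary least squares on dummy-coded arm and
demographic factors. Reference levels default to the baseline arm and the
largest categories (male, 22–34, White, bachelor's, non-medical
profession); categories absent from a cohort are dropped as empty levels,
variables constant in the cohort are dropped *with a recorded note*, and
genuine aliasing raises an error naming the terms. Demographic tables
round percentages half-up to integers (27 of 41 renders "27 (66)").

One reporting discrepancy is worth documenting for users comparing against
published three-arm results of this design: the same active-aid vs
baseline raw-score contrast has been printed as $P = .008$ in one place
and $P = .01$ in another within a single report; the package takes no side
and simply reports the computed value.

## Numerical choices and degenerate inputs

- Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the EM
  objective so saturated logistics cannot produce $\log 0$.
- `testInformation` marks SE as `NA` (not `Inf`) at grid points of zero
  information.
- Welch tests require two finite values per sample and nonzero pooled
  variance; `rawScores` rejects all-missing respondents by id; QC
  filtering without designated QC items is a configuration error, never a
  silent skip.
- Extreme-item reports break percent-correct ties by item id, so output
  is deterministic.
- All randomness flows from explicit integer seeds through R's
  Mersenne-Twister; `simulateStudy` derives its component seeds (bank,
  cohort, responses) from the run seed by fixed offsets, making studies
  byte-identical across reruns and platforms.

## Problem sizes used in validation

The test suite validates estimator quality at sizes chosen to make
Monte-Carlo noise negligible relative to the asserted tolerances while
keeping the default run quick: 1000 random 10-item patterns for the
MLE-vs-grid-search agreement (tolerance 0.002 against a 0.001-step grid);
500 respondents on the default 55-item bank for ability recovery
($r \ge 0.85$, mean bias within ±0.05); a 1000 × 20 matrix for
calibration recovery ($r_b \ge 0.9$); 10,000 null replicates at $n = 30$
per group for the Welch type-I error band [0.035, 0.065]; and 200
replicates of the full 97-respondent pipeline for the arm-ordering check
(active arm's mean estimated ability above baseline's in at least 90%).

## Known limitations

- The guessing floor is fixed, never estimated; banks whose items differ
  in effective guessing will absorb that misfit into $a$ and $b$.
- MLE ability on a deliberately easy bank is imprecise above the mean
  (little information at high $\theta$); the EAP fallback shrinks extreme
  patterns toward the prior mean, which is the intended behaviour but
  biases individual extreme scores toward zero.
- Calibration assumes unidimensionality and conditional independence;
  neither is tested for.
- The bank-filtering thresholds are a surrogate for an unpublished
  procedure; audited, but not a reconstruction.
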