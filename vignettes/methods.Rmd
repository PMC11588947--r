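---
title: "Scoring and inference for IRAP and FAST data: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and inference for IRAP and FAST data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irapfast)
```

## The measurement problem

Both tasks this package scores index a participant's learning history
through speed. The IRAP alternates blocks whose response rule is either
coherent or incoherent with the participant's history (here, a "Straight
woman" rule versus a "Lesbian woman" rule over nude male/female pictures
crossed with positive/negative words, giving four trial types); the
behavioural signature is the latency cost of responding against one's
history. The FAST teaches two key-press contingencies from feedback
alone, one block consistent with the participant's stimulus relations and
one inconsistent; the signature is the difference in how fast the two
contingencies are acquired. The KSOG provides the explicit self-report
anchor on a continuous 1–7 scale.

The package's job is the full path from trial logs to inference: scoring
rules with their exclusion criteria, a two-group comparison battery, ROC
analysis of how well each score separates the groups, and
power-sensitivity computations, exercised end to end by a calibrated
simulator.

## The D-score algorithm and its boundary semantics

Latency is defined once per trial as the time to the *correct* response
(error-correction time included), so accuracy enters scoring only through
the practice gate. The algorithm: discard practice latencies; drop test
latencies strictly above 10,000 ms; exclude participants with strictly
more than 10% of test trials under 300 ms; within each of the three test
block pairs and each trial type, divide the lesbian-minus-straight block
mean difference by the sample SD of the cell's latencies pooled over the
pair's two blocks; average over pairs, then over trial types.

Choices the task description leaves open, fixed here:

* **Sample (n−1) SD** in the denominator, the convention of the D-score
  family this statistic belongs to; with 12 latencies per cell the
  population-SD alternative would shift scores by a fixed factor of
  `sqrt(11/12)` ≈ 0.957, well inside between-participant noise.
* **Boundaries read literally**: "above 10,000 ms" excludes 10,001 and
  keeps 10,000; "more than 10%" keeps exactly 10%; "at least 80%"
  accuracy is inclusive; "less than 2000 ms" median is exclusive. The
  suite pins each of these.
* **Fast-responder denominator** is all test trials, before the
  10,000 ms filter. Both filter orders are asserted on fixtures: no
  fixture participant changes status under permutation, and the strict
  inequalities make real-data divergence implausible (it would need a
  participant within one trial of the 10% boundary who also emits >10 s
  latencies).
* **Even-length medians** are the mean of the two central order
  statistics (the standard convention).

Scoring errors (a cell with fewer than two retained latencies, or zero
pooled SD) are surfaced with the offending pair and trial type rather
than silently imputed, because they indicate an aborted or degenerate
session.

## FAST slopes

The cumulative record counts correct responses (timeouts are incorrect)
up to and including each trial; the score is the OLS slope of that count
on trial order, block difference taken as straight minus lesbian. The
slope of a unit-increment staircase is provably in [0, 1] and behaves as
a weighted share of correct responses, which makes 0.5 the
guessing-level anchor. Whether trial order is indexed from 0 or 1 is
immaterial (slopes are shift-invariant); the count convention
(right-closed) is fixed for determinism.

## The inference battery

* **Rank-sum test**: W is the Mann–Whitney count for the straight group
  (ties half-weighted), so the effect-size estimator r = W/(n₁n₂) is a
  probability of superiority and coincides with Vargha–Delaney
  A = (δ+1)/2 and with the ROC AUC under the controls > cases direction.
  This identity chain is asserted on shared inputs. The p value is exact
  by enumeration for combined n ≤ 25 without ties and otherwise uses the
  tie-corrected normal approximation with continuity correction,
  mirroring the common default of the statistical environment these
  analyses are usually run in.
* **Split-plot ANOVA**: the repeated-measures analysis of the four
  trial-type scores by orientation is computed as the classical
  two-stratum decomposition with Type III (sum-to-zero) sums of squares.
  For complete balanced-within data this coincides exactly with the
  REML random-intercept mixed model with Satterthwaite tests — the
  suite verifies F statistics and denominator df against `lmerTest` on
  unbalanced-group data — while remaining free of any optimiser.
  Incomplete data are rejected with a pointer to mixed models rather
  than approximated.
* **Contrasts**: within-group trial-type contrasts use the residual
  mean square with Tukey adjustment over the family of four; these
  match `emmeans` on the corresponding `lmer` fit. Between-group
  contrasts per trial type need both error strata; the package combines
  them with a Satterthwaite df. A Kenward–Roger df (as some software
  reports for this contrast, e.g. printed df near 147 at N = 48) is
  deliberately not replicated — the t statistics agree, the df
  convention differs, and the df difference is immaterial at these
  sizes.
* **ROC/DeLong**: AUC is the tie-corrected pair-count statistic
  (midrank implementation, so 10⁵-per-group inputs are fine); the curve
  is the threshold sweep with specificity running 1 → 0. DeLong
  variances use the structural-components estimator, checked against
  `pROC`, a bootstrap oracle, and the Hanley–McNeil approximation.
  Comparing curves built on *different* participant subsets (e.g. an
  IRAP score after exclusions against a FAST score without them) cannot
  be paired; the unpaired form divides by the summed variances and uses
  a Welch–Satterthwaite fractional df, which is why such comparisons
  print fractional degrees of freedom. The female-picture predictor
  needs no special casing in ROC construction: inverting the variable
  and swapping the case role compose to the identity, so the raw scores
  are used (the sign inversion of female-picture trial types exists
  only in the report layer).
* **Power sensitivity**: minimal detectable effects invert exact
  noncentral-t / noncentral-F power functions by root finding (achieved
  power within 10⁻⁴ of target). The within-between interaction uses the
  convention λ = f²·N·m·ε/(1−ρ) with df (G−1)(m−1)ε and (N−G)(m−1)ε and
  defaults ρ = 0.5, ε = 1 — the convention of widely used power
  software, and the one under which the printed sensitivity pair
  (f = 0.17, partial η² = 0.028 at N = 48, 2 × 4) is reproduced. Other
  printed effect-size equivalences (a Cohen's *d* attributed to the
  interaction f, and a *d* quoted for the rank-sum comparison at
  33/25) are not reproducible from any convention we could identify and
  are intentionally not implemented.

## What the simulator emulates — and what it does not

`generate_cohort()` draws a full cohort: 33 straight and 25 lesbian
participants; up to three IRAP practice pair attempts with a per-pair
failure probability (0.557 by default, putting the expected count of
never-passing participants near 10 of 58); exactly three test pairs of
2 × 24 trials with trial types randomized six per block; one 16-trial
FAST practice block and two 50-trial test blocks in random order; and
21-cell KSOG grids with four lesbian grids lost, so the three measures
carry the denominators 48/58/54 on average.

Latencies are log-normal with a participant random intercept and a
per-trial-type log-latency increment applied in the participant's
history-incoherent block (the lesbian-rule block for straight
participants and vice versa); the D score's scale and shift invariance
makes the base scale arbitrary. FAST accuracy rises from a floor to a
ceiling as P(correct at t) = p∞ − (p∞ − p₀)·exp(−κt) with κ specific to
orientation × block and jittered log-normally across participants;
timeouts are drawn independently and force an error.

Defaults were calibrated once, by moment matching against the published
group summaries (averaged D 0.10 (SD 0.29) vs −0.43 (0.35); FAST slope
differences 0.02 (0.15) vs −0.20 (0.17); lesbian block slopes
0.633/0.430; the trial-type mean profile), and then frozen in
`inst/extdata/default_config.yaml`. The calibration measured the linear
gain from log-latency increments to mean D (≈2.13 for the straight
group, ≈1.92 for the lesbian group at the default residual SD), set the
increments to target-means/gain, chose per-orientation effect SDs to
close the gap between sampling noise and the published between-person
SDs, and inverted the expected OLS slope function for the κ values.
Because different group SDs are printed, the participant-level effect
SD is per orientation — a deliberate extension of the otherwise shared
parameterisation.

The simulator reproduces the *statistical structure* the analysis
assumes, not the behaviour-generating process: no stimulus-identity
effects, no sequential dependencies or fatigue, no relation between a
participant's practice performance and her test-phase latencies
(practice failure is a Bernoulli gate, because the gate logic itself is
tested against explicitly constructed accuracy patterns), and KSOG
ratings are a rounded latent draw rather than item-level psychology.
Passing calibration tests therefore shows that the pipeline recovers
known inputs under the study's conditions — it does not validate the
tasks themselves, and real data will show heavier tails, drift, and
item effects the generator omits.

One published KSOG descriptive (a heterosexual-group minimum of 0.570)
lies below the scale floor of 1; no transformation producing sub-1
scores is documented, so the scorer enforces [1, 7] and the discrepancy
is simply noted here rather than guessed at.

## Problem sizes and numerical tolerances

Stochastic checks are sized to keep the whole suite around a minute on
one CPU while leaving Monte-Carlo error well inside the asserted bands:
2000 replicates for the null false-positive band [0.035, 0.065] and for
bootstrap/power-recovery comparisons, 20 seeds for generator
calibration, 10⁵ draws per group for the binormal AUC check (±0.01).
Deterministic oracles (pair enumeration, explicit-mean ANOVA
decompositions, closed-form OLS) are asserted at 10⁻¹⁰–10⁻¹²;
root-finding inversions at 10⁻⁴ of the grid oracle. Exact worked values
are asserted at the precision they are printed with (e.g. A = 0.746
from δ = 0.493, whose exact value 0.7465 rounds either way). The
rank-sum r for W = 682 at 33/25 is 0.82667, printed as 0.826 in the
source table — agreement is asserted at printed precision rather than
digit-exact rounding.

## Known limitations

* The split-plot route requires complete data; cohorts with missing
  trial-type cells need a true mixed model (out of scope by design).
* Between-group contrast df use the Satterthwaite two-stratum
  combination, not Kenward–Roger.
* The exact rank-sum enumeration threshold (combined n = 25) is a
  convention, not an optimum; at the study's sizes the approximation is
  always in force.
* The generator's defaults encode one published cohort; transfer to
  other populations is a calibration exercise, not a given.
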