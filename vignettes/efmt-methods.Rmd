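---
title: "Adaptive cognitive-emotional training and in-silico trial methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cognitive-emotional training and in-silico trial methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmt)
```

## Overview

`efmt` implements an adaptive dual N-back training task for
cognitive-emotional remediation in major depressive disorder, together with
everything needed to exercise a two-arm randomized controlled trial of that
task entirely in silico: simulated trainees and clinical trajectories,
permuted-block randomization, protocol adherence and discontinuation rules,
and the trial's statistical analysis suite (MMRM with weekly least-squares
mean contrasts, an LOCF sensitivity model, responder, dose-response, and
symptom-item analyses).

The package has two kinds of consumers in mind: methodologists who want a
concrete, testable implementation of this class of digital-therapeutic
trial, and statisticians who want a sandbox in which every stage of the
analysis can be validated against known ground truth before any real data
exist.

## The training task

Stimuli are presented for 1 s each, followed by a 1 s fixation cross. In the
active task each stimulus is a face labelled with one of six emotions
(happy, sad, angry, fearful, surprised, neutral); in the control task it is
one of six neutral shapes. After each stimulus the trainee judges whether
its category matches the one N positions earlier. The two variants are
deliberately identical in everything except the label set — the package
even consumes the random-number stream identically in both — so any
difference in simulated outcomes is attributable to the clinical model, not
the engine.

A session consists of 15 blocks. Each block presents
`n_scored_items + n_level` items: the first `n_level` items are unscorable
lead-in. Targets (label matches at lag N) are placed at an exact count,
`round(target_rate * n_scored_items)`; lures (label matches at lag N±1 but
not N) likewise. Remaining scored items receive labels differing from all
three comparison lags, so the target/lure bookkeeping is exact by
construction; the tests verify this with an independent re-scan of every
emitted sequence.

Difficulty adapts between blocks: accuracy at or above `up_threshold`
raises N by one, at or below `down_threshold` lowers it by one, always
clamped to `[n_min, n_max]`. The first session of a regimen starts at
N = 1; later sessions start at the level carried over from the previous
session (by default the level earned after its final block).

Defaults that the original task description leaves open, chosen once and
exposed as configuration:

| parameter | default | rationale |
|---|---|---|
| scored items per block | 15 | keeps a 15-block session at 2 s/item inside a 20–35 min envelope |
| target rate | 1/3 | common N-back construction |
| lure rate | 0.2 | forces lag-specific memory |
| up/down thresholds | 0.85 / 0.60 | standard adaptive N-back practice |
| carryover rule | last earned level | simplest performance-determined rule |
| N bounds | 1..15 | structural (N cannot exceed scored items) |

Omitted responses are scored as incorrect; on a non-target they are tallied
in the false-alarm bucket so the four counts always sum to the number of
scored items.

## Simulated trainees

A trainee is a psychometric observer whose probability of a correct
match/non-match judgment declines logistically in the load N:

$$\mathrm{acc}(n) = (1-b)\left[\tfrac12 + (\tfrac12-\lambda)\,
\mathrm{logit}^{-1}\!\big(s(\kappa - n)\big)\right]$$

with capacity $\kappa$ (the load at 75% accuracy when $\lambda = b = 0$),
slope $s$, lapse $\lambda$, and an optional additional error rate $b$ on
emotional stimuli. The floor is chance (0.5) on the two-alternative
judgment. Under the default thresholds the staircase settles so that the
long-run mean block level lies within one unit of $\kappa$ — a property the
suite checks at several capacities.

For whole-trial simulation a fast path draws each block's accuracy directly
from the binomial at $\mathrm{acc}(n)$, reproducing the staircase dynamics
without item-level bookkeeping. Per-arm capacity distributions default to
N(3.4, 1.7²) for the active arm and N(4.4, 2.0²) for the control arm,
matching the reported achieved mean-N summaries of the trial this design
replicates; the achieved mean N sits slightly below capacity because every
session restarts its climb from the carried-over level.

## Clinical trajectories

Weekly Ham-D totals over weeks 0..6 are multivariate normal around per-arm
weekly means with a full 7×7 residual covariance, then rounded and clamped
to the instrument range (0–52). Defaults:

* The active arm declines linearly from 19.25 at baseline to 10.60 at week
  6 (the anchor means of the trial being emulated). Weekly per-arm means
  are not published, only weekly between-arm differences; linear
  interpolation of the active arm is therefore a modelling choice, flagged
  here, and the control arm is defined as the active mean plus the
  published weekly difference profile. That pins the expected week-6
  contrast at 3.8681 Ham-D points — the value the recovery experiments
  target. It also implies a control week-6 mean of 14.47 rather than the
  published raw mean 14.71; the two cannot both hold because published
  least-squares and raw means differ.
* Residual covariance is compound-symmetric with SD 4.9 and correlation
  0.5 (the correlation the original power analysis assumed), stored as a
  dense unstructured matrix so nothing downstream can exploit the
  structure. Any positive semi-definite matrix may be substituted.
* The week-0 residual is pinned to the participant's screened baseline
  (drawn from the arm's truncated normal within the eligibility window
  16–27) and weeks 1..6 are drawn from the multivariate-normal
  conditional. Screening truncation therefore propagates into follow-up
  exactly as eligibility screening does in practice; it raises the
  realized baseline mean about 0.4 points above the configured center and
  follow-up means by about half that (through the 0.5 correlation), which
  is why Monte-Carlo mean checks use a 0.5-point band.
* A dose term adds `dose_effect` Ham-D points per completed session to the
  active arm, centered on expected attendance so arm means are unchanged;
  the default −0.6 induces a sessions-versus-response correlation near
  −0.5, the size reported for the trial. Setting it to 0 removes the dose
  channel entirely (and under full attendance the centered term is zero
  regardless).

Item-level scores allocate each total over the 17 Hamilton items
(nine 0–4 items, eight 0–2 items, instrument convention) proportionally to
a weight profile with stochastic rounding, under the per-item caps, so
items always re-sum to the total. BDI-II is a noisy linear transform of the
Ham-D total with per-arm coefficients solved from the published
baseline/outcome anchor pairs. The working-memory composite is the mean
scaled score of the three subtests.

Adherence: each of 6 training weeks schedules 3 sessions; attendance is
per-session Bernoulli with probability 0.87, chosen once against the
published adherence facts (it yields ≈5% week-1 discontinuation versus
the reported 3/51, m-ITT mean sessions ≈14.5 versus the reported
14.46/14.91, and ≈30% overall discontinuation versus ≈27%). The protocol
rule discontinues a participant in the first week with fewer than two
sessions, or once more than three sessions have been missed cumulatively;
the implementation is verified against a brute-force re-application of the
rule.

What the generator does *not* emulate: real MDD pathophysiology, rater
behavior and drift, non-random (outcome-dependent) dropout, site effects,
or any link between task engagement and symptom change beyond the single
linear dose term. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under the stated generative model —
not that the clinical effect itself would replicate.

## Randomization and trial assembly

Treatment allocation uses permuted blocks of six (3:3 within every complete
block; a final partial block is the leading portion of a freshly permuted
balanced block), reproducing the protocol's blocking. The protocol
additionally describes balancing on expected regimen completion; no
algorithm is given for it, so the package deliberately does not guess one —
arm totals at n = 51 therefore differ by at most 3 rather than the
published 28/23 split.

The pipeline randomizes, draws profiles, simulates adherence, trajectories
and task performance, and truncates each participant's visit rows at any
discontinuation week (the discontinuation week itself carries session
counts but no assessment, matching a protocol in which discontinuation
precedes that week's rating). Everyone randomized is ITT; m-ITT
additionally requires a completed first week of training and at least one
post-baseline assessment. The week-6 visit is taken as the outcome
assessment. Schema invariants (no post-discontinuation rows, monotone
cumulative sessions, items re-summing to totals) are enforced by a
validator, and a fixed seed makes the whole dataset byte-identical across
runs.

## The analysis suite

**Primary MMRM.** Ham-D totals are modelled with arm, categorical week,
and their interaction as fixed effects and an unstructured within-subject
covariance, fitted by REML on observed data (no imputation). Two engines
agree on complete data: a closed-form solution (cell means are arm-by-week
sample means; covariance is the pooled residual cross-product over N − 2),
and `nlme::gls` with `corSymm` correlation plus per-week variance weights,
used whenever visits are missing. A failed unstructured fit is restarted
from a compound-symmetry estimate. The suite additionally checks both
engines against a generic GLS matrix-algebra oracle written independently
in the test helpers.

Weekly least-squares-mean contrasts are reported as control minus active
(so positive values favor the active arm, matching the published table's
sign convention) with t tests at residual degrees of freedom (observations
minus fixed-effect parameters — the convention that reproduces the
published df of 205 given that trial's missingness pattern: 219 observed
visits minus 14 parameters). For the overall group-by-time test the
complete-data engine uses the exact Hotelling $T^2 \to F(q,\,\nu-q+1)$
mapping ($\nu = N - 2$): at pilot-trial sizes the large-sample Wald F with
residual df rejects well above its nominal level, whereas the Hotelling
form is exact under normality; the null-calibration experiments check that
the test's simulated size stays inside [0.03, 0.07]. On the incomplete-data path the interaction test is a
Wald F with residual df, and the method used is always named in the output.

**Sensitivity and secondary analyses.** The LOCF sensitivity model is a
change-score ANCOVA on the m-ITT LOCF dataset — change from baseline to
week 6 regressed on arm, baseline Ham-D, and sessions completed. Its arm F
carries (1, n − 4) degrees of freedom, which reproduces the published
(1, 44) at n = 48; this correspondence is why the change-score form was
adopted. The 17 item-level tests are the analogous change-score F at
(1, n − 2) per item — matching the published (1, 46) — with deliberately
uncorrected p values and an explicit no-correction marker in the output.
Responders are participants with at least a 50% Ham-D reduction (boundary
inclusive) at the week-6/LOCF value. Summary-statistic utilities
(pooled-variance t, correlation-to-p, Cohen's d) exist because the
published secondary results are given only as summaries; all are verified
against definitional oracles and `stats` reference implementations on raw
data. The formula behind the published standardized effect sizes (d =
0.46/0.23/0.30) is not stated in the source material, so `cohens_d_from_summary`
offers the two standard pooled variants and nothing depends on reproducing
those printed values.

## Numerical and design choices

* Ham-D totals are integers: rounding noise (variance 1/12) and the floor
  at zero are part of the generative model; at the default means the floor
  affects under 2% of week-6 active-arm draws.
* Residual covariance matrices are accepted when positive semi-definite,
  so exact zero-noise configurations (used by identifiability tests) are
  representable.
* Degenerate single-label stimulus sets are allowed only behind an
  explicit `allow_degenerate` flag; they exist to force all-target blocks
  in tests and demonstrations.
* Modal carryover breaks ties toward the higher level; an incomplete
  session falls back to N = 1 with a logged message.
* Sequence construction retries (up to 100 draws) when lure constraints
  collide with earlier labels; with the default six-category sets
  collisions are rare, and a category set smaller than 3 is rejected
  outright.

## Problem sizes used by the simulation experiments

The recovery experiment runs 500 replicate trials of 200 participants per
arm with full attendance, totals only, and a zero dose term, and demands
bias under 0.15 Ham-D points with 93–97% CI coverage for the configured
week-6 contrast. Null-calibration experiments run 500 replicates at the
study's own size (n = 51): complete data for the primary test (isolating
its calibration from missingness) and default adherence for the LOCF
model. These sizes give Monte-Carlo standard errors of about 0.01 on a
rejection rate and about 0.02 on the recovered contrast, proportionate to
the bands being checked.

## Known limitations

* The completer-balancing component of the original randomization scheme
  is unspecified and not implemented.
* The trajectory model is arm-mean plus dose plus Gaussian noise; it
  cannot produce outcome-dependent dropout, and the week-0 variance
  (screening-truncated, SD ≈ 2.3) is smaller than the follow-up residual
  SD, unlike the published table where baseline and follow-up standard
  errors are similar.
* The gls engine's interaction test uses residual df and will be
  anticonservative on small incomplete datasets; the exact Hotelling form
  is only available for complete data.
* Likert acceptability items are not simulated; the summary t utilities
  cover that published pathway from reported summaries.
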