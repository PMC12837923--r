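---
title: "Methods: agreement, Bayes factors and ordinal performance patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, Bayes factors and ordinal performance patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catpattern)
```

## The analysis problem

Studies that compare human and machine object recognition typically
collect one label per trial from each observer: an image from a known
category is flashed briefly (e.g. 50 ms, followed by a mask) and the
observer — a person or a fine-tuned network — picks one of N category
labels, or types a free answer. Three questions recur:

1. **How accurate is each rater**, per category and condition?
2. **Do two raters make the same trial-by-trial decisions**, beyond
   what their accuracies force? (Two raters at 85% can agree on almost
   every image or on rather few.)
3. **Does a model reproduce the *shape* of an individual's performance
   across categories**, not merely its mean?

`catpattern` answers these with accuracy aggregation, chance-corrected
agreement, default Bayes-factor t tests, and an ordinal-discretisation
framework, all driven either by real response tables (CSV) or by a
synthetic cohort generator with known ground truth.

## Chance-corrected agreement

For two aligned label sequences the package computes unweighted
Cohen's kappa, \(\kappa = (p_o - p_e)/(1 - p_e)\), over the union of
the labels either rater used; in free-naming data the `UNKNOWN` code
(an answer outside the category set) participates as a category of its
own, which keeps \(\kappa\) well defined when a model's closed
vocabulary meets an open human vocabulary. The standard error is the
classical large-sample estimator for unweighted kappa (the
Fleiss–Cohen–Everitt form), with Wald intervals clamped to
\([-1, 1]\); the estimator used is recorded in the result object.
Qualitative wording follows the Landis–Koch bands (≤ 0 none, then
slight, fair, moderate, substantial, almost perfect in steps of 0.2).

Two degenerate cases are resolved by explicit convention, since the
formula is 0/0 or trivial there: two constant raters using the same
label give \(\kappa = 1\); any other constant-rater configuration is
computed as usual but flagged `degenerate`.

Cohort summaries are emitted both ways where the aggregation is
genuinely ambiguous: the median of pairwise kappas *and* a pooled
kappa over all pairs' concatenated trials, since the two can differ
and different studies report either.

## Default Bayes-factor t tests

Accuracy comparisons use the Jeffreys–Zellner–Siow Bayes factor: under
H1 the standardised effect \(\delta\) has a Cauchy(0, r) prior
(equivalently \(\delta \mid g \sim N(0, g r^2)\) with \(g\)
inverse-chi-squared), under H0 \(\delta = 0\). The default
\(r = \sqrt{2}/2 \approx 0.707\) is the conventional "medium" scale of
this test family. BF₁₀ depends on the data only through t, the degrees
of freedom and the effective sample size (\(n\) paired;
\(n_1 n_2/(n_1+n_2)\) two-sample).

Numerically, the one-dimensional g-integral is evaluated by adaptive
quadrature after mapping \(g = u/(1-u)\) onto the unit interval, with
the integrand shifted by its log-scale maximum before exponentiation so
large |t| cannot overflow; the quadrature tolerance is 1e-10. The test
suite checks the result against an independent fine-grid Simpson
quadrature over the *effect-size* variable (noncentral-t likelihood ×
Cauchy prior — a different integration variable entirely) to 1e-6
relative, along with strict monotonicity in |t| and scale invariance.

Evidence wording uses the BF > 3/10/100 star convention and
Jeffreys-style grades symmetric around 1 (e.g. BF = 0.23 is moderate
evidence for the null, BF = 0.46 anecdotal).

Human-vs-model comparisons are exposed in two variants, because a
deterministic network can defensibly be treated either as a known
constant (one-sample test on participant accuracies minus the model's
accuracy — the default) or as a second sample (its per-category
accuracies). The output records which variant produced each row.
Multi-way Bayesian ANOVA (condition × category interactions) is a
non-goal; the pipeline substitutes per-category tests and says so in
its reports.

## Ordinal discretisation

Each rater's per-category accuracy vector is reduced to pairwise
qualitative relations: for categories i before j in the configured
order, the cell is `=` when the pair falls inside the equivalence
band, otherwise `>` or `<` by the sign of \(p_i - p_j\). Equivalence
is decided *before* sign — a pair inside the band is `=` even when the
difference is nonzero. Two criteria are available:

- **threshold** (default): \(|p_i - p_j| \le \tau\), with
  \(\tau = 0.1\) — 3 images out of 30 — as the default. A non-trivial
  band is essential: with a strict criterion virtually no two
  empirical proportions are ever equal, while very wide bands collapse
  everything to all-equivalent (the package's monotone-coarsening
  property). τ is a first-class knob and every report records it.
- **ci_overlap**: the two Wilson score intervals overlap. Wilson
  rather than Wald because per-category accuracies in this domain sit
  near 1, where Wald intervals misbehave.

The k(k−1)/2 cells in fixed row-major pair order form the pattern's
string signature; signatures are compared only within one configured
category order and are deliberately *not* canonicalised under category
permutation (the order is part of the instrument). Frequency tables
rank signatures by count with lexicographic tie-break; modal-pattern
queries return all tied signatures; cross-session consistency is the
share of participants with identical test and retest signatures; and
model matching reports exact identity with the modal human signature,
the fraction of agreeing cells, and the model signature's rank in the
human frequency table.

### Estimation noise and pattern recovery

A point that shapes both the tests and the interpretation of real
data: with 30 trials per category, the per-category proportion has a
standard error around 0.065 at p ≈ 0.85, so the *difference* of two
such proportions fluctuates by ±0.09. Against a τ = 0.1 band, a rater
whose true profile is perfectly flat shows an all-`=` observed pattern
with probability only ≈ 0.07 (an exact binomial-range computation),
and almost never keeps the same 36-cell observed signature across two
sessions. Observed-count pattern statistics at this trial count are
therefore dominated by estimation noise rather than by true profile
structure.

The package consequently validates pattern recovery at the level the
generator controls: `generate_cohort()` attaches each participant's
exact per-session accuracy profile as ground truth, the recovery tests
discretise those planted profiles, and modal share and session
consistency are then recovered within binomial sampling error of the
planted subgroup weight and stability. A separate check confirms that
observed-count discretisation converges to the same answer once trials
per category are large (600 trials/category in the test suite, where
the noise sits ≈ 5 standard errors inside the band). Reports on real
30-trial data should treat per-individual observed patterns as noisy
measurements — or use the wider `ci_overlap` criterion, which adapts
the band to the trial count.

## The synthetic cohort generator

The generator emulates the input structure of a large two-session
online study: 398 participants, nine object categories at three
difficulty levels (difficult: Plate, Vase, Basket; moderate: TV,
Helmet, Mug; easy: Banana, Match, Plunger), 30 images per category,
each image presented once per session at 50 ms, in six equally sized
blocks per session, with trial order re-randomised per participant and
session. Two-duration counterbalanced schedules (e.g. 10 categories ×
60 images × two durations in eight blocks of 150, category–duration
binding reversed between halves) are available for carryover analyses.

Participants belong to latent subgroups, each with a per-category
accuracy profile. The defaults place 65% of the cohort in a flat
subgroup at 0.87 (the cohort's observed mean accuracy then lands near
0.85) and the rest in minority subgroups whose dips echo the error
structure such studies report: helmet-specific confusions, difficulty
with plates and vases, texture-driven observers strong only on easy
categories, and generally weak observers. Wrong answers are drawn from
a per-category confusion kernel (uniform over the other labels by
default, configurable, with an optional `UNKNOWN` column for
free-naming cohorts). At retest a participant keeps their profile with
probability `session_stability` (default 0.6, matching the share of
individuals such studies find pattern-consistent) or has it redrawn
with Gaussian jitter on the logit scale (default SD 1.0, i.e. typical
accuracy shifts of 10–20 points — an "inconsistent" participant is one
whose profile genuinely changed; the logit scale keeps probabilities
inside (0,1) without truncation artefacts). An optional
`second_exposure_boost` adds accuracy when a stimulus is seen the
second time within a session, for planting carryover effects.

Reproducibility: one master seed spawns per-participant substreams via
a stable string hash of the rater id, so generation is a pure function
of the spec — the same seed yields byte-identical tables, including
under any future parallelisation of the participant loop.

What the generator does **not** emulate, and what passing tests
therefore do not show about real data: there is no item-level
difficulty (every image within a category is exchangeable), so
intra-rater reliability tops out around κ ≈ 0.7 at these accuracy
levels, whereas real observers — who find the *same* images hard twice
— can exceed it; trials are independent (no attention lapses, fatigue
or sequential effects beyond the optional exposure boost); free-naming
vocabulary effects are reduced to an `UNKNOWN` mass; and model raters
are stationary stochastic profiles, not actual networks.

## Numerical and design choices

- Proportions are exact ratios of integer counts; nothing is rounded
  before downstream use.
- Category labels are matched case-insensitively after trimming and
  stored canonically as spelled in the configured category set;
  free-naming answers resolve exact-match first, then synonym map,
  then `UNKNOWN`, making the coding function total, deterministic and
  idempotent on coded labels.
- In first/second-exposure splitting, a stimulus seen only once goes
  to the first set (partial data must not crash the carryover check);
  three exposures are an integrity error.
- Kappa CIs are Wald on the large-sample SE, clamped to [−1, 1];
  per-participant reliability CIs use the same estimator.
- Block dealing guarantees block sizes within one trial of each other
  for any category/image/block combination.
- The pipeline uses only test-session human data for human–model
  comparisons; the retest session feeds reliability and pattern
  consistency alone.
- Problem sizes in the test suite: the kappa oracle runs 10,000 random
  sequence pairs (lengths 2–50, up to 10 labels) at 1e-12; the
  discretisation invariants 10,000 fuzzed vectors; carryover behaviour
  200 replicates per arm at 25 raters on the full 1200-trial
  two-duration design; recovery checks use the full 398-participant
  cohort.

## Known limitations

- The equivalence band is an instrument setting, not an estimate; τ
  defaults to 0.1 but real analyses should report sensitivity in τ (or
  use `ci_overlap`).
- Weighted kappa, multi-rater kappa (Fleiss) and Krippendorff's alpha
  are out of scope, as are posterior effect-size estimates and
  model-averaged ANOVA Bayes factors.
- Observed-count pattern statistics at 30 trials/category are noise
  dominated (see above); the package reports them as computed and
  leaves the interpretation to the analyst.
- Reaction times, image content and perceptual mechanism are outside
  the data model; stimuli are opaque identifiers.
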