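---
title: "Mapping semantic spaces from triadic and pairwise word judgements"
author: "semspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping semantic spaces from triadic and pairwise word judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semspace)
```

## The problem

Degenerative semantic disorders — the semantic variant of primary
progressive aphasia (PPA SV) being the clearest case — do not simply delete
words from the mental lexicon; they distort the *structure* of the semantic
space in which word meanings live. This package implements a complete
analysis chain for probing that structure with two forced-choice paradigms
over a common word set:

* an **odd-one-out triad task** (three words; pick the most similar pair,
  implicitly marking the third word odd), analysed with a Bayesian
  multidimensional scaling (MDS) model, and
* two **pairwise judgement tasks** (pick the more concrete/abstract or the
  more positive/negative word), analysed as relative scales with rank
  agreement and configuration-matching statistics.

Because the behavioural data that motivated this design are not publicly
deposited, the package treats the *synthetic cohort generator* as a
first-class module: every downstream statistic can be exercised, and its
recovery properties demonstrated, on simulated control-like and
patient-like responders whose ground truth is known.

## The stimulus model

Words carry nine psycholinguistic norms: concreteness (1–5), valence,
arousal and dominance (1–7), age of acquisition (years), log10 word
frequency, orthographic neighbourhood density, length in letters, and
prevalence (fraction of the population knowing the word). The stimulus
inclusion rules define a 2 x 2 quadrant design:

* concreteness in [1.5, 2.5] = abstract, [4, 5] = concrete; mid-scale words
  are excluded (their ratings are unstable);
* valence in [2, 4) = negative, (4, 6] = positive. Valence exactly 4.0 lies
  on the boundary of both printed intervals, so `classify_word()` excludes
  it rather than guessing a pole;
* words with log10 frequency < 1 or prevalence < 0.98 are excluded.

`synthesize_word_set()` draws 8 words per quadrant (32 in total, the
default). Concreteness and valence come from per-class normal distributions
with the configured class means and SDs (the defaults reproduce the
statistics of a well-matched quadrant stimulus set); draws are
rejected until the word passes its intended classification. All other
features are sampled from class-independent truncated normals at the pooled
means, so the classes are matched on them *by construction*; neighbourhood
density and length are rounded to nonnegative integers, prevalence is
clamped to [0.98, 1]. `check_matching()` verifies the design with one-way
ANOVAs per feature: concreteness and valence must differ strongly across
classes, the nuisance features should not (individual nuisance features
will still cross p < 0.05 at the nominal false-positive rate).

Word identities are opaque labels (`w01`…`w32`); the package does not model
real Dutch words or query norm databases.

## Experimental designs

`build_triad_design()` produces 192 presented trials of which 24 are exact
repeats of earlier triads (168 unique triples), with every word presented
exactly 18 times (3 x 192 / 32) and no unordered pair contained in more
than 6 distinct triads. Two printed totals ("192 trials" and "24 repeated")
can only be reconciled by counting the repeats inside the 192, and only the
presented-trial count can be word-balanced (504 unique-triad slots do not
divide by 32, 576 presented slots do); the builder therefore chooses the 24
duplicated triads so that they exactly absorb each word's balance deficit.
Construction is randomized: balanced sampling that prefers unseen pairs,
then a budgeted hill-climb replacing triads containing pairs that occur in
only one triad (a count the design should keep small, since a pair seen
once is judged in a single, arbitrary context). The hill-climb is a local
search with a stall cut-off; it typically leaves a small two-digit number
of singleton pairs rather than the global optimum. All constraints are
re-checkable with `design_stats()`, and the builder's output always passes
its own validator.

`build_pair_design()` selects 256 unique pairs — 64 within-quadrant (16 per
quadrant), 128 sharing exactly one of valence/concreteness (32 per
quadrant-pair), 64 sharing neither — via random regular graphs (a 4-regular
graph within each quadrant; 4 disjoint random matchings, i.e. a random
Latin rectangle, between quadrants), which makes every word a member of
exactly 16 unique pairs. Each pair appears twice per task with opposite
instructions, scheduled into 16 blocks that never repeat a pair and never
show a word more than 5 times, by randomized first-fit with restarts.
`randomize_presentation()` yields per-participant orders: a full shuffle
with duplicates kept non-adjacent to their originals (triads), or shuffled
block order and within-block order (pairs).

## The synthetic cohort

`make_latent_config()` builds each group's true 2D semantic configuration
as a linear map of the z-scored norms plus Gaussian noise, min–max rescaled
to the unit square (the support of the inference prior):

* `control_like`: dim1 = 0.7·concreteness + 0.6·valence; dim2 =
  0.7·dominance − 0.5·arousal; noise SD 0.3;
* `sv_like`: dim1 = −0.9·valence; dim2 = 0.6·valence; same noise.

The signs and sparsity mirror the qualitative group contrast the analysis
is meant to detect (a concreteness-plus-affect plane in controls, a
valence-only organization in patients) without committing to particular
effect magnitudes. Note a geometric consequence: the sv-like weight
matrix is rank-1, so the patient-like configuration is a noisy *line*. Its
posterior fits are therefore *more* clustered than the control ones under a
2D uniform null (lower spatial-randomness ratio), whereas severely impaired
human responders push the posterior toward the uniform prior (ratio rising
toward 1). The generator reproduces the regression signature of the group
contrast faithfully, but not the direction of the randomness shift
observed in patients; the group *difference* in randomness distributions remains large and
is what the test suite asserts.

Responders are stochastic:

* triads follow the model's own choice rule — P(odd = X) proportional to
  exp(−delta · d(Y, Z)) with Minkowski distances — with per-participant
  determinism `delta` drawn log-normally (control median 3, sv median 1.5,
  so patient-like responses are noisier) and a lapse probability of a
  uniform guess (2% controls, 5% sv);
* pairwise choices use a logistic comparator on the z-scored task attribute
  with slope `kappa` ("concrete" and "positive" poles positive, their
  opposites sign-flipped); the sv preset sets the concreteness slope far
  below the valence slope (0.3 vs 2). The pairwise response model is a
  package convention: only the triad task has a model-implied rule, and the
  logistic form is the standard psychophysical choice.

`simulate_cohort()` defaults to 77 control-like and 10 sv-like
participants, cohort sizes typical of a single-centre patient study, and
returns the ground truth for recovery tests.

## The Bayesian MDS model

For words at latent positions $x_1, \dots, x_n \in [0,1]^2$ and a
participant with determinism $\delta > 0$, the probability that word $C$ is
the odd one out of $\{A, B, C\}$ is

$$P(\text{odd}=C) = \frac{e^{-\delta\, d(x_A, x_B)}}
{e^{-\delta\, d(x_B, x_C)} + e^{-\delta\, d(x_A, x_C)} +
 e^{-\delta\, d(x_A, x_B)}},$$

with $d$ the Minkowski-$r$ distance ($r = 2$ by default; the exponent is a
config knob because the model family is stated for general Minkowski
metrics). The prior is uniform on the unit square for every coordinate —
the square is the conventional bounded support for this model family — and
Gamma(2, 1) for each participant's $\delta$ (neither choice is forced by
the model family; both are exposed in `bmds_config()`). Pooled fits share one configuration across participants
with one $\delta$ each.

`bmds()` samples the joint posterior by random-walk Metropolis-within-Gibbs
over per-word coordinate blocks and per-participant $\delta$ (log-scale
proposals), with step sizes adapted toward ~30% acceptance during warmup
only. Defaults are 2,000 warmup and 5,000 kept iterations thinned to **50
retained draws** — the number of posterior samples all downstream
distributional summaries use. Gradient-based samplers would be overkill at
64 free coordinates, and a plain Metropolis scheme keeps fits exactly
reproducible from a seed. The hot likelihood loop is C++.

Two numerical points deserve care:

* **Identifiability.** The likelihood is invariant to translations,
  rotations and reflections of the configuration. Convergence is therefore
  diagnosed on pairwise-distance summaries (split-chain statistic on the
  mean pairwise distance), never on raw coordinates, and retained samples
  are aligned before any coordinate-level summary. `align_samples()`
  applies the rigid (no-scaling) Procrustes transform to an iterated mean
  template, or to an explicit reference configuration. In the synthetic
  studies here, fits are aligned to the generator's ground truth — the
  standard recovery-study convention, which resolves the residual symmetry
  of the square prior (its 8 symmetries can swap or flip dimensions, which
  would otherwise scramble which "dimension 1" a regression sees). For real
  data, the mean-template alignment leaves an arbitrary but internally
  consistent orientation.
* **Degenerate inputs.** Zero trials are legal (the sampler then reproduces
  the prior — a property the tests exploit); coincident coordinates are
  legal (distance 0); responses naming a word outside its triad are data
  errors.

## Interpreting dimensions

`regress_dimension()` fits OLS with intercept of one coordinate vector on
the eight norm predictors (concreteness, valence, AoA, arousal, dominance,
neighbourhood density, length, prevalence — frequency is an inclusion
filter, not a predictor). Predictors are z-scored by default so
coefficients are comparable across fits of different scale; coordinates are
left in sampled units. Significance is two-tailed |t| > 1.96 with no
multiplicity correction, the convention of reporting per-sample t-value
distributions in this literature. `regress_posterior_samples()` repeats the
regression on each of the 50 retained configurations (one cached QR for all
samples) and reports, per dimension x predictor, the t distribution and the
fraction of samples crossing the cut; it refuses unaligned fits, since
regressing rotation-scattered samples would mix the dimensions.
`interpret_patient()` runs the same report on a single participant's fit.

The regression needs at least 10 words (eight predictors plus intercept);
the end-to-end driver skips the interpretation stage for smaller toy word
sets.

## Spatial randomness

`spatial_randomness()` computes R = (mean nearest-neighbour Minkowski
distance of the configuration) / (the same quantity averaged over 10,000
uniform configurations of equal size). R near 1 indicates complete spatial
randomness; clusters push R below 1; grid-like regularity pushes it above
1. The null's support is the configuration's axis-aligned bounding box by
default — the natural translation- and scale-invariant choice when nothing
else is known — and can be given explicitly (e.g. the unit square when the
configuration is known to live there). Worth knowing: for points *truly*
uniform on a known support, the bounding-box null is slightly too small and
inflates R by roughly 5–7% at n = 32, so calibration checks pass the
support explicitly. The reference count (10,000) only controls Monte-Carlo
error of the denominator and is reducible in tests.
`randomness_over_samples()` evaluates one R per retained posterior draw
(sharing one null seed, so identical draws give identical R), and
`compare_R_distributions()` compares two such distributions with a
two-sample Kolmogorov–Smirnov test (asymptotic p).

## Pairwise scales, single cases and Procrustes

`build_relative_scale()` scores each word +1 whenever it is selected under
the positive-pole instruction, −1 under the negative pole, 0 otherwise, and
divides by the word's unique-pair count (16): a consistently extreme word
attains ±1, and a word picked in both presentations of every pair cancels
to 0. The divisor is the pair count rather than the trial count because
that is the number of "presentations" in the scale's definition and it
makes the consistent-responder bound exactly ±1. Unchosen words contribute
explicit zeros.

`kendall_vs_ratings()` compares a scale with the corresponding rating by
Kendall rank correlation — tau-b, because scores at 1/16 resolution tie
frequently — since only the relative word order is meaningful.
`crawford_howell()` implements the modified single-case t-test,
$t = (x - \bar{c}) / (s_c \sqrt{(n+1)/n})$ on $n - 1$ df, the standard
small-normative-sample comparison (two-tailed by default; the SS comparison
below uses the one-tailed "greater" form since only abnormally *high* error
is of interest).

`combine_and_procrustes()` places each word at (valence score, concreteness
score), targets the (valence rating, concreteness rating) plane, centres
both configurations and scales each to unit total sum of squares, then fits
translation + rotation/reflection + isotropic scaling minimizing the
residual sum of squares (via vegan's Procrustes machinery, with an SVD
closed form as the independent check in the tests). The
configuration-level normalization makes SS invariant to similarity
transforms of either input. Reflection is permitted — the conventional
behaviour of ordination Procrustes, and necessary since a response scale
can be globally mirrored without being wrong about structure. Per-stimulus
squared residuals feed `stimulus_error_anova()`, a one-way ANOVA over the
four word classes used when a patient's total SS is flagged high.

## Data quality

`triad_consistency()` is the fraction of the 24 duplicate triads answered
with the same odd word twice (chance for a uniform guesser: 1/3).
`pair_consistency()` is the fraction of the 256 pairs whose two
opposite-instruction presentations selected different words (chance: 1/2).
Both metrics rise monotonically with the responder's determinism, which the
tests verify on the generator. Reaction-time screening is out of scope (the
generator does not simulate latencies).

## The end-to-end driver

`run_study()` chains everything: word set, designs, cohort, consistency,
pooled per-group fits (aligned to the generator truth), dimension
regressions, randomness distributions with the KS comparison, relative
scales with Kendall agreement, Crawford–Howell tests of each patient-like
participant against the control-like distribution (two-tailed for tau,
one-tailed for Procrustes SS), and the per-class error ANOVA for flagged
cases. Every stage derives its seed from the master seed, so a rerun is
identical; artefacts are written as plain CSV/JSON with the config hash in
the summary.

Problem sizes used by the package's own checks: the test suite fits reduced
chains (hundreds of iterations) on cohorts of up to ten simulated
participants and verifies distance-structure recovery of the planted
configuration (seed-averaged correlation of distance matrices), the group
regression signatures, and the calibration of the randomness ratio at 100
uniform configurations x 10,000 nulls; the full-scale defaults (2,000 +
5,000 iterations, 77 + 10 participants) remain the analysis settings.

## Known limitations

* The pairwise response model (logistic comparator) is a convention; real
  pairwise judgement data may follow a different psychometric form.
* The sv-like latent geometry is a noisy line, not a circumplex; it
  reproduces the valence-only regression signature but inverts the
  direction of the group shift in mean spatial randomness (see above).
* The singleton-pair optimizer is a budgeted local search; it keeps
  singleton pairs rare but does not reach the global minimum.
* Norm regressions assume linear, additive effects of z-scored norms; no
  interactions, no multiplicity correction.
* The sampler is single-chain by default; the split-chain diagnostic on
  distance summaries flags gross non-convergence but short chains remain
  the user's responsibility.
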