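---
title: "Scoring prediction strategies and their network correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring prediction strategies and their network correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(predstat)
```

## The problem

In serial prediction experiments, observers watch a stream of symbols
generated by a stochastic source and predict the next symbol. Two
quantities summarise behaviour: *how well* the observer's response
statistics track the source (a performance index), and *how* the
observer converts knowledge into choices — reproducing the source's
conditional probabilities (*probability matching*) or always choosing
the most probable outcome (*probability maximization*). This package
implements the full analysis chain for such experiments, from stimulus
generation to robust correlations between behaviour and
functional-network change, and ships a synthetic-data module that can
regenerate every input with known ground truth.

## Markov sources and sequence selection

Stimuli come from Markov sources over a four-symbol alphabet. A
zero-order (memory-less) source draws each symbol independently; the
default is $P = (.18, .72, .05, .05)$: one frequent symbol, one less
frequent, two rare. A first-order source conditions on the previous
symbol; the default is a cyclic structure in which each context allows
exactly two successors with probabilities $.8$ and $.2$:

```{r}
default_level1_matrix()
```

Because every column of this matrix also sums to 1, its stationary
distribution is exactly uniform, so the marginal frequency of every
symbol is $.25$ and first-order sequences differ from zero-order ones
in their *temporal* structure only.

Finite sequences fluctuate around the source statistics. To present
sequences that are representative of the generating model,
`select_sequences()` generates a candidate pool, scores each candidate
by the Kullback–Leibler divergence of the source from the sequence's
empirical distribution,

$$\mathrm{KL} = \sum_{c} Q(c) \sum_{t} Q(t \mid c)\,
  \ln \frac{Q(t \mid c)}{P(t \mid c)},$$

with $Q$ the source and $P$ the empirical table, and keeps the lowest
scorers (the design default: 50 out of 10{,}000 candidates of 672
symbols). Numerical choices here:

* **Logarithm base.** Natural log. The base only rescales KL and cannot
  change the selection ordering.
* **Empirical zeros.** A sequence that never shows a source-positive
  transition gets $\mathrm{KL} = +\infty$ and sorts last. No smoothing
  is applied: selection needs only the ordering, and smoothing would
  silently alter it.
* **Context weights.** The first-order KL weights contexts by the
  source's stationary distribution, not by the empirical context
  counts: $Q(\cdot)$ denotes the source throughout the formula.
* **Ties.** Broken by generation index, making a seeded run fully
  reproducible.

## The Performance Index

Responses are scored by minimum overlap with the presented
distribution, per context:

$$\mathrm{PI}(c) = \sum_{t} \min\!\big(R(t \mid c),\, P(t \mid c)\big),
 \qquad \mathrm{PI} = \sum_{c} \mathrm{PI}(c)\, P(c).$$

PI is 1 exactly when the response distribution reproduces the
presented one, and is symmetric in its arguments. A uniform guesser
achieves $\mathrm{PI}_{\mathrm{rand}} = .53$ against the default
zero-order source and $.45$ against the first-order source;
`normalize_pi()` subtracts this baseline so the two levels share a
common zero. A pure maximizer tops out at $.72$ (zero-order) and $.8$
(first-order) — these ceilings also provide the $.8/.72$ factor
`scale_strategy_index()` uses to compare strategy indices across
levels. Zero-order data flow through the same weighted-PI code path as
first-order data, using a single null context of weight 1.

Missing responses (no answer before the deadline) are excluded from
both numerator and denominator of the response distribution rather
than imputed; at the design's 2% miss rate the difference is
negligible, and exclusion does not bias the conditional frequencies.

## Strategy choice and the strategy index

Two reference models are built from the source: *Model-matching* (the
source's own conditional table) and *Model-maximization* (probability 1
on the argmax target per context; a tied argmax is a hard error unless
an explicit tie-break order is supplied, because silent tie-breaking
would make results irreproducible). The per-block *strategy choice* is

$$\Delta \mathrm{KL} = \mathrm{KL}(\text{matching} \,\|\, R)
  - \mathrm{KL}(\text{maximization} \,\|\, R),$$

negative when the responses sit closer to matching, positive when
closer to maximization. Summing the per-block curve and subtracting
the exact matcher's curve gives the *integral curve difference* (ICD)
strategy index.

Three numerical decisions matter:

* **Smoothing.** A maximizer puts zero mass on model-positive targets,
  which would make the matching KL infinite. Response rows are
  smoothed as $R \leftarrow (R + \varepsilon)/(1 + 4\varepsilon)$
  before the divergence; the default
  $\varepsilon = 1/(2 \times \text{trials per block})$ scales with the
  resolution at which a block can estimate a probability (half a
  count). The index is reported alongside the $\varepsilon$ used.
* **The matcher reference curve.** We use the analytic constant
  $-\mathrm{KL}(\text{maximization} \,\|\, \text{source}) =
  \ln p_{\mathrm{high}}$ per block ($\ln .72 = -.3285$ zero-order,
  $\ln .8 = -.2231$ first-order) rather than simulating a finite-trial
  matcher, so the reference — and hence the zero of the ICD scale — is
  deterministic.
* **Integration rule.** Blocks are discrete and equally spaced, so the
  integral is a plain sum (rectangular rule); a trapezoid option is
  provided and differs only in endpoint weights.

A consequence worth knowing: at 56 trials per block the plug-in KL of
a *sampled* matcher is biased upward (sampling noise inflates both
divergences asymmetrically), so finite-trial matchers score slightly
positive ICDs. The zero of the scale is pinned by the analytic
matcher; recovery tests therefore run at $10^4$ trials per block,
where the sampled-matcher ICD shrinks below $.05$ and the ICD is
strictly increasing across matcher-to-maximizer blends.

Per-block response windows are per-block (not cumulative); strategy
curves therefore reflect the observer's state within each block.
`residualize()` supports the control analysis that regresses
post-training PI out of the strategy index.

## Component-level imaging statistics

The imaging side starts from ICA component timecourses and spatial
maps; ICA estimation itself, and all volume preprocessing, are
upstream of this package.

**Component selection.** `select_components()` z-scores a component's
spatial map, thresholds at $z = 1.96$, and computes squared Pearson
correlations with grey-matter, white-matter and CSF probability maps.
A component is rejected when $R^2_{\mathrm{CSF}} > .025$ or
$R^2_{\mathrm{WM}} > .025$ or $R^2_{\mathrm{GM}} < .025$. The
z-scoring makes the decision invariant to affine rescaling of the
input map.

**Timecourse cleaning.** `clean_timecourse()` regresses out the
nuisance matrix (six motion parameters plus mean WM and CSF signal),
then removes a linear trend — in that order. Nuisance regressors are
*not* re-entered into the task GLM: cleaning happens once, which
avoids any ambiguity about shared variance between nuisance and task
regressors (the cost is that task variance spanned by the nuisance
space is lost; with white nuisance regressors this is a small,
unbiased attenuation).

**GLM betas.** Condition regressors are 20-s block boxcars convolved
with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
amplitude ratio 1/6, 32-s support, unit-peak normalized — all exposed
as parameters), built on a 0.1-s grid and sampled at volume onsets.
`glm_betas()` fits OLS per run and averages run betas per session;
averaging before or after the post-minus-pre subtraction is
algebraically identical.

**FNC.** `fnc_matrix()` computes pairwise Pearson correlations of
cleaned component timecourses per run, Fisher-z transforms them, and
averages across runs. A degenerate $|r| = 1$ is clipped to
$1 - 10^{-12}$ with a warning so the transform stays finite.

**Robust correlation.** `skipped_correlation()` relates change scores
to strategy while guarding against bivariate outliers, which dominate
ordinary Pearson correlations at $n = 19$. Each point is projected
onto the direction from the coordinatewise-median centre through
itself; it is flagged when its projection is extreme relative to the
sample's projections. The default rule is Carling's ideal-fourths
boxplot rule with the sample-size-adjusted constant; a MAD rule with
the $\sqrt{\chi^2_{.975,2}}$ cutoff is available as
`detector = "mad"`. Pearson's $r$ on the retained points is
accompanied by a percentile-bootstrap CI over the retained pairs using
Wilcox's small-sample-adjusted quantile bounds (wider, asymmetric
tails below $n = 250$). We calibrated this default deliberately: the
plain $.95$ percentile bootstrap after outlier removal is markedly
anti-conservative at $n = 19$, because removal inflates the sampling
variance of $r$ in a way a cleaned-pairs bootstrap cannot see. The
test suite verifies that the shipped construction covers zero in at
least 90% of null replicates while still flagging a 10-SD contaminant
and barely moving the estimate relative to a clean-subset Pearson
oracle. With no flagged outliers the estimate reduces to plain
Pearson exactly. "1000 permutations" in this literature describes
bootstrap resamples; a significance call is a CI excluding zero, and
multiple components are tested without multiplicity correction by
default.

**Steiger's z.** `steiger_z()` compares two dependent correlations
sharing a variable (structured-condition vs random-condition
correlations with the same strategy index), using the
back-transformed-average variant of the statistic and a two-sided
normal p-value.

## The synthetic cohort

`simulate_responses()` and `simulate_cohort_behavior()` generate
responder agents on the matching–maximization continuum: per trial a
context is drawn (stationary distribution for first-order sources),
and the response is sampled from
$(1-\lambda)\,P(\cdot \mid c) + \lambda\,\mathbf{1}_{\arg\max}$.
Cohorts default to $n = 19$ subjects — matching the design this
emulates, so CI widths are realistic — with $\lambda$ on an even grid
over $[0, 1]$: a grid guarantees the cohort spans the continuum at any
$n$, where random draws might not. A `learner` policy approaches
maximization as $\lambda_b = 1 - e^{-\text{rate}\, b}$ across blocks,
emulating the empirical tendency for maximization to strengthen with
training; the functional form is ours and is exposed as a parameter.
Two per cent of trials are recorded as missing by default so the
missing-response path is always exercised.

`simulate_timecourses()` builds component timecourses as planted
condition betas times HRF-convolved regressors, plus an optional
shared latent (setting pairwise component correlation), a nuisance
mixture, and white noise. Post-training structured betas are shifted
by $\text{coupling} \times \text{strategy}$ so the post-minus-pre beta
change correlates with strategy at the planted level; the residual
component is orthogonalized so the *in-sample* correlation equals the
coupling exactly, which makes recovery tests sharp. All ground truth
is returned.

What the generator does *not* emulate: physiological BOLD
nonlinearity (no balloon model — convolution is linear), scanner
drift beyond a linear trend, autocorrelated noise, genuine ICA
estimation error, and response dynamics richer than the λ-blend (real
observers drift between strategies within blocks). Passing recovery
tests therefore demonstrate that the *estimators* are correct and
calibrated under the design's geometry, not that real data meet these
assumptions.

## Test and simulation sizes

The suite runs sequence selection at the full design size
(10,000 × 672), strategy recovery at $10^4$ trials per block,
GLM recovery at 180 volumes × 200 replicates, FNC recovery over
3 runs × 180 volumes, null calibration of the skipped correlation over
100 replicates, and the end-to-end cohort recovery
($n = 19$, coupling $-.7$) over 50 replicates with 2 components —
sizes chosen to make sampling error small relative to each tolerance
while keeping a full run inside a few minutes.

## Interfaces

All stages are plain functions; `run_pipeline()` chains them
(sequence selection → cohort behaviour → timecourses → betas → FNC →
strategy–brain correlation) and writes a JSON report stamped with the
seed and a config hash, so a fixed config and seed reproduce a report
byte for byte. Configurations are YAML (`load_config()`,
`save_config()`) with the design's defaults filled in for absent keys
and unknown keys rejected. Sequences, responses and event tables read
and write delimited text; spatial maps accept in-memory arrays or
NIfTI files.

## Known limitations

* Only Markov orders 0 and 1 are implemented; the containers permit
  higher orders but no operation builds them.
* The strategy index depends on the smoothing constant for
  near-deterministic responders; comparisons across datasets should
  hold $\varepsilon$ (or the trials-per-block rule) fixed.
* The skipped-correlation CI is calibrated for the small-$n$ regime
  this design uses; for very large $n$ the adjusted bounds converge to
  the plain percentile bootstrap.
* `select_components()` assumes tissue maps and component maps share a
  grid; no resampling is provided.
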