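---
title: "Methods: gloss discrimination psychophysics and gloss-selective unit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gloss discrimination psychophysics and gloss-selective unit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glossperm)
```

## The problem

Neurons in a small region of the lower bank of the superior temporal sulcus
in the central inferior temporal cortex respond selectively to surface
gloss. glossperm implements the statistical pipeline used to relate that
selectivity to behavior in a two-alternative gloss discrimination task: a
monkey views a mid-gloss reference and a test stimulus drawn from a
seven-step gloss ladder and reports, by saccade, whether the test looked
glossier. Causal manipulations — electrical microstimulation on half the
trials, or reversible muscimol inactivation across sessions — may shift or
flatten the psychometric function, and the package quantifies those changes
with a within-session permutation test. Because no public dataset exists
for this preparation, the package ships a synthetic-data generator with
known ground truth; every analysis stage is validated against that
generator rather than against irreproducible in-vivo results.

## Stimulus design

Gloss is parameterized in the perceptual *c–d* space: *c* tracks highlight
contrast, *d* highlight sharpness. A discrimination ladder samples the
diagonal of that space at equal intervals, holding the increment ratio
Δ*c*/Δ*d* fixed at 1.78 so that steps are perceptually uniform. Only the
increments of *d* are constrained by that ratio, so the ladder stores *d*
relative to a configurable anchor (default 0 at level 1); absolute *d*
values, and the mapping from (*c*, *d*) to physical reflectance parameters
(specular reflectance, diffuse reflectance, specular spread), are
deliberately out of scope — the package designs and analyzes experiments,
it does not render stimuli.

The canonical task crosses 7 gloss levels × 5 object shapes × 3
illuminations (105 test stimuli) with a stimulation on/off factor (210
conditions, each run once per session). Shapes are random
spherical-harmonics surfaces regenerated each session by incrementing an
integer seed. The complexity metric — unspecified in the source protocol —
is defined here as total coefficient power in harmonic orders above 2; the
high-order coefficient block is rescaled so that this power is exactly
$(0.15\,(k-1)/4)^2$ for complexity level $k$, making complexity strictly
monotone by construction (level 1 is an ellipsoid-like surface with no
high-order power). All random draws use the Mersenne–Twister generator
under a locally scoped RNG state, so shape sets are bit-reproducible across
platforms and package versions.

## Neural selectivity

Responses are spike counts in a 300-ms window starting 50 ms after
stimulus onset, baseline-subtracted using the 300-ms pre-stimulus window
and expressed in spikes/s. A multiunit site is screened with a one-way
ANOVA across the 7 gloss levels, per shape (minimum 5 repetitions per
stimulus; under-sampled curves raise an exclusion error rather than
silently passing). Classification as gloss-selective requires:

1. significant gloss modulation (ANOVA, $p < 0.05$) for the optimal shape
   (largest peak mean response; exact ties broken lexicographically) **and**
   at least one other shape;
2. a significant Pearson correlation (two-sided, $n = 7$ level means)
   between the optimal-shape tuning and at least one other significantly
   modulated shape — "all shapes" is available behind a flag, since the
   protocol's plural phrasing supports either reading, and "at least one"
   was chosen as the default because it matches units whose selectivity is
   confirmed on only a subset of shapes;
3. a shuffled-image control: if responses to pixel-shuffled images (which
   preserve the luminance histogram but destroy gloss structure) are
   themselves significantly modulated *and* correlate with the
   optimal-shape tuning, the unit is rejected as luminance-confounded.

Sites significant only for the optimal shape are reported as
*not classifiable*, distinct from *not selective*. The preference sign
(glossy vs. matte) is the sign of the Spearman correlation between level
and the optimal-shape tuning. The conjunction of criteria makes the
classifier conservative: on simulated flat Poisson units the false-positive
rate is far below the nominal $\alpha$ (0/200 in the acceptance run). ANOVA
is computed from per-trial baseline-subtracted *rates*; counts versus rates
is unstated in the protocol, and rates were chosen because they are the
quantity the window arithmetic defines.

## Psychometric fitting

Choices are averaged over shapes and illuminations into per-level
proportions of "glossier" reports (15 trials per level per condition in
the canonical session; middle-level trials, which are randomly rewarded,
contribute their recorded choice). The psychometric function is the
two-parameter logistic

$$y = \frac{1}{1 + e^{-a(x-b)}}$$

with slope $a$ (sensitivity per gloss-level unit) and offset $b$ (the 50%
point). Fitting minimizes the per-level least-squares criterion — matching
fits to plotted proportions — via damped Gauss–Newton with step halving,
which guarantees a monotonically non-increasing objective (the trace is
returned so the contract is checkable). The initializer is deterministic:
$b_0$ interpolates the 0.5 crossing of the proportions, $a_0$ is the
least-squares slope of the logit of proportions clipped to [0.01, 0.99].
A trial-level binomial-likelihood mode exists behind a flag for sensitivity
checks. Fits are unweighted by default; weighting by trial count is moot
for canonical sessions (equal counts) and available as a flag for pooled
data.

Fit screening excludes datasets whose RMS residual strictly exceeds 0.25
(the protocol says only "extremely large"; 0.25 is half the dynamic range
of a proportion and is configurable), whose optimizer failed, or whose
fitted slope is degenerate ($|a| < 10^{-3}$). The degeneracy rule exists
because level-independent proportions near 0.5 are fit *exactly* by the
$a \to 0$ flat logistic — their residual is ~0, so a residual threshold
alone can never exclude them, yet they carry no psychometric information.

**Known limitation.** The least-squares slope estimator is biased upward in
small samples: at the canonical 15 trials/level, $\hat a$ averages ≈ 1.10
when the true slope is 1 (confirmed with an independent optimizer); the
bias shrinks roughly tenfold at 150 trials/level. This is a property of
the estimator the protocol prescribes, not of the implementation, and it
is why the slope-recovery acceptance assertion at 15 trials/level is
expected to fail while offset recovery is unbiased. The permutation test is
unaffected: both pseudo-groups carry the same bias, which cancels in the
difference under the null.

## The permutation test

For each gloss level the two conditions contribute 15 + 15 = 30 binary
samples. Each of the (default 10,000) permutations pools the 30 samples
per level, draws 15 into pseudo-group A and assigns the complement to B,
refits both logistics, and records Δ$a$ and Δ$b$. The complement choice —
rather than two independent draws — was made the default because the
protocol's wording ("randomly selecting 15 samples" twice) is ambiguous
and a true permutation preserves exchangeability exactly; the
independent-draw variant is available via `mode = "independent"`.
Internally the per-level reassignment is drawn as a hypergeometric count
of pooled successes, which is distribution-identical to permuting the
individual samples and much faster.

The observed difference is significant when it lies within the extreme
2.5% of either end of its null distribution, evaluated by rank with the
add-one convention (the observed value counts as a member of its own null),
so p-values are never exactly 0 and the test errs conservative.
Permutation fits that fail to converge are dropped from the null with a
logged count; more than 5% failures flags the result unreliable.
Measured calibration on 200 null sessions at 1,000 permutations: a Δ$b$
rejection rate of 0.045 (seed 1), within the binomial noise of the nominal
5% criterion; power for a −1.5-level offset shift at $a = 1$ is ≈ 0.96.

A significant negative Δ$b$ (condition − control) moves the 50% point to
lower test-gloss levels: the subject reports "glossier" more often under
the condition. This sign convention is verified against the generator.

## Muscimol time course

Inactivation outlasts the trial and affects the perception of reference
and test stimuli alike, so offset changes are uninterpretable; only slope
changes are interpreted (Δ$b$ is still computed and reported). The
generator models muscimol as a pure slope multiplier with the default
profile 0.8 at 0.5 h, 0.4 at 18 h (the observed maximum of the drug
effect) and 1.0 at 42 h (full recovery), and attenuates the deficit
geometrically over repeated injections:
$m(t, k) = 1 - (1 - m(t))\,\rho^{k}$ for injection index $k$ and
attenuation $\rho \in (0, 1]$. The attenuation rate is a free parameter:
the in-vivo observation is qualitative (the first injection produced the
largest, and only significant, deficit). The time-course analysis reuses
the permutation machinery with "before" and "after" sessions as the two
conditions on the 105-condition no-stimulation grid, and the
repeated-injection summary reports the 18-h slope difference per injection
plus a Spearman trend of |effect| against injection number.

## What the generator does and does not emulate

The generator reproduces the trial economy of the task (one trial per
condition, level-4 random reward, 15 samples per level per condition),
Poisson spike-count statistics with monotone gloss tuning and a
luminance-confound mode, Bernoulli choices from the logistic model, and
the muscimol slope profile. It does **not** emulate: rendered images or
any image-computable confound beyond the shuffled-image flag, sequential
or motivational effects across a session, current spread or muscimol
diffusion geometry, spatial structure of the cortical map, or lapse/guess
behavior (the protocol's logistic has no lapse parameter). A green test
therefore establishes that the *statistical pipeline* is correct and
calibrated under the stated generative model — not that the biological
conclusions would replicate.

Defaults that define the stated world: slope $a = 1$ and offset $b = 4$
(the ladder midpoint) for behavioral truth; 40 spikes/s baseline for
multiunit sites (the recording threshold criterion is emulated as a
default rate, not as voltage thresholding); gain 40 spikes/s over a
10 spikes/s base as the "strong gain" unit used in classifier validation,
matching the generator's own ANOVA power example; stimulation effects
parameterized as an additive offset shift plus a multiplicative slope
factor, reflecting that nearly all observed effects were horizontal
shifts. The reference-stimulus illumination mode (fixed vs.
matched-to-test, which differed between animals) is recorded in the config
for fidelity but has no effect on the generative model, which never
renders the reference.

## Numerical choices

* Ladder endpoints are exact by construction; increment ratios hold to
  better than $10^{-12}$.
* ANOVA uses the closed-form one-way F (validated against `anova(lm())`);
  within-group sum of squares of exactly 0 yields $p = 1$ for a flat curve
  and $p = 0$ for a between-group-only curve.
* Degenerate (zero-variance) tuning correlations return $r$ = NA, $p$ = 1
  rather than erroring.
* Every stochastic step derives sub-seeds from one master seed via a
  seeded `sample.int` schedule; all seeds stay below $2^{31}$.
* Time points are keyed by their canonical decimal string ("0", "0.5",
  "18", "42") to avoid floating-point map lookups.
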