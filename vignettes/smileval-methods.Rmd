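---
title: "Validating rated facial-expression stimulus sets with smileval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating rated facial-expression stimulus sets with smileval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

smileval implements the statistical machinery of a stimulus-validation
study for facial-expression image sets: a counterbalanced rating design,
a generative model of multi-rater rating data, chance-corrected
recognition accuracy, interrater reliability, a composite quality
ranking of the photographed individuals ("expressors"), and the
a-priori power analysis that sizes such a study. The motivating use
case is sets of functionally distinct smile types — reward smiles
(expressing positive affect), affiliative smiles (signalling social
bonding) and dominance smiles (asserting status) — synthesized
alongside disgust and neutral expressions from neutral portraits via
FACS action-unit manipulation, but every component is parameterised and
none requires the images themselves.

```{r setup}
library(smileval)
```

## The AU prototype registry

Each expression is defined by a FACS action-unit configuration.
Essential AUs are the subset whose activation is required for an
expression to read as its category; the rest may appear at any
intensity. Because all three smiles hinge on the Lip Corner Puller,
AU12 is pinned at 80% intensity in the smile recipes; every other AU
defaults to a midpoint 50%, which deliberately takes no position on
fine-tuning — synthesis software is expected to adjust per face, and
intensities are user-overridable. Composite synthesis tokens (`"ahh"`,
`"i"`, `"k"`, parenthesised AU groups) are vendor-defined macro
controls with no published AU decomposition, so the registry stores
them as opaque labels rather than guessing an expansion. The neutral
"recipe" is intentionally empty: neutral stimuli are the unmodified
base portraits.

Two genuinely open representation choices are worth recording. First,
asymmetric AU12 activation — the defining feature of the dominance
smile — is typically unavailable in AU-morphing software; the registry
represents the workaround (a unilateral Dimpler plus a manual
mouth-corner adjustment) as `AU14_Unilateral` with a free-text note,
because the manual adjustment is a GUI action, not an AU. Second,
which hemiface carries the unilateral AUs is a configuration option
(`dominance_side`, default `"left"`), as no convention fixes it.

```{r}
get_recipe("dominance")
```

## The counterbalanced design

The design splits the 90 expressors (45 male, 45 female) into five
gender-balanced groups of 18 and pairs groups with expressions by a
cyclic Latin square: list *k* shows group *g* the expression at
position *(g + k − 2) mod 5* of the base rotation (reward, neutral,
disgust, dominance, affiliative). The five lists are duplicated for
the horizontally mirrored R-version — mirroring controls for hemiface
biases in face perception — giving ten lists of 90 images. Thirteen
raters per list yield 13 ratings per image and 26 per
expressor-by-expression combination, while no rater ever sees two
expressions of the same face (which would invite comparison
strategies).

Two details are undetermined by the design's constraints and fixed
here by explicit convention: expressors are dealt to groups cyclically
by sorted id within gender, and rater ids are a seeded permutation
assigned to lists in blocks. Both choices are arbitrary but
deterministic, which is what the tests need. Presentation order
within a list is not modelled at all; the trial table carries no order
column.

```{r}
plan <- build_design(seed = 1)
plan
nrow(enumerate_trials(plan))
```

## The rating simulator

The simulator exists so that every downstream statistic can be
exercised against data whose generating process is known exactly. It
emulates three response channels per trial.

**Categorical choice.** Each intended expression has a row of
probabilities over the six response options (the five expressions plus
"other"). The default rows place the observed mean simple hit rates
on the diagonal (reward .921, affiliative .692, dominance .660,
disgust .915, neutral .926) and the documented confusions off the
diagonal — most prominently affiliative→reward at .177, the
perceptual overlap between the two positive smiles. Mass not pinned
by a documented cell is spread uniformly over the row's remaining
cells; this is the maximum-ignorance completion, not an empirical
claim. Rater heterogeneity enters as a Dirichlet perturbation of each
row with concentration 50 — large enough that raters share the
population structure, small enough to create the rater-level variance
that reliability statistics feed on. The concentration is a free
parameter of the simulator; the studies this emulates describe rater
variability only through random intercepts in fitted models, so any
generative account is necessarily a modelling choice.

**Ordinal ratings.** Arousal (9-point pictorial scale) and
plausibility (7-point) are generated by thresholding a latent normal
variable: latent mean = per-expression mean + rater intercept
(SD 0.5 by default) + a male-expressor shift + (for plausibility) a
mirrored-version shift. The per-expression means and SDs default to
the observed rating means/SDs, and the structural shifts to the
reported model coefficients (arousal male effect −0.145; plausibility
male effect +0.248, mirror effect −0.169), treated as latent-scale
shifts. The arousal scale is set at 9 points: the pictorial
instrument is standard at 5 or 9, and observed means up to 6.72 rule
out 5. Thresholds are equally spaced half-integer boundaries shifted
by a common offset found by root-finding so that the discretised mean
reproduces the latent mean (moment matching); without the shift,
discretisation biases the mean toward the scale midpoint whenever the
latent mean sits off-centre, because the extreme bins clip
asymmetrically.

```{r}
ratings <- simulate_ratings(plan, seed = 1)
round(tapply(ratings$arousal, ratings$expression_intended, mean), 2)
```

What the simulator does *not* emulate: reaction times, attention and
dropout, order and fatigue effects, rater-gender effects (none were
found in the motivating data), and any item-level idiosyncrasy beyond
what the confusion rows and latent means induce — every expressor is
exchangeable within gender. Passing round-trip tests therefore shows
that the analysis code recovers known structure, not that real raters
behave this way.

## Recognition metrics

The simple hit rate (SHR) per expression is the percentage of its
presentations answered correctly; with six alternatives, chance is
16.7%. SHR conflates accuracy with response bias, so the pipeline's
primary accuracy measure is Wagner's unbiased hit rate

$$\mathrm{UHR}_i = \frac{c_{ii}^2}{r_i \, u_i},$$

the squared diagonal count over the product of the row marginal
(presentations of expression *i*) and the column marginal (uses of
response *i*): the joint probability that a stimulus is correctly
identified given presentation and the response correctly used given
use. Its chance reference is $(r_i/N)(u_i/N)$ from the same
marginals. Because UHR is a proportion with variance tied to its
mean, values are arcsine square-root transformed
($\arcsin\sqrt{p} \in [0, 1.5708]$) before averaging or modelling;
the plain $\arcsin(p)$ variant is exposed as an option since the two
coincide at the endpoints that anchor interpretation. UHR is
computed per rater (18 presentations per expression under the default
design) and then aggregated, matching rater-level mixed-model
analysis; a pooled-matrix route is also available. A response
category never used by a rater makes UHR's denominator zero; it is
reported as 0 with a `zero_use` flag rather than as missing, so
summaries stay complete.

## Interrater reliability

Agreement on the categorical choices uses Fleiss' kappa,
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$, computed per list
(each list is a complete 90-item × 13-rater block) and also pooled.
Ordinal ratings use the two-way random-effects, absolute-agreement
intraclass correlations ICC(2,1) (single rater) and ICC(2,k) (mean of
k raters), estimated from the ANOVA mean squares. For balanced
complete data — which the design guarantees — this estimator
coincides with the two-way cross-classified multilevel estimate, so
the simpler closed form is used and a REML fit serves as an
independent cross-check in the test suite. Negative ICC estimates
are reported unclipped with a flag: truncation at zero would bias
per-list averages upward.

## Expressor ranking

Expressor quality combines recognition and naturalness: per expressor,
arcsine-transformed UHR from the expressor's own pooled confusion
matrix averaged over the five expressions, and raw mean plausibility
over all their trials. (A per-rater route is unavailable here — each
rater sees each expressor exactly once.) Both are standardised across
expressors and averaged with equal weight; plausibility enters on its
raw 1–7 scale since only proportions need variance stabilisation.
Z-scores use the sample SD (n−1); the population-SD variant is a
switch, and the two give identical rankings. Ranks descend by
composite with ties broken by expressor id, and the ranking is cut
into ten contiguous blocks of nine, with gender counts per block to
expose gender asymmetries in synthesis quality.

## Power analysis

The a-priori computation for the mixed-design ANOVA within-between
interaction uses the noncentral-F formulation: with *g* groups, *m*
repeated measures, sphericity correction $\varepsilon$ and assumed
repeated-measures correlation $\rho$,

$$df_1 = (g-1)(m-1)\varepsilon,\quad df_2 = (N-g)(m-1)\varepsilon,
\quad \lambda = \frac{f^2 N m \varepsilon}{1-\rho},$$

and power is $P(F' > F_{\mathrm{crit}})$. Two effect-size
conventions circulate: the default takes Cohen's *f* on the raw
effect scale and applies the repeated-measures multiplier
$m\varepsilon/(1-\rho)$ internally; the `"spss"` option assumes *f*
already absorbs it ($\lambda = f^2 N$). The default reproduces the
conventional preregistration result for this design family —
*f* = 0.25, α = 0.01, power 0.90, 10 groups, 5 measures, ρ = 0.5,
ε = 1 requires N = 80 (8 per group) — which adjudicates the
convention. The sample-size search steps by whole groups so per-group
sizes stay equal.

```{r}
minimal_sample_size(power_spec())
```

## Numerical and testing notes

Problem sizes in the test suite are chosen to keep the full suite
fast while leaving Monte-Carlo margins honest: stochastic checks run
the full 11,700-trial design (seconds) or 30–40 replicate simulations,
with acceptance bands of three standard errors of the quantity under
test. Threshold calibration brackets its root over
mean ± (scale + 6 SD), where the discretised mean is monotone in the
offset, so `uniroot` cannot miss. Degenerate inputs are first-class:
constant score vectors z-score to 0 with a warning rather than NaN;
a single-category agreement table returns NA kappa with a warning
(expected agreement is 1); zero-variance matrices return NA ICCs.

Known limitations: the simulator's confusion rows are stationary over
time and over items within expression, so item-level reliability in
real data will generally be lower than simulated; the Dirichlet
concentration and rater-intercept SD defaults are modelling choices,
not estimates; and the pipeline deliberately stops at tidy exports —
GLMM/LMM inference on the exported tables is left to the modelling
packages built for it.
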