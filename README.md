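# smileval

Design, simulate and analyse forced-choice rating studies that validate
facial-expression stimulus sets — in particular sets of functionally
distinct smiles (reward, affiliative, dominance) synthesized alongside
disgust and neutral expressions from neutral portraits via FACS
action-unit manipulation.

Validating such a stimulus set means answering three questions with
ratings from many observers: are the intended expressions recognized
above chance, how aroused and how plausible (photo-realistic) do the
faces look, and how consistent are raters with one another? smileval
packages the statistical skeleton of that workflow:

- **AU recipe registry** — machine-readable action-unit prototypes for
  the five expressions (essential vs. optional AUs, AU12 pinned at 80%
  for all smiles, unilateral AUs for the dominance smile), with
  validation and JSON round-trip.
- **Latin-square design** — 90 expressors in 5 gender-balanced groups,
  crossed with 5 expressions over 10 lists (original + mirrored
  versions), 13 raters per list: 26 ratings per expressor × expression,
  and no rater sees two expressions of the same face.
- **Rating simulator** — multinomial category choices from a
  per-expression confusion model (with Dirichlet rater heterogeneity)
  and latent-normal ordinal arousal/plausibility ratings with
  moment-matched thresholds, rater intercepts, and model-gender and
  mirror effects.
- **Recognition metrics** — simple hit rate, Wagner's unbiased hit rate
  `UHR_i = c_ii² / (r_i · u_i)`, its marginal-based chance level
  `(r_i/N)(u_i/N)`, and the arcsine square-root transform
  `arcsin(√p) ∈ [0, 1.57]`.
- **Interrater reliability** — Fleiss' kappa for the categorical
  choices; ICC(2,1) and ICC(2,k) (two-way random effects, absolute
  agreement) for the ordinal scales, per list and averaged.
- **Expressor ranking** — composite of standardized arcsine-UHR and
  plausibility, ranked into ten subgroups with per-subgroup gender
  counts.
- **Power analysis** — noncentral-F power and minimal sample size for
  the mixed-design repeated-measures ANOVA within-between interaction
  (G*Power-style `λ = f²·N·m·ε/(1−ρ)`).

## Worked example

```r
library(smileval)

plan <- build_design(seed = 1)      # 10 lists, 130 raters, 11,700 trials
ratings <- simulate_ratings(plan, seed = 1)

round(simple_hit_rate(tally_confusion(ratings)), 1)
#>      reward affiliative   dominance     disgust     neutral
#>        93.0        70.1        64.9        92.0        92.9

rel <- reliability_summary(ratings)
subset(as.data.frame(rel), list_id %in% c("mean", "pooled"))
#>    list_id            statistic     value
#> 51    mean         fleiss_kappa 0.6429850
#> 55    mean icc_2_1_plausibility 0.1094996
#> 52    mean      icc_2_1_arousal 0.4190113
#> 53    mean      icc_2_k_arousal 0.9034725
#> ...
#> 56  pooled         fleiss_kappa 0.6431167

minimal_sample_size(power_spec(f = 0.25, alpha = 0.01, target_power = 0.90,
                               g = 10, m = 5, rho = 0.5, epsilon = 1))
#> $N
#> [1] 80
#> $per_group
#> [1] 8
#> $power
#> [1] 0.9329526
```

The hit rates recover the confusion model's diagonal (reward 92.1%,
affiliative 69.2%, ... at Monte-Carlo precision); pooled Fleiss' kappa
around 0.64 indicates substantial categorical agreement; the arousal
ICCs show the familiar pattern of moderate single-rater but excellent
13-rater-mean reliability; and the preregistration-style power spec
requires 80 participants, 8 per group.

A complete run (design → simulate → metrics → reliability → ranking,
all stages as CSV plus a JSON manifest) is one call:

```r
run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

or, from a shell, via the thin CLI in `inst/cli/`:

```sh
Rscript inst/cli/smileval.R run --seed 1 --out run1
Rscript inst/cli/smileval.R power --f 0.25 --alpha 0.01 --power 0.90 \
  --groups 10 --measures 5 --rho 0.5 --epsilon 1
```

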