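# dcemix

Latent-class analysis of discrete choice (conjoint) experiments with
partial-profile, no-level-overlap designs — the instrument style used to
measure how front-line mental-health providers weigh the attributes of
implementing an evidence-based practice (EBP): supervisor and colleague
support, trainer quality, expected client benefit, modifiability,
training time, format and follow-up.

## Who this is for

Researchers analysing (or planning) stated-preference surveys in which
each choice task shows a few of many attributes: the package generates
the randomized survey versions, effects-codes the choices, segments
respondents with a latent-class conditional logit, turns coefficients
into zero-centered part-worths and importance scores, validates against
hold-out tasks, and simulates preference shares for policy scenarios.

## The model

Respondent *i* belongs to latent class *c* with probability π<sub>c</sub>;
given the class, choices follow a conditional logit over the
effects-coded alternatives *x*:

P(y<sub>it</sub> = j | c) = exp(x<sub>tj</sub>′β<sub>c</sub>) / Σ<sub>k</sub> exp(x<sub>tk</sub>′β<sub>c</sub>),
  ℓ = Σ<sub>i</sub> log Σ<sub>c</sub> π<sub>c</sub> Π<sub>t</sub> P(y<sub>it</sub> | c).

Estimation is multi-start EM with posterior-weighted Newton conditional
logit M-steps; model selection uses AIC/AIC3/BIC/CAIC on the number of
respondents plus an entropy-based separation index and a parametric
bootstrap likelihood-difference test. Within a class an attribute's
**importance** is its utility range as a percentage of the summed ranges
of all attributes. **Randomized first choice** share simulation perturbs
individual part-worths with attribute-level and product-level Gumbel
error over many iterations and credits each respondent's maximum-utility
profile. The methods vignette
(`vignettes/latent-class-dce.Rmd`) documents every assumption and
numerical choice.

No raw responses are deposited with the source study, so the package
ships a synthetic-respondent generator seeded from the study's published
two-segment solution (`study_presets()`, `study_config()`): 563
respondents, 999 survey versions, 18 partial-profile tasks (3
alternatives × 3 of 14 four-level attributes, no within-attribute level
overlap) plus two fixed hold-out tasks at positions 6 and 14, choices
drawn from a 12%/88% conditional-logit mixture.

## Worked example

```r
library(dcemix)

cfg  <- study_config(seed = 1)              # the replicated study layout
sim  <- simulate_respondents(cfg)           # 563 respondents, 11,260 choices
parts <- split_holdout(sim$dataset)         # 18 estimation + 2 hold-out tasks

fit <- fit_latent_class(parts$estimation, C = 2, n_starts = 10, seed = 1)
fit
#> Latent-class conditional logit: C = 2, N = 563, LL = -7613.84
#> Class shares: 0.882, 0.118

imp <- importance_scores(fit)                  # class 2 = the 12% segment
head(imp[imp$class == 2, ][order(-imp$importance[imp$class == 2]), ], 3)
#>             attribute class range importance rank
#> 15 supervisor_support     2  2.17       14.5    1
#> 16  colleague_support     2  1.58       10.5    2
#> 17  trainer_expertise     2  1.52       10.2    3
```

The fitted shares recover the generating 88%/12% mixture to about a
point, and the minority segment's importance ordering — supervisor
support first — matches the generator's. Downstream, `individual_partworths()` feeds `rfc_shares()` /
`sensitivity_sweep()` for scenario simulation and
`predict_holdout_shares()` + `mean_absolute_error()` for validation;
the numbered drivers under `analysis/` run the whole chain and print the
tables cited below.

## The analysis workflow

| script | what it does | writes |
|---|---|---|
| `analysis/01_simulate.R` | synthetic study cohort + design balance | `results/choices.csv`, `truth.csv`, `attributes.json` |
| `analysis/02_fit.R` | 1–3 class fits, fit-index table, bootstrap LRT, Wald tests | `fit_indices.csv`, `solution_2class.json`, `lrt.csv` |
| `analysis/03_importance.R` | part-worths ± SE, importance and ranks | `utilities.csv`, `importance.csv` |
| `analysis/04_validate.R` | hold-out share prediction and MAE | `holdout_shares.csv`, `holdout_mae.csv` |
| `analysis/05_share_simulation.R` | basic vs enhanced training scenario, supervisor-support sweep | `scenario_shares.csv` |

On the seed-1 replica the 2-class fit gives LL = −7613.84 with shares
0.882/0.118 and entropy R² = 0.86; the bootstrap −2LL difference for 1
vs 2 classes is 266.1 (p < 0.1 at 9 replicates, none reaching the
observed statistic); hold-out prediction MAEs are 0.6% and 3.0%
(overall 1.8%), and the enhanced-training scenario share rises
monotonically (41% → 66% of the sample) as its supervisor-support level
sweeps from "does not support" to "supports 100%".

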