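# sepshift

Benchmarking deployment strategies for sepsis early-warning models under
cross-site distribution shift.

Deep-learning sepsis predictors trained on one ICU cohort often degrade
when deployed at another because feature distributions shift between sites.
A hospital adopting an external model must choose how to deploy it:
use it unchanged (**generalization**), update only its classification head
(**fine-tuning**), update all weights from the source initialization
(**retraining**), train from scratch locally (**target training**), pool
source and local data (**fusion training**), or train jointly with an
explicit feature-alignment penalty (**supervised domain adaptation** via
multi-kernel MMD or CORAL). `sepshift` implements the full evaluation loop
for comparing these six strategies, end to end and on synthetic data, so
the whole protocol runs on a laptop with no access-restricted downloads:

* a multi-site **synthetic ICU cohort generator** (hourly AR(1) dynamics for
  48 features, stay-level site shifts of controllable effect size,
  MCAR missingness, and Sepsis-3-compatible antibiotic/culture/organ-score
  event streams);
* strict **Sepsis-3 labeling**: suspicion of infection (culture paired with
  a ≥72 h antibiotic course), onset confirmation (organ-score rise ≥2 in a
  window around suspicion), exclusion of stays septic within 6 h of
  admission, and hourly labels on `onset−6 … onset+13`;
* the standard **preprocessing stack**: temporal 80/10/10 splits with
  label-balance repair, nested 5–100% training subsets, missingness flags
  with forward-fill imputation, train-only standardization, sliding 6-hour
  windows;
* three compact sequence classifiers (CNN, LSTM, InceptionTime) trained
  with a reproducible protocol (weighted BCE, per-architecture optimizers,
  plateau scheduling, early stopping) on a built-in matrix-algebra engine
  whose gradients are verified against finite differences;
* **shift quantification**: per-stay summary statistics (mean/var/min/max,
  4 × 48 = 192 columns), two-sample Kolmogorov–Smirnov tests with
  Benjamini–Hochberg correction, absolute Cohen's *d* binned at
  0.2/0.5/0.8;
* threshold-free **evaluation** including the prevalence-normalized AUPRC,
  `nAUPRC = AUPRC / (positives/total)` (1 = chance at any prevalence), and
  paired Wilcoxon strategy **ranking** with Bonferroni correction.

## Worked example

Generate a source/target pair with a strong heterogeneous covariate shift
(effect size ±2 with mixed variance ratios on four informative vitals), and
compare strategies at 20% and 100% target data with a compact CNN:

```r
library(sepshift)

cfg <- experiment_config(
  reference = site_config(n_features = 8, seed = 1,
                          stay_mean_extra = 10, stay_max = 48),
  shift_d   = c(hr = 2, map = -2, resp = 2, temp = -2),
  var_ratio = c(hr = 4, map = 0.25, resp = 0.25, temp = 4),
  n_source = 200, n_target = 200,
  archs = "cnn", strategies = c("target", "retrain", "fusion"),
  fractions = c(0.2, 1), seeds = 1, max_epochs = 8
)
out <- run_pipeline(cfg)
dplyr::select(out$results, strategy, target_fraction, auroc, nauprc, recall)
#> # A tibble: 7 × 5
#>   strategy       target_fraction auroc nauprc recall
#>   <chr>                    <dbl> <dbl>  <dbl>  <dbl>
#> 1 generalization            NA   0.987  16.0  1
#> 2 target                     0.2 0.760   3.82 0.0526
#> 3 retrain                    0.2 0.946  11.2  0
#> 4 fusion                     0.2 0.994  21.7  0
#> 5 target                     1   0.995  21.2  1
#> 6 retrain                    1   0.981  13.5  1
#> 7 fusion                     1   0.986  16.8  1
```

With only 20% of the target data, training from scratch on the target
(AUROC 0.76) is clearly beaten by strategies that reuse the source —
retraining (0.95) and fusion (0.99); at 100% target data the strategies
converge. An nAUPRC of 16 means the model's precision-recall area is 16×
the positive prevalence of the test windows. The accompanying shift report
confirms the induced covariate shift:

```r
glance(out$shift)
#> # A tibble: 1 × 4
#>   n_features n_summary_columns n_fully_shifted n_medium_or_large
#> 1          8                32               4                 4
```

All four shifted features are significant in all four summary statistics
(K-S + BH at adjusted p < 0.01) and carry medium-or-large effect sizes.
`plot_strategy_curves(out$results)` draws AUROC against the target-data
fraction per strategy, and `autoplot(out$shift)` shows the effect-size
bins. Lower-level entry points (`generate_pair()`, `label_cohort()`,
`prepare_site()`, `train_model()`, `run_finetune()`, `run_da()`,
`shift_report()`, `rank_strategies()`) expose each stage separately; the
vignette in `vignettes/deployment-strategies.Rmd` documents the model,
its assumptions, and every tunable default.

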