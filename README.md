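# earlychange

Latent classes of early symptom change in web-based depression
treatment: piecewise growth mixture modeling of biweekly PHQ-9 scores,
two-fold BIC + BLRT class enumeration, Jacobson–Truax reliable change,
and the downstream statistics that link early-change class to outcome
and adherence.

## The problem

In 12-week web-based interventions for mild-to-moderate depression,
how a participant's symptoms move over the *first four weeks* — and
even between screening and registration, before the program starts —
predicts where they end up and how much of the program they use.
`earlychange` is for intervention researchers who want to identify
those early-change patterns from repeated PHQ-9 measurements
(9 items, total score 0–27) and quantify what class membership adds to
the prediction of outcome and adherence.

## The model

Let `y_i` be subject *i*'s PHQ-9 scores on the occasion grid
{screening, registration, week 2, week 4}. The piecewise growth model
uses three growth factors `η = (η₀, η₁, η₂)` — intercept,
pre-registration slope (phase 1), early-intervention slope (phase 2) —
with fixed loadings

```
Λ = [ 1 0 0        ; 1 1 0        ; 1 1 log10(2) ; 1 1 log10(3) ]
      screening      registration   week 2         week 4
```

(the log-linear coding of the phase-2 time indices 2 and 3; a linear
coding is available for comparison). A latent class `c ∈ {1..K}` gives
each class its own mean growth factors `μ_k`, with the hybrid variance
structure: slope variances fixed to 0, one intercept variance `ψ`
shared across classes, one residual variance `θ` shared across
occasions and classes. Marginally, within class `k`,

```
y_i | c = k  ~  N( Λ μ_k ,  ψ · 11ᵀ + θ · I )
```

restricted to each subject's observed occasions (full-information
likelihood: partially missing series contribute without imputation).
Estimation is multi-start EM over the latent class and the latent
intercept deviation; a compiled core makes the parametric bootstrap
affordable.

The number of classes is chosen by the two-fold rule: fit K = 1, 2, …
until BIC stops decreasing; test that K against K−1 with the
bootstrapped likelihood ratio test (BLRT); if not significant, step
down (K−1 vs K−2, …) until a test is significant, else keep one class.

Reliable change uses the Jacobson–Truax threshold
`ΔRC = z·√2·SD·√(1−r)`; with the PHQ-9 values used here (r = .86,
SD = 2.37, z = 1.96) the threshold is 2.46 points. Effect sizes are
`d = mean(pre − post) / SD(screening)` within groups and
`(m₁ − m₂)/SD_pooled` between groups with the (n−1)-weighted pooled SD.

## Worked example

A full synthetic run at the emulated study conditions (n = 409, three
latent classes, biweekly grid, study missingness):

```r
library(earlychange)

report <- run_pipeline(run_config(generator = default_study_config(),
                                  B = 49, seed = 20))
print(report)
```

```
== Early-change analysis report ==
Selected K = 3 | BIC stopped decreasing at K = 3; BLRT 3 vs 2 significant (p = 0.02)

Class enumeration:
  K   loglik  p     bic   sabic     aic  entropy converged blrt_p
1 1 -3110.55  5 6251.17 6235.30 6231.10       NA      TRUE     NA
2 2 -3000.80  9 6055.73 6027.17 6019.60 0.908982      TRUE     NA
3 3 -2940.99 13 5960.17 5918.92 5907.99 0.842705      TRUE   0.02
4 4 -2938.68 17 5979.60 5925.65 5911.36 0.873841      TRUE     NA

Class trajectories (growth-factor means):
  class weight intercept slope1 slope2 n_modal
1     1  0.538      8.55 -0.764  -1.68     222
2     2  0.331     12.38  0.106  -5.06     134
3     3  0.131     11.39  1.047   3.69      53

Reliable change threshold: 2.49

Class x reliable-change:
Pearson chi-square = 73.37, df = 4, p = 4.41e-15
standardized residuals:
     improved deteriorated unchanged
  C1     0.89        -1.51     -0.37
  C2     0.93        -2.62      0.11
  C3    -3.25         7.18      0.58
```

Reading the output: BIC is minimized at K = 3 and the bootstrap test
confirms 3 over 2 classes, reproducing the qualitative enumeration
pattern the generator was built to emulate. The three classes are an
early-response class that starts mild (intercept 8.6, both slopes
negative), an early-response-after-registration class that starts
moderate (12.4, flat phase 1, steep phase-2 decline), and a small
early-deterioration class (11.4, both slopes positive; 13% of
subjects). The reliable change threshold here is 2.49 rather than 2.46
because the pipeline estimates the screening SD from the simulated
data. The contingency table ties class to reliable change: the
deterioration class is heavily over-represented among reliably
deteriorated subjects (Pearson residual 7.2).

Downstream pieces can be used alone, tidyverse-style:

```r
compute_rci(r = 0.86, sd = 2.37)       # threshold 2.46
pooled_sd_effect_size(9.84, 3.90, 158, 8.64, 4.52, 185)  # 0.28
tidy(report$fit)                        # class-level parameters
glance(report$fit)                      # one-row fit summary
autoplot(report$fit)                    # mean trajectories per class
```

## Package map

- `occasion_grid()`, `build_loading_matrix()` — time coding of the two
  change phases.
- `longitudinal_dataset()`, `read_long_dataset()` — validated data
  container with the screening + week-2/4 inclusion rule.
- `em_fit()`, `marginal_loglik_subject()`, `information_criteria()`,
  `relative_entropy()`, `classify_subjects()` — the mixture model.
- `fit_sequence()`, `blrt()`, `select_by_bic_blrt()` — class
  enumeration.
- `compute_rci()`, `classify_change()`, `within_group_effect_size()`,
  `pooled_sd_effect_size()` — reliable change and effect sizes.
- `contingency_analysis()`, `oneway_anova_bonferroni()`,
  `screen_predictors()`, `hierarchical_regression()`,
  `multinomial_class_prediction()` — association statistics.
- `default_study_config()`, `simulate_study()`, `simulate_pgmm()` —
  synthetic data with ground truth.
- `run_pipeline()`, `write_report()` — the end-to-end analysis.
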