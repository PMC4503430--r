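# riskviz

Clinical risk prediction models — logistic regressions, Cox models, and the
points-based score systems derived from them — are usually reported as
coefficient tables or odds/hazard ratios, which are hard for clinicians and
patients to read. riskviz implements an alternative, color-based
visualization family for any *additive* model:

* **color-bar model charts**: one color bar per predictor (one color panel
  per interaction), where the color encodes the predictor value's
  contribution to the linear predictor, plus a legend and a score-to-risk
  bar;
* **patient contribution charts**: bar charts of one patient's per-term
  points with whiskers marking the contribution range observed in training
  data;
* **cumulative (waterfall) contribution charts**: each term's bar starts
  where the previous ended, ending at the patient's total score, with risk
  bars colored by configurable thresholds (default: red at ≥ 10%).

It is aimed at model developers and implementers who need to communicate
how a published risk equation works, both in general and for one specific
patient.

## The model

A model evaluates the linear predictor

```
z = β₀ + Σₜ βₜ fₜ(x)
```

over effect terms with transformations fₜ (identity, `(x−c)^k`,
`((x−c)/s)^k`, level indicators, or products of two for interactions), and
converts `z` to a risk through the logistic link `1/(1+e^(−z))` or the Cox
link `risk = 1 − S₀(t)^exp(z − z̄)` (baseline survival at a tabulated
horizon, centered at the training means). Charts display each term's
*referenced contribution* (points)

```
pointsₜ(x) = βₜ fₜ(x) − rₜ
```

where the reference rₜ is the minimal contribution observed in the
training data (default, as in nomograms), the contribution at the
predictor means, or at a custom reference patient. References change the
display only — the risk is always computed from the unshifted linear
predictor.

Models, patients and score systems are exchanged as JSON; training data as
CSV. Fitting is out of scope: models are inputs.

## Worked example

The bundled Framingham intermittent-claudication score system, for a
55-year-old man with high-normal blood pressure and diabetes, who smokes 6
cigarettes a day, has cholesterol 190 mg/dL and no coronary heart disease:

```r
library(riskviz)
ic  <- builtin_ic_score_system()
pat <- example_patients()$ic_low_risk
(s  <- total_score(ic$table, pat))
#> [1] 14
risk_for_score(ic$conversion, s)$label
#> [1] "2%"
```

He totals 14 points (3 sex + 2 age + 1 cholesterol + 1 blood pressure +
2 cigarettes + 5 diabetes + 0 CHD), which the conversion table maps to an
estimated 4-year risk of 2%.

The bundled artificial logistic model (4 main effects, 3 interactions,
including a quadratic age effect), for a 62-year-old smoking woman with a
biomarker level of 82 U/mL:

```r
m    <- builtin_artificial_model()
d    <- generate_training_data(default_artificial_spec(), m)  # seeded
summ <- compute_training_summary(m, d)
contribution_profile(m, example_patients()$artificial, summ)
#> <riskviz_profile>
#>             id     points  label
#>         gender 0.00000000      1
#>            age 0.01999579     62
#>         smoker 3.00000000      1
#>      biomarker 2.35832149     82
#>     gender:age 7.98810256  1, 62
#>  gender:smoker 0.00000000   1, 1
#>  age:biomarker 0.01639184 62, 82
#> total score: 13.38   risk: 0.01628
```

Each row is one term's points above the minimal contribution observed in
the (synthetic, seeded) training set; being a smoker contributes most for
her, while her sex sits at the observed minimum. The total score 13.38 and
the risk 1.6% come from the unshifted linear predictor z = −4.1012 — the
points only decompose it for display. Charts are built from these objects
and written to SVG/PNG:

```r
scene <- build_model_chart(m, summ)
scene <- annotate_patient(scene, m, example_patients()$artificial,
                          contribution_profile(m, example_patients()$artificial, summ))
render(scene, "model.svg")
```

A command-line wrapper covers the same workflows
(`inst/cli/riskviz predict|score|render-model|render-patient|render-score-system|make-summary|synth`).

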