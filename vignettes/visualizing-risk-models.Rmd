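---
title: "Color charts and contribution charts for additive risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color charts and contribution charts for additive risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskviz)
```

## The model class

riskviz visualizes *additive* risk prediction models. The linear predictor
for a patient with predictor values $x^1, \dots, x^d$ is

$$z = \beta_0 + \sum_t \beta_t f_t(x),$$

where each effect term $t$ applies a deterministic transformation $f_t$ to
one predictor (main effect) or to a pair (interaction, $f^{p,q}(x^p,x^q)$,
typically a product of two per-predictor transformations). Supported
transformation forms are the identity, shifted and scaled powers
$(x-c)^k$ and $((x-c)/s)^k$, level indicators for categorical predictors
(one coefficient per non-reference level), and products of two of these.
Model *fitting* is out of scope by design: models arrive fully specified,
either constructed in code or read from a JSON document with
`read_model()`.

Two links convert $z$ to a risk:

* **logistic**: $\mathrm{risk} = 1/(1+e^{-z})$;
* **Cox**: $S(t) = S_0(t)^{\exp(z - \bar z)}$, where $S_0(t)$ is the
  baseline survival at a *tabulated* horizon and $\bar z$ is the linear
  predictor at the training-mean predictor values; the risk is $1 - S(t)$.
  Horizons are never interpolated — requesting an untabulated horizon is an
  error, because a baseline survival function known at one time point
  carries no information about others.

## Contributions and the zero reference

The quantity the charts display for term $t$ and patient $x$ is the
*referenced contribution* (its "points"):

$$\mathrm{points}_t(x) = \beta_t f_t(x) - r_t,$$

where $r_t$ is a patient-independent reference constant fixed by the
`reference_policy()`:

* `observed_min` (default): $r_t = \min_{i \in D} \beta_t f_t(x_i)$ over
  the training set $D$, in analogy with nomograms — every patient then has
  non-negative points and some training patient scores zero on each term;
* `mean_reference`: $r_t = \beta_t f_t(\bar x)$ at the training means
  (taken from a Cox link, or supplied explicitly for logistic models);
* `custom`: $r_t$ evaluated at any reference patient record.

Because $r_t$ does not depend on the patient, switching policy shifts every
patient's points by the same constants. The estimated risk is **always**
computed from the unshifted linear predictor: the score-to-risk bar and the
profile footer absorb $\sum_t r_t$ (and $\beta_0$) inside the score-to-risk
map, so the displayed risk is identical — bit for bit — under every policy.
This invariant is enforced by tests over a thousand random patients.

## Training summaries

`compute_training_summary()` scans a training dataset once and records, per
term, the min and max raw contribution (the observed-minimum reference and
the whisker ends of contribution charts); per continuous predictor, the
empirical percentiles (type-7 quantiles, i.e. linear interpolation between
order statistics; defaults 5 and 95); and the extremes of the total
referenced score (the span of the score-to-risk bar and the "maximal
observed score" bar of cumulative charts). Summaries serialize to JSON
(`write_summary()`), so the training data itself never needs to travel with
the model.

## Score systems

Points-based score systems are a discretized model representation: each
predictor value falls in a bin carrying integer points, the points sum to a
score, and an ordered conversion table maps score intervals to printed risk
labels. The bundled `builtin_ic_score_system()` encodes the published
Framingham system for 4-year intermittent-claudication risk.

Printed score tables leave real-valued gaps between integer bin edges
(cholesterol 170–209 is followed by 210–249). Since such tables assume
integer-reported measurements, numeric lookups floor the value first, so
209.5 falls in the 170–209 bin; closed ranges include both printed
endpoints. Scores beyond the last printed conversion entry return the last
entry's risk flagged `extrapolated` — the printed table simply ends, and
inventing numbers past it would misrepresent the source. Labels that are
bounds ("< 1%") return the bound and its direction rather than an invented
midpoint. Overlapping bins, integer gaps and non-monotone risk sequences
are rejected at parse time.

## Color mapping

Contributions are encoded by color on a shared legend scale. Sequential
maps (the default: dark green → light green → ecru, a colorblind- and
print-safe ramp whose anchor hexes are package constants) require strictly
monotone lightness across anchors — this is the constructor's formal
definition of "perceptually ordered", and it is precisely what rainbow
palettes violate, so they cannot be built. Diverging maps have an explicit
middle anchor mapped to a midpoint value; they are only accepted for
mean/custom references, because the observed-minimum reference has no
meaningful midpoint.

Colors are quantized into `steps` equal bins (default 64): a color can be
read back through the legend (`legend_lookup()`) to its contribution within
one quantum of the legend range. Values outside the scale clamp with a
flag; a degenerate scale (`lo == hi`, e.g. a zero-coefficient term alone on
a chart) returns the mid-palette color with a flag instead of dividing by
zero.

## Chart scenes and rendering

All builders return a *scene* — a JSON-serializable description of bars,
segments, colors, markers and legends — rather than a drawing.
`build_model_chart()` emits one color bar per main-effect term (continuous
domains sampled at 256 positions; categorical ones one segment per level),
one color panel per interaction (101×101 per continuous axis — both
resolutions trade legend fidelity against file size and are package
constants, not published values), a legend spanning the union of displayed
contributions, and the score-to-risk bar. `build_score_system_chart()`
prints each bin's integer points inside its segment.
`build_contribution_chart()` and `build_cumulative_chart()` turn a
patient's `contribution_profile()` into the per-patient bar charts; the
cumulative variant telescopes exactly (each bar starts where the previous
ended, the last ends at the total score) and colors its risk bars by
`risk_thresholds()` bands with *inclusive* comparison: a risk of exactly
0.10 falls in the higher (red) band.

Sorting by contribution is an opt-in chart/profile operation
(`sort_terms()`, a stable sort so tied terms keep model order); the default
is model order. Under mean/custom references contributions can be negative;
cumulative bars then run leftward and are marked `reversed`.

`render()` writes SVG or PNG. SVG is emitted directly from the scene's
drawing primitives and is byte-stable — the same scene always produces
identical bytes, which makes figure regressions diffable. PNG rasterizes
the same primitives through `grid`. Structural figure fidelity (element
counts, labels, monotone coloring) is what the test suite pins down, via
golden scene fingerprints; pixel geometry and the exact palette are
explicit design constants.

## Synthetic training data

`generate_training_data()` draws reproducible datasets from per-predictor
distributions (uniform, domain-truncated normal via inverse-CDF sampling,
Bernoulli, categorical) with a mandatory seed; the global RNG state is
restored afterwards. `default_artificial_spec()` fixes the sampling
conditions used throughout the examples and tests of the bundled
4-predictor artificial model: age ~ U(30, 90), biomarker ~ U(0, 200),
gender ~ Bernoulli(0.5), smoker ~ Bernoulli(0.3), n = 1000. These are
documented conventions (only the example value 82 U/mL constrains the
biomarker), chosen once for reproducibility. Synthetic data emulates
independent predictors with simple marginals; it does not emulate the
correlation structure, measurement error or selection effects of a real
cohort such as Framingham, so passing tests demonstrate the *mechanics*
(referencing, reconstruction, chart invariants) on realistic ranges, not
epidemiological validity.

## Encodings the sources leave open

Three encodings are deliberate package choices, documented rather than
claimed from the sources: in the artificial model, gender = 1 is the woman
of the worked example and smoker = 1 smokes; in the stroke model, sex is
coded man = 1 / woman = 2 (the published mean 1.48 forces 1/2 coding but
not its direction); and the intermittent-claudication score table treats
ages outside its printed 45–84 band as out of domain rather than clamping.
Out-of-range continuous values error by default everywhere — the safest
behavior for clinical inputs — with an opt-in clamp mode that flags the
profile and draws clamped markers at the domain boundary.

## Numerical choices and limitations

* "Contribution equals the training minimum" uses an absolute tolerance of
  1e-9; reconstruction tests use a relative 1e-9.
* Continuous "points" are raw referenced contributions, not rescaled to a
  0–100 nomogram scale.
* The conversion-table and score-bin validators work on the integer
  lattice; non-integer score systems are out of scope.
* The published coefficient tables of the two Framingham models are not
  reproduced in the sources available to this package, so no fixture claims
  them; the generic machinery (plus `stroke_model_with()` around the
  published link constants) covers models of that shape once coefficients
  are supplied.
* Problem sizes in the test suite (n = 1000 training rows, 1000
  reconstruction patients) are the package's reference conditions for its
  property checks.
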