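#' Bundled intermittent-claudication score system
#'
#' The published Framingham score system for the 4-year risk of intermittent
#' claudication: seven predictors (sex, age, serum cholesterol, blood
#' pressure category, cigarettes smoked per day, diabetes, coronary heart
#' disease) with integer point bins, and the conversion from total score to
#' a 4-year risk estimate. Age is tabulated for 45-84 years; values outside
#' that band are out of the system's domain.
#'
#' @return A list with `table` ([score_table()]) and `conversion`
#'   ([risk_conversion()]).
#' @export
builtin_ic_score_system <- function() {
  table <- score_table(list(
    sex = list(bin_level("male", 3), bin_level("female", 0)),
    age = list(bin_range(45, 49, 0), bin_range(50, 54, 1),
               bin_range(55, 59, 2), bin_range(60, 64, 3),
               bin_range(65, 69, 4), bin_range(70, 74, 5),
               bin_range(75, 79, 6), bin_range(80, 84, 7)),
    cholesterol = list(bin_below(170, 0), bin_range(170, 209, 1),
                       bin_range(210, 249, 2), bin_range(250, 289, 3),
                       bin_above(289, 4)),
    blood_pressure = list(bin_level("normal", 0),
                          bin_level("high normal", 1),
                          bin_level("stage 1", 2),
                          bin_level("stage 2+", 4)),
    cigarettes = list(bin_value(0, 0), bin_range(1, 5, 1),
                      bin_range(6, 10, 2), bin_range(11, 20, 3),
                      bin_above(20, 4)),
    diabetes = list(bin_level("no", 0), bin_level("yes", 5)),
    chd = list(bin_level("no", 0), bin_level("yes", 5))))
  conversion <- risk_conversion(list(
    list(scores = bin_below(10, 0L), label = "< 1%"),
    list(scores = bin_range(10, 12, 0L), label = "1%"),
    list(scores = bin_range(13, 15, 0L), label = "2%"),
    list(scores = bin_range(16, 17, 0L), label = "3%"),
    list(scores = bin_value(18, 0L), label = "4%"),
    list(scores = bin_value(19, 0L), label = "5%"),
    list(scores = bin_value(20, 0L), label = "6%"),
    list(scores = bin_value(21, 0L), label = "7%"),
    list(scores = bin_value(22, 0L), label = "8%"),
    list(scores = bin_value(23, 0L), label = "10%"),
    list(scores = bin_value(24, 0L), label = "11%"),
    list(scores = bin_value(25, 0L), label = "13%"),
    list(scores = bin_value(26, 0L), label = "16%"),
    list(scores = bin_value(27, 0L), label = "18%"),
    list(scores = bin_value(28, 0L), label = "21%"),
    list(scores = bin_value(29, 0L), label = "24%"),
    list(scores = bin_value(30, 0L), label = "28%")))
  list(table = table, conversion = conversion)
}

#' Bundled artificial logistic model
#'
#' A 4-predictor logistic model used to exercise non-linear effects and
#' interactions: gender (binary), age (years), smoker (binary) and a
#' biomarker (U/mL), with
#' `z = -1 - 2*gender + 0.005*(age-60)^2 + 3*smoker - 0.02*biomarker
#'  + 0.3*gender*((age-60)/10)^3 - 2.5*gender*smoker
#'  + 0.00005*(age-60)^2*biomarker`.
#' Encoding: gender 1 = woman, smoker 1 = yes (the indicator direction is a
#' documented fixture choice). The age domain 30-90 and biomarker domain
#' 0-200 are documented fixture choices; only the example value 82 U/mL is
#' prescribed.
#'
#' @return A [risk_model()] with 4 main-effect and 3 interaction terms.
#' @export
builtin_artificial_model <- function() {
  risk_model(
    intercept = -1,
    predictors = list(
      predictor("gender", "binary", c("0", "1")),
      predictor("age", "continuous", c(30, 90), unit = "years"),
      predictor("smoker", "binary", c("0", "1")),
      predictor("biomarker", "continuous", c(0, 200), unit = "U/mL")),
    terms = list(
      effect_term("gender", "gender", -2),
      effect_term("age", "age", 0.005, transform_shifted_power(60, 2)),
      effect_term("smoker", "smoker", 3),
      effect_term("biomarker", "biomarker", -0.02),
      effect_term("gender:age", c("gender", "age"), 0.3,
                  transform_product(transform_identity(),
                                    transform_scaled_power(60, 10, 3))),
      effect_term("gender:smoker", c("gender", "smoker"), -2.5,
                  transform_product(transform_identity(),
                                    transform_identity())),
      effect_term("age:biomarker", c("age", "biomarker"), 0.00005,
                  transform_product(transform_shifted_power(60, 2),
                                    transform_identity()))),
    link = link_logistic())
}

#' Bundled stroke-model Cox link constants
#'
#' The published link constants of the Framingham model for stroke after
#' atrial fibrillation: baseline survival `S0(5) = 0.8571` at 5 years of
#' follow-up and training means for sex, age, systolic blood pressure,
#' diabetes and prior stroke/TIA (1.48, 75, 146, 0.15, 0.14). Sex is coded
#' 1/2 (the published mean 1.48 implies that coding); this package codes
#' man = 1, woman = 2, a documented choice since the assignment is not
#' published.
#'
#' @return A [link_cox()] object.
#' @export
builtin_stroke_link <- function() {
  link_cox(baseline_survival = c("5" = 0.8571),
           means = c(sex = 1.48, age = 75, sbp = 146, diabetes = 0.15,
                     prior_stroke = 0.14))
}

#' Assemble a stroke-style Cox model from a coefficient vector
#'
#' The coefficients of the published stroke model are not reproduced here;
#' this helper builds a structurally faithful Cox model (linear main effects
#' on sex, age, systolic blood pressure, diabetes, prior stroke/TIA; the
#' bundled link constants) around any user-supplied coefficient vector, e.g.
#' for the mean-identity property or for synthetic demonstrations.
#'
#' @param coefficients Named numeric vector with entries `sex`, `age`,
#'   `sbp`, `diabetes`, `prior_stroke`.
#' @return A [risk_model()] with a cox link.
#' @export
stroke_model_with <- function(coefficients) {
  need <- c("sex", "age", "sbp", "diabetes", "prior_stroke")
  coefficients <- unlist(coefficients)
  missing_c <- setdiff(need, names(coefficients))
  if (length(missing_c))
    stop("coefficients needed for: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  risk_model(
    intercept = 0,
    predictors = list(
      predictor("sex", "continuous", c(1, 2)),
      predictor("age", "continuous", c(45, 100), unit = "years"),
      predictor("sbp", "continuous", c(80, 250), unit = "mm Hg"),
      predictor("diabetes", "continuous", c(0, 1)),
      predictor("prior_stroke", "continuous", c(0, 1))),
    terms = lapply(need, function(p)
      effect_term(p, p, coefficients[[p]])),
    link = builtin_stroke_link())
}

#' Worked example patients
#'
#' The example patients used throughout the charts:
#' * `ic_low_risk`: 55-year-old man, high-normal blood pressure, diabetes,
#'   6 cigarettes/day, cholesterol 190 mg/dL, no coronary heart disease.
#' * `ic_high_risk`: 80-year-old man, stage 1 hypertension, diabetes,
#'   cholesterol 289 mg/dL, coronary heart disease, 30 cigarettes/day.
#' * `stroke_low_risk`: 60-year-old man, systolic blood pressure 120 mm Hg.
#' * `stroke_high_risk`: 80-year-old woman, systolic blood pressure
#'   183 mm Hg, diabetes, prior stroke/TIA.
#' * `artificial`: 62-year-old smoking woman, biomarker 82 U/mL
#'   (gender 1 = woman).
#'
#' @return Named list of patient records (named lists of values).
#' @export
example_patients <- function() {
  list(
    ic_low_risk = list(sex = "male", age = 55, cholesterol = 190,
                       blood_pressure = "high normal", cigarettes = 6,
                       diabetes = "yes", chd = "no"),
    ic_high_risk = list(sex = "male", age = 80, cholesterol = 289,
                        blood_pressure = "stage 1", cigarettes = 30,
                        diabetes = "yes", chd = "yes"),
    stroke_low_risk = list(sex = 1, age = 60, sbp = 120, diabetes = 0,
                           prior_stroke = 0),
    stroke_high_risk = list(sex = 2, age = 80, sbp = 183, diabetes = 1,
                            prior_stroke = 1),
    artificial = list(gender = 1, age = 62, smoker = 1, biomarker = 82))
}
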