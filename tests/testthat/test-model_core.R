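test_that("linear predictor matches independent term-by-term evaluation", {
  # degenerate cases first
  m0 <- risk_model(-1, terms = list(),
                   predictors = list(predictor("x", "continuous", c(0, 1))),
                   link = link_logistic())
  expect_identical(evaluate_linear_predictor(m0, list(x = 0.5)), -1)

  m1 <- risk_model(0,
    terms = list(effect_term("x", "x", 2)),
    predictors = list(predictor("x", "continuous", c(0, 10))))
  expect_identical(evaluate_linear_predictor(m1, list(x = 3)), 6)

  # the artificial model against the symbolic oracle, frozen worked value
  m <- builtin_artificial_model()
  p <- example_patients()$artificial
  z <- evaluate_linear_predictor(m, p)
  expect_equal(z, -4.1012, tolerance = 1e-12)
  expect_equal(z, oracle_artificial_z(1, 62, 1, 82), tolerance = 1e-12)

  # 100 random (model, patient) pairs against independent closures
  for (seed in 1:20) {
    rm_ <- random_linear_model(seed)
    set.seed(seed + 1000)
    for (i in 1:5) {
      vals <- as.list(stats::setNames(runif(length(rm_$names), -10, 10),
                                      rm_$names))
      expect_equal(evaluate_linear_predictor(rm_$model, vals),
                   rm_$oracle(vals), tolerance = 1e-12)
    }
  }
})

test_that("patient validation reports missing and out-of-domain values", {
  m <- builtin_artificial_model()
  p <- example_patients()$artificial
  expect_error(evaluate_linear_predictor(m, p[-2]), "age")
  bad <- p; bad$age <- 200
  expect_error(evaluate_linear_predictor(m, bad), "domain")
  # clamp mode records what was clamped
  vals <- validate_patient(m, bad, out_of_domain = "clamp")
  expect_identical(vals$age, 90)
  expect_identical(attr(vals, "clamped"), "age")
  bad2 <- p; bad2$gender <- 3
  expect_error(evaluate_linear_predictor(m, bad2), "level")
})

test_that("logistic link is correct, bounded and strictly monotone", {
  expect_identical(logistic_risk(0), 0.5)
  expect_equal(logistic_risk(-4.1012), oracle_logistic(-4.1012),
               tolerance = 1e-12)
  expect_equal(logistic_risk(-4.1012), 0.0163, tolerance = 5e-3)
  z <- sort(runif(200, -20, 20))
  r <- logistic_risk(z)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_lt(abs(logistic_risk(40) - 1), 1e-12)
})

test_that("cox survival centers on the means and respects horizons", {
  coefs <- c(sex = 0.5, age = 0.03, sbp = 0.01, diabetes = 0.4,
             prior_stroke = 0.6)
  m <- stroke_model_with(coefs)
  means <- as.list(m$link$means)
  # patient at the means: exponent is analytically zero
  expect_identical(cox_survival(m, means, 5), 0.8571)
  # zero coefficients: any patient gets S0(t)
  m0 <- stroke_model_with(c(sex = 0, age = 0, sbp = 0, diabetes = 0,
                            prior_stroke = 0))
  expect_identical(
    cox_survival(m0, list(sex = 2, age = 80, sbp = 160, diabetes = 1,
                          prior_stroke = 1), 5), 0.8571)
  # hand-evaluated exponent then power
  pat <- list(sex = 2, age = 80, sbp = 160, diabetes = 1, prior_stroke = 1)
  eta <- sum(unlist(coefs) * unlist(pat))
  eta_bar <- sum(unlist(coefs) *
                   c(1.48, 75, 146, 0.15, 0.14))
  expect_equal(cox_survival(m, pat, 5), 0.8571^exp(eta - eta_bar),
               tolerance = 1e-12)
  expect_error(cox_survival(m, means, 10), "not tabulated")
})

test_that("training summaries equal a brute-force row scan", {
  m <- builtin_artificial_model()
  # single row: min == max, referenced score extremes are both 0
  one <- data.frame(gender = 1, age = 62, smoker = 1, biomarker = 82)
  s1 <- compute_training_summary(m, one)
  for (t in s1$terms) expect_identical(t$min, t$max)
  expect_identical(s1$score_min, 0)
  expect_identical(s1$score_max, 0)

  # two rows, identity term
  m2 <- risk_model(0, list(effect_term("x", "x", 1)),
                   list(predictor("x", "continuous", c(0, 10))))
  s2 <- compute_training_summary(m2, data.frame(x = c(2, 5)))
  expect_identical(s2$terms$x$min, 2)
  expect_identical(s2$terms$x$max, 5)

  # generated dataset vs exhaustive scan with the independent evaluator
  d <- generate_training_data(default_artificial_spec(n = 1000, seed = 42),
                              m)
  s <- compute_training_summary(m, d)
  raw <- oracle_artificial_terms(d)
  for (id in colnames(raw)) {
    expect_equal(s$terms[[id]]$min, min(raw[, id]), tolerance = 1e-12)
    expect_equal(s$terms[[id]]$max, max(raw[, id]), tolerance = 1e-12)
  }
  tot <- rowSums(sweep(raw, 2, apply(raw, 2, min)))
  expect_equal(s$score_min, min(tot), tolerance = 1e-12)
  expect_equal(s$score_max, max(tot), tolerance = 1e-12)
  # percentiles are the interpolated order statistics
  expect_equal(s$percentiles$age[["5"]],
               unname(quantile(d$age, 0.05, type = 7)), tolerance = 1e-12)
  expect_error(compute_training_summary(m, d[0, ]), "no rows")
})

test_that("referenced contributions honor each policy", {
  m <- builtin_artificial_model()
  d <- generate_training_data(default_artificial_spec(n = 500, seed = 7), m)
  s <- compute_training_summary(m, d)
  p <- example_patients()$artificial

  # observed_min: the interaction term against an exhaustive scan
  term <- m$terms[["age:biomarker"]]
  got <- term_contribution(term, p, s, reference_policy("observed_min"),
                           model = m)
  scan_min <- min(0.00005 * (d$age - 60)^2 * d$biomarker)
  expect_equal(got, 0.00005 * 4 * 82 - scan_min, tolerance = 1e-12)

  # a patient attaining the training minimum scores zero
  i_min <- which.min(0.00005 * (d$age - 60)^2 * d$biomarker)
  at_min <- list(gender = d$gender[i_min], age = d$age[i_min],
                 smoker = d$smoker[i_min], biomarker = d$biomarker[i_min])
  expect_equal(term_contribution(term, at_min, s, model = m), 0,
               tolerance = 1e-9)

  # self-reference zeroes every term
  pol <- reference_policy("custom", reference = p)
  for (t in m$terms)
    expect_equal(term_contribution(t, p, s, pol, model = m), 0,
                 tolerance = 1e-12)
})

test_that("profiles reconstruct the direct risk and ignore the policy", {
  m <- builtin_artificial_model()
  d <- generate_training_data(default_artificial_spec(n = 500, seed = 11), m)
  s <- compute_training_summary(m, d)
  p <- example_patients()$artificial
  ref <- list(gender = 0, age = 60, smoker = 0, biomarker = 100)
  policies <- list(reference_policy("observed_min"),
                   reference_policy("custom", reference = ref))
  risks <- vapply(policies, function(pol) {
    prof <- contribution_profile(m, p, s, pol)
    expect_equal(prof$total_score, sum(prof$terms$points),
                 tolerance = 1e-12)
    # link(intercept + points + offsets) == direct evaluation
    z <- m$intercept + sum(prof$terms$points) + sum(prof$offsets)
    expect_equal(logistic_risk(z), prof$risk, tolerance = 1e-9)
    prof$risk
  }, numeric(1))
  # risk is bitwise identical across policies
  expect_identical(risks[1], risks[2])
  expect_equal(risks[1], oracle_logistic(oracle_artificial_z(1, 62, 1, 82)),
               tolerance = 1e-12)

  # cox at the means under mean_reference: all points 0, risk = 1 - S0
  sm <- stroke_model_with(c(sex = 0.3, age = 0.05, sbp = 0.02,
                            diabetes = 0.4, prior_stroke = 0.6))
  set.seed(3)
  ds <- data.frame(sex = sample(1:2, 200, TRUE),
                   age = runif(200, 50, 95), sbp = runif(200, 90, 200),
                   diabetes = rbinom(200, 1, 0.15),
                   prior_stroke = rbinom(200, 1, 0.14))
  ss <- compute_training_summary(sm, ds)
  prof <- contribution_profile(sm, as.list(sm$link$means), ss,
                               reference_policy("mean_reference"),
                               horizon = 5)
  expect_equal(prof$terms$points, rep(0, 5), tolerance = 1e-12)
  expect_equal(prof$risk, 1 - 0.8571, tolerance = 1e-12)
  # horizon is mandatory for cox
  expect_error(contribution_profile(sm, as.list(sm$link$means), ss),
               "horizon")
})

test_that("policy changes shift points by patient-independent constants", {
  m <- builtin_artificial_model()
  d <- generate_training_data(default_artificial_spec(n = 300, seed = 5), m)
  s <- compute_training_summary(m, d)
  ref <- list(gender = 1, age = 70, smoker = 0, biomarker = 50)
  pats <- random_artificial_patients(20, seed = 99)
  deltas <- sapply(seq_len(nrow(pats)), function(i) {
    pat <- as.list(pats[i, ])
    a <- contribution_profile(m, pat, s, reference_policy("observed_min"))
    b <- contribution_profile(m, pat, s,
                              reference_policy("custom", reference = ref))
    expect_identical(a$risk, b$risk)
    a$terms$points - b$terms$points
  })
  expect_lt(max(apply(deltas, 1, function(x) diff(range(x)))), 1e-12)
})
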