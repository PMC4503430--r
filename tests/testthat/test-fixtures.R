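test_that("builtin score system matches the checked-in literal tables", {
  lines <- readLines(fixture_path("ic_tables_literal.tsv"))
  lines <- lines[!startsWith(lines, "#")]
  split_at <- grep("^score\t", lines)
  tab <- read.delim(text = lines[2:(split_at - 1)], header = FALSE,
                    col.names = c("predictor", "range_or_level", "points"))
  conv <- read.delim(text = lines[split_at:length(lines)], header = TRUE)

  name_map <- c(Sex = "sex", Age = "age", `Cholesterol..mg.dL` = "cholesterol",
                `Blood.pressure` = "blood_pressure",
                `Cigarettes.d..n` = "cigarettes", Diabetes = "diabetes",
                `Coronary.heart.disease` = "chd")
  tab$predictor <- name_map[make.names(tab$predictor)]
  ic <- builtin_ic_score_system()

  # row counts per predictor
  expect_identical(
    as.integer(table(tab$predictor)[names(ic$table$predictors)]),
    unname(vapply(ic$table$predictors, length, integer(1))))
  # every literal row reproduces through the builtin lookup
  for (i in seq_len(nrow(tab))) {
    probe <- literal_probe(tab$range_or_level[i])
    expect_identical(points_for(ic$table, tab$predictor[i], probe),
                     as.integer(tab$points[i]),
                     label = paste(tab$predictor[i], tab$range_or_level[i]))
  }
  # every literal conversion row reproduces
  for (i in seq_len(nrow(conv))) {
    probe <- literal_probe(conv$score[i])
    expect_identical(risk_for_score(ic$conversion, as.numeric(probe))$label,
                     conv$estimate[i])
  }
})

test_that("builtin artificial model has the printed structure and values", {
  m <- builtin_artificial_model()
  inter <- vapply(m$terms, function(t) length(t$predictors) == 2L,
                  logical(1))
  expect_identical(sum(!inter), 4L)
  expect_identical(sum(inter), 3L)
  expect_identical(m$intercept, -1)
  # all terms vanish at the reference corner
  z0 <- evaluate_linear_predictor(
    m, list(gender = 0, age = 60, smoker = 0, biomarker = 0))
  expect_identical(z0, -1)
  expect_equal(evaluate_linear_predictor(m, example_patients()$artificial),
               -4.1012, tolerance = 1e-12)
})

test_that("builtin stroke link carries the published constants", {
  link <- builtin_stroke_link()
  expect_identical(unname(link$baseline_survival["5"]), 0.8571)
  expect_identical(unname(link$means[c("sex", "age", "sbp", "diabetes",
                                       "prior_stroke")]),
                   c(1.48, 75, 146, 0.15, 0.14))
  m <- stroke_model_with(c(sex = 1, age = 1, sbp = 1, diabetes = 1,
                           prior_stroke = 1))
  expect_error(cox_survival(m, as.list(link$means), 10), "not tabulated")
})

test_that("example patients carry the documented values", {
  pts <- example_patients()
  expect_identical(pts$ic_low_risk$cholesterol, 190)
  expect_identical(pts$stroke_low_risk$sbp, 120)
  expect_identical(pts$artificial$biomarker, 82)
  # bundled JSON copies agree with the in-code records
  for (nm in names(pts)) {
    onl <- jsonlite::read_json(fixture_path("patients",
                                            paste0(nm, ".json")))
    expect_equal(onl, pts[[nm]])
  }
})

test_that("synthetic data is reproducible and respects domains", {
  m <- builtin_artificial_model()
  spec <- default_artificial_spec(n = 500, seed = 123)
  d1 <- generate_training_data(spec, m)
  d2 <- generate_training_data(spec, m)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 500L)
  expect_identical(names(d1), c("gender", "age", "smoker", "biomarker"))
  expect_true(all(d1$age >= 30 & d1$age <= 90))
  expect_true(all(d1$biomarker >= 0 & d1$biomarker <= 200))
  expect_true(all(d1$gender %in% 0:1))

  # n = 1 stays in-domain
  one <- generate_training_data(default_artificial_spec(n = 1, seed = 9), m)
  expect_identical(nrow(one), 1L)

  # truncated normal never leaves the declared domain
  spec_n <- synthetic_spec(list(
    gender = dist_bernoulli(0.5), age = dist_normal(60, 40),
    smoker = dist_bernoulli(0.3), biomarker = dist_normal(100, 300)),
    n = 2000, seed = 4)
  dn <- generate_training_data(spec_n, m)
  expect_true(all(dn$age >= 30 & dn$age <= 90))
  expect_true(all(dn$biomarker >= 0 & dn$biomarker <= 200))

  # empirical percentile of a uniform sample sits near the theoretical one
  du <- generate_training_data(
    synthetic_spec(list(u = dist_uniform(0, 1)), n = 10000, seed = 77))
  expect_lt(abs(unname(quantile(du$u, 0.05, type = 7)) - 0.05), 0.01)

  # seeds are mandatory; generation restores the global RNG stream
  expect_error(synthetic_spec(list(u = dist_uniform(0, 1)), n = 10),
               "seed")
  set.seed(555); before <- rnorm(1)
  set.seed(555); invisible(generate_training_data(spec, m))
  expect_identical(rnorm(1), before)
})

test_that("distribution support outside the predictor domain is rejected", {
  m <- builtin_artificial_model()
  bad <- synthetic_spec(list(
    gender = dist_bernoulli(0.5), age = dist_uniform(0, 200),
    smoker = dist_bernoulli(0.3), biomarker = dist_uniform(0, 200)),
    n = 10, seed = 1)
  expect_error(generate_training_data(bad, m), "support")
})
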