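test_that("sequential colormaps are monotone and hit the boundary anchors", {
  cm <- colormap("sequential")
  expect_identical(as.character(map_contribution_to_color(0, c(0, 1), cm)),
                   as.character(riskviz:::cmap_color_at(cm, 0)))
  expect_identical(as.character(map_contribution_to_color(1, c(0, 1), cm)),
                   as.character(riskviz:::cmap_color_at(cm, 1)))
  # value order equals scale position order on random values
  set.seed(8)
  v <- runif(1000, -3, 7)
  cols <- map_contribution_to_color(v, c(-3, 7), cm)
  pos <- legend_lookup(as.character(cols), c(-3, 7), cm)
  expect_true(all(diff(pos[order(v)]) >= 0))
  # legend round trip is exact to one color-step quantum
  expect_true(all(abs(pos - v) <= 10 / cm$steps))
})

test_that("diverging maps anchor the midpoint and clamp out-of-range values", {
  cm <- colormap("diverging", steps = 63L)
  mid <- map_contribution_to_color(0, c(-2, 2), cm)
  expect_identical(as.character(mid),
                   as.character(riskviz:::cmap_color_at(cm, 0.5)))
  # asymmetric range: midpoint still maps to the middle anchor
  mid2 <- map_contribution_to_color(0, c(-1, 9), cm)
  expect_identical(as.character(mid2), as.character(mid))
  out <- map_contribution_to_color(c(-5, 5), c(-2, 2), cm)
  expect_identical(attr(out, "clamped"), c(TRUE, TRUE))
  expect_identical(as.character(out),
                   as.character(map_contribution_to_color(c(-2, 2),
                                                          c(-2, 2), cm)))
  deg <- map_contribution_to_color(1, c(1, 1), cm)
  expect_true(attr(deg, "degenerate"))
})

test_that("rainbow-style palettes cannot be constructed", {
  expect_error(colormap("sequential",
                        anchors = grDevices::rainbow(5)),
               "monotone lightness")
  expect_error(colormap("diverging", anchors = c("#000000", "#FFFFFF")),
               "odd")
  expect_error(colormap("sequential", steps = 1), "steps")
})

m <- builtin_artificial_model()
d <- generate_training_data(default_artificial_spec(n = 400, seed = 2), m)
s <- compute_training_summary(m, d)

test_that("model charts carry one element per term on a shared legend", {
  scene <- build_model_chart(m, s)
  expect_identical(length(scene$bars), 4L)
  expect_identical(length(scene$panels), 3L)
  expect_identical(vapply(scene$bars, `[[`, "", "predictor"),
                   c("gender", "age", "smoker", "biomarker"))
  # continuous bars sample the domain, categorical bars one segment/level
  age_bar <- scene$bars[[2]]
  expect_identical(length(age_bar$contributions), 256L)
  expect_identical(length(scene$bars[[1]]$contributions), 2L)
  # legend spans the union of displayed contributions
  all_c <- c(unlist(lapply(scene$bars, `[[`, "contributions")),
             unlist(lapply(scene$panels, `[[`, "contributions")))
  expect_identical(scene$legend$range, range(all_c))
  # color monotonicity within a bar under the sequential default
  pos <- legend_lookup(age_bar$colors, scene$legend$range, colormap())
  expect_true(all(diff(pos[order(age_bar$contributions)]) >= 0))
  # score-to-risk bar spans the training score extremes, risks are monotone
  expect_equal(range(scene$score_bar$scores), c(s$score_min, s$score_max),
               tolerance = 1e-12)
  expect_true(all(diff(scene$score_bar$risks) > 0))
  # the score-to-risk map absorbs the reference offsets
  expect_equal(scene$score_bar$risks[1],
               logistic_risk(m$intercept + s$score_min +
                               sum(vapply(s$terms, `[[`, numeric(1),
                                          "min"))),
               tolerance = 1e-12)
})

test_that("degenerate model bars are handled", {
  m1 <- risk_model(0, list(effect_term("b", "b", 1.5),
                           effect_term("z", "x", 0)),
                   list(predictor("b", "binary", c("0", "1")),
                        predictor("x", "continuous", c(0, 1))))
  d1 <- data.frame(b = c(0, 1), x = c(0.2, 0.9))
  s1 <- compute_training_summary(m1, d1)
  scene <- build_model_chart(m1, s1)
  expect_identical(length(scene$bars[[1]]$contributions), 2L)
  # zero-coefficient bar is uniformly the zero-contribution color
  zb <- scene$bars[[2]]
  expect_identical(length(unique(zb$colors)), 1L)
  expect_identical(zb$colors[1],
                   as.character(map_contribution_to_color(
                     0, scene$legend$range, colormap())))
  # diverging maps need a midpoint-bearing policy
  expect_error(build_model_chart(m1, s1, cmap = colormap("diverging")),
               "midpoint")
})

test_that("score-system charts carry labelled, rank-ordered segments", {
  ic <- builtin_ic_score_system()
  scene <- build_score_system_chart(ic$table, ic$conversion)
  expect_identical(length(scene$bars), 7L)
  sex_bar <- scene$bars[[1]]
  expect_identical(sex_bar$labels, c("3", "0"))
  # within each bar, color rank order equals points rank order
  for (b in scene$bars) {
    pos <- legend_lookup(b$colors, scene$legend$range, colormap())
    expect_true(all(diff(pos[order(b$points)]) >= 0))
  }
  # score bar covers the printed conversion entries in order
  expect_identical(scene$score_bar$labels[1], "< 1%")
  expect_identical(scene$score_bar$labels[17], "28%")
})

test_that("patient markers land on every bar, panel and the score bar", {
  pat <- example_patients()$artificial
  prof <- contribution_profile(m, pat, s)
  scene <- annotate_patient(build_model_chart(m, s), m, pat, prof)
  targets <- vapply(scene$markers, `[[`, "", "target")
  expect_identical(sum(targets == "bar"), 4L)
  expect_identical(sum(targets == "panel"), 3L)
  expect_identical(sum(targets == "score_bar"), 1L)
  sb <- scene$markers[[which(targets == "score_bar")]]
  expect_identical(sb$value, prof$total_score)

  # score-system chart: the worked patient's marker sits at 14
  ic <- builtin_ic_score_system()
  ss <- annotate_patient(build_score_system_chart(ic$table, ic$conversion),
                         ic$table, example_patients()$ic_low_risk)
  t2 <- vapply(ss$markers, `[[`, "", "target")
  expect_identical(ss$markers[[which(t2 == "score_bar")]]$value, 14L)
  # a patient at a bar's lower domain edge marks the segment start
  low <- list(gender = 0, age = 30, smoker = 0, biomarker = 0)
  pl <- contribution_profile(m, low, s)
  sc2 <- annotate_patient(build_model_chart(m, s), m, low, pl)
  age_m <- sc2$markers[[2]]
  expect_identical(age_m$value, 30)
})

test_that("percentile lines appear on continuous bars only", {
  scene <- annotate_percentiles(build_model_chart(m, s), s, c(5, 95))
  preds <- vapply(scene$percentile_lines, `[[`, "", "predictor")
  expect_identical(sort(unique(preds)), c("age", "biomarker"))
  expect_identical(length(scene$percentile_lines), 4L)  # 2 predictors x 2
  expect_error(annotate_percentiles(build_model_chart(m, s), s, 50),
               "percentile")
  # median of wide uniform data sits near the domain midpoint
  su <- compute_training_summary(
    m, generate_training_data(default_artificial_spec(n = 4000, seed = 31),
                              m), percentiles = c(50))
  sc <- annotate_percentiles(build_model_chart(m, su), su, 50)
  age_line <- Filter(function(l) l$predictor == "age", sc$percentile_lines)
  expect_equal(age_line[[1]]$value, 60, tolerance = 1.5)
})
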