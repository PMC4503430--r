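#' Build a color-bar model chart scene
#'
#' Produces a backend-independent description of the color-chart model
#' representation: one horizontal color bar per main-effect term (continuous
#' predictors sampled across their domain, categorical ones one segment per
#' level), one two-way color panel per interaction term, a color legend
#' spanning the union of all displayed contribution ranges, and a
#' score-to-risk bar spanning the training score range, colored by the risk
#' obtained through the model link. Contributions are referenced under the
#' given policy so the chart and patient profiles share a scale.
#'
#' @param model A [risk_model()].
#' @param summary A [compute_training_summary()] for `model`.
#' @param policy [reference_policy()] used to zero the contributions.
#' @param cmap [colormap()] for contributions; diverging maps are only
#'   meaningful (and only allowed) with `mean_reference`/`custom` policies,
#'   since `observed_min` has no natural midpoint.
#' @param horizon Required for Cox models.
#' @param n_samples Sampling resolution of continuous bars (default 256).
#' @param grid_n Per-axis resolution of interaction panels (default 101).
#' @return A `riskviz_scene` of subclass `model_chart`.
#' @export
build_model_chart <- function(model, summary,
                              policy = reference_policy("observed_min"),
                              cmap = colormap(), horizon = NULL,
                              n_samples = 256L, grid_n = 101L) {
  stopifnot(inherits(model, "riskviz_model"),
            inherits(summary, "riskviz_summary"))
  if (cmap$family == "diverging" && policy$mode == "observed_min")
    stop("a diverging colormap needs a midpoint; use a mean_reference or ",
         "custom policy", call. = FALSE)
  if (model$link$family == "cox" && is.null(horizon))
    stop("a horizon is required for cox models", call. = FALSE)
  missing_t <- setdiff(names(model$terms), names(summary$terms))
  if (length(missing_t))
    stop("training summary lacks term(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  offs <- term_reference_offsets(model, summary, policy)

  bars <- list()
  panels <- list()
  for (term in model$terms) {
    off <- offs[[term$id]]
    if (!is_interaction(term)) {
      p <- model$predictors[[term$predictors[1L]]]
      grid <- predictor_grid(p, n_samples)
      contrib <- term$coefficient *
        eval_transform(term$transformation, grid$values) - off
      bars[[length(bars) + 1L]] <- list(
        type = "color_bar", term_id = term$id, predictor = p$name,
        kind = p$kind, unit = p$unit, domain = p$domain,
        positions = grid$labels, contributions = contrib)
    } else {
      p1 <- model$predictors[[term$predictors[1L]]]
      p2 <- model$predictors[[term$predictors[2L]]]
      g1 <- predictor_grid(p1, grid_n)
      g2 <- predictor_grid(p2, grid_n)
      cg <- expand.grid(x = seq_along(g1$values), y = seq_along(g2$values))
      vals <- list(g1$values[cg$x], g2$values[cg$y])
      contrib <- term$coefficient *
        eval_transform(term$transformation, vals) - off
      panels[[length(panels) + 1L]] <- list(
        type = "interaction_panel", term_id = term$id,
        predictors = term$predictors,
        x_kind = p1$kind, y_kind = p2$kind,
        x_domain = p1$domain, y_domain = p2$domain,
        x_positions = g1$labels, y_positions = g2$labels,
        contributions = matrix(contrib, nrow = length(g1$values)))
    }
  }

  all_contrib <- c(unlist(lapply(bars, `[[`, "contributions")),
                   unlist(lapply(panels, `[[`, "contributions")))
  legend_range <- range(all_contrib)

  # colors are assigned on the shared legend scale
  for (i in seq_along(bars))
    bars[[i]]$colors <- as.character(map_contribution_to_color(
      bars[[i]]$contributions, legend_range, cmap))
  for (i in seq_along(panels))
    panels[[i]]$colors <- matrix(as.character(map_contribution_to_color(
      as.numeric(panels[[i]]$contributions), legend_range, cmap)),
      nrow = nrow(panels[[i]]$contributions))

  score_bar <- build_score_risk_bar(model, summary, policy, cmap,
                                    horizon = horizon,
                                    n_samples = n_samples)

  new_scene("model_chart",
            bars = bars, panels = panels,
            legend = legend_spec(legend_range, cmap),
            score_bar = score_bar,
            policy = policy$mode, horizon = horizon,
            markers = NULL, percentile_lines = NULL)
}

predictor_grid <- function(p, n) {
  if (p$kind == "continuous") {
    v <- seq(p$domain[1L], p$domain[2L], length.out = n)
    list(values = v, labels = v)
  } else {
    list(values = p$domain, labels = p$domain)
  }
}

legend_spec <- function(range, cmap) {
  centers <- (seq_len(cmap$steps) - 0.5) / cmap$steps
  list(range = range, family = cmap$family, anchors = cmap$anchors,
       steps = cmap$steps, colors = cmap_color_at(cmap, centers))
}

# the score-to-risk ruler at the bottom of model charts; scores are on the
# observed_min scale internally and relabelled for other policies
build_score_risk_bar <- function(model, summary, policy, cmap,
                                 horizon = NULL, n_samples = 256L) {
  shift <- sum(term_reference_offsets(model, summary, policy)) -
    sum(vapply(summary$terms, `[[`, numeric(1), "min"))
  scores_om <- seq(summary$score_min, summary$score_max,
                   length.out = n_samples)
  risks <- vapply(scores_om, function(s)
    risk_from_score(model, summary, s, horizon = horizon), numeric(1))
  rr <- range(risks)
  list(type = "score_risk_bar",
       scores = scores_om - shift,
       risks = risks, risk_range = rr,
       colors = as.character(map_contribution_to_color(risks, rr, cmap)))
}

#' Build a score-system chart scene
#'
#' The color-chart representation of a points-based score system: one bar
#' per predictor with one segment per bin, each segment labelled with its
#' integer points and colored on a shared points scale, plus a score-to-risk
#' bar assembled from the conversion entries.
#'
#' @param table A [score_table()].
#' @param conv A [risk_conversion()].
#' @param cmap A sequential [colormap()].
#' @return A `riskviz_scene` of subclass `score_system_chart`.
#' @export
build_score_system_chart <- function(table, conv, cmap = colormap()) {
  stopifnot(inherits(table, "riskviz_score_table"),
            inherits(conv, "riskviz_risk_conversion"))
  all_pts <- unlist(lapply(table$predictors, function(bins)
    vapply(bins, `[[`, integer(1), "points")))
  pts_range <- range(as.numeric(all_pts))
  bars <- lapply(names(table$predictors), function(nm) {
    bins <- table$predictors[[nm]]
    pts <- vapply(bins, `[[`, integer(1), "points")
    list(type = "points_bar", predictor = nm,
         segments = lapply(bins, function(b) c(bin_to_match(b),
                                               list(points = b$points))),
         points = pts,
         labels = as.character(pts),
         colors = as.character(map_contribution_to_color(
           as.numeric(pts), pts_range, cmap)))
  })
  vals <- vapply(conv$entries, `[[`, numeric(1), "value")
  vr <- range(vals, na.rm = TRUE)
  score_bar <- list(
    type = "score_risk_bar",
    segments = lapply(conv$entries, function(e) c(bin_to_match(e$scores),
                                                  list(label = e$label))),
    labels = vapply(conv$entries, `[[`, "", "label"),
    risks = vals,
    colors = as.character(map_contribution_to_color(vals, vr, cmap)))
  new_scene("score_system_chart",
            bars = bars, panels = list(),
            legend = legend_spec(pts_range, cmap),
            score_bar = score_bar, markers = NULL)
}

#' Add patient markers to a model or score-system chart
#'
#' Places one marker (triangle) per main-effect bar at the patient's value,
#' one (diamond) per interaction panel at the value pair, and one on the
#' score-to-risk bar at the patient's total score.
#'
#' @param scene A scene from [build_model_chart()] or
#'   [build_score_system_chart()].
#' @param source The [risk_model()] or [score_table()] the scene was built
#'   from.
#' @param patient Named list of predictor values.
#' @param profile The patient's [contribution_profile()] (model charts), or
#'   `NULL` for score systems (the score is computed from the table).
#' @return The scene with a populated `markers` element.
#' @export
annotate_patient <- function(scene, source, patient, profile = NULL) {
  stopifnot(inherits(scene, "riskviz_scene"))
  markers <- list()
  if (scene$kind == "model_chart") {
    stopifnot(inherits(source, "riskviz_model"),
              inherits(profile, "riskviz_profile"))
    vals <- validate_patient(source, patient, out_of_domain = "clamp")
    clamped <- attr(vals, "clamped")
    for (b in scene$bars)
      markers[[length(markers) + 1L]] <- list(
        target = "bar", term_id = b$term_id, shape = "triangle",
        value = vals[[b$predictor]],
        clamped = b$predictor %in% clamped)
    for (p in scene$panels)
      markers[[length(markers) + 1L]] <- list(
        target = "panel", term_id = p$term_id, shape = "diamond",
        value = list(vals[[p$predictors[1L]]], vals[[p$predictors[2L]]]),
        clamped = any(p$predictors %in% clamped))
    markers[[length(markers) + 1L]] <- list(
      target = "score_bar", shape = "triangle",
      value = profile$total_score, risk = profile$risk)
  } else if (scene$kind == "score_system_chart") {
    stopifnot(inherits(source, "riskviz_score_table"))
    patient <- as.list(patient)
    for (b in scene$bars)
      markers[[length(markers) + 1L]] <- list(
        target = "bar", predictor = b$predictor, shape = "triangle",
        value = patient[[b$predictor]],
        points = points_for(source, b$predictor, patient[[b$predictor]]))
    sc <- total_score(source, patient)
    markers[[length(markers) + 1L]] <- list(
      target = "score_bar", shape = "triangle", value = sc)
  } else {
    stop("patient markers apply to model or score-system charts",
         call. = FALSE)
  }
  scene$markers <- markers
  scene
}

#' Add percentile lines to a model chart
#'
#' Dashed vertical lines at the requested training percentiles of each
#' continuous predictor, used to flag extreme values in new patients.
#' Categorical bars are left untouched.
#'
#' @param scene A scene from [build_model_chart()].
#' @param summary The [compute_training_summary()] whose percentiles to draw.
#' @param which Percentiles (in 0-100) to draw; all must be present in the
#'   summary.
#' @return The scene with a populated `percentile_lines` element.
#' @export
annotate_percentiles <- function(scene, summary, which = c(5, 95)) {
  stopifnot(inherits(scene, "riskviz_scene"),
            scene$kind == "model_chart",
            inherits(summary, "riskviz_summary"))
  have <- summary$percentile_levels
  missing_p <- setdiff(which, have)
  if (length(missing_p))
    stop("summary does not hold percentile(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  lines <- list()
  for (b in scene$bars) {
    if (b$kind != "continuous") next
    q <- summary$percentiles[[b$predictor]]
    for (p in which)
      lines[[length(lines) + 1L]] <- list(
        predictor = b$predictor, term_id = b$term_id,
        percentile = p, value = unname(q[[as.character(p)]]),
        style = "dashed_gray")
  }
  scene$percentile_lines <- lines
  scene
}
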