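#' Risk thresholds for cumulative charts
#'
#' Ordered probability cutoffs with one color per resulting band. The
#' default reproduces the two-band scheme used for the stroke example: risks
#' below 10% are drawn green, risks of 10% or higher red. Comparison is
#' inclusive (`risk >= cutoff` selects the higher band). More cutoffs can
#' encode, e.g., different management pathways per risk band.
#'
#' @param cutoffs Strictly increasing probabilities in (0, 1).
#' @param colors One color per band: `length(cutoffs) + 1`.
#' @return A `riskviz_thresholds`.
#' @export
risk_thresholds <- function(cutoffs = 0.10,
                            colors = c("#2E7D32", "#C62828")) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1L || any(!is.finite(cutoffs)) ||
      any(cutoffs <= 0) || any(cutoffs >= 1))
    stop("cutoffs must lie strictly inside (0, 1)", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing", call. = FALSE)
  if (length(colors) != length(cutoffs) + 1L)
    stop("need one color per band: length(cutoffs) + 1", call. = FALSE)
  structure(list(cutoffs = cutoffs, colors = as_hex(colors)),
            class = "riskviz_thresholds")
}

#' @rdname risk_thresholds
#' @param risk Probability to classify.
#' @param thresholds A `riskviz_thresholds`.
#' @return `threshold_color`: the color of the band `risk` falls in.
#' @export
threshold_color <- function(risk, thresholds = risk_thresholds()) {
  stopifnot(is.numeric(risk))
  idx <- 1L + vapply(risk, function(r) sum(r >= thresholds$cutoffs),
                     integer(1))
  thresholds$colors[idx]
}

#' Reorder the terms of a contribution profile
#'
#' Stable sort of a profile's terms by their points (or the model order it
#' was built in). The total score and the risk are order-independent and are
#' left untouched.
#'
#' @param profile A [contribution_profile()].
#' @param order `"model_order"` (as built), `"increasing"` or
#'   `"decreasing"` points.
#' @return The profile with reordered `terms`.
#' @export
sort_terms <- function(profile,
                       order = c("model_order", "increasing", "decreasing")) {
  order <- match.arg(order)
  stopifnot(inherits(profile, "riskviz_profile"))
  if (order == "model_order") return(profile)
  o <- order(profile$terms$points,
             decreasing = (order == "decreasing"))
  # order() is a stable sort (radix for doubles), ties keep input order
  profile$terms <- profile$terms[o, , drop = FALSE]
  rownames(profile$terms) <- NULL
  profile
}

#' Build a patient contribution-chart scene
#'
#' One horizontal bar per effect term showing the patient's referenced
#' contribution (points), with whiskers marking the minimal and maximal
#' contribution of that term observed in the training set (on the same
#' reference scale as the bars), the patient's value printed next to each
#' bar, and a footer carrying the total score and the link-derived risk.
#' Interaction terms appear as ordinary bars.
#'
#' @param profile A [contribution_profile()].
#' @param summary The [compute_training_summary()] used to build the
#'   profile's reference.
#' @param sort Passed to [sort_terms()].
#' @return A `riskviz_scene` of subclass `contribution_chart`.
#' @export
build_contribution_chart <- function(profile, summary,
                                     sort = c("model_order", "increasing",
                                              "decreasing")) {
  stopifnot(inherits(profile, "riskviz_profile"),
            inherits(summary, "riskviz_summary"))
  missing_t <- setdiff(profile$terms$id, names(summary$terms))
  if (length(missing_t))
    stop("training summary lacks term(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  profile <- sort_terms(profile, match.arg(sort))
  bars <- lapply(seq_len(nrow(profile$terms)), function(i) {
    id <- profile$terms$id[i]
    off <- profile$offsets[[id]]
    list(term_id = id,
         points = profile$terms$points[i],
         label = profile$terms$label[i],
         whisker = c(summary$terms[[id]]$min - off,
                     summary$terms[[id]]$max - off))
  })
  new_scene("contribution_chart",
            bars = bars,
            total_score = profile$total_score,
            risk = profile$risk,
            policy = profile$policy$mode)
}

#' Build a cumulative (waterfall) contribution-chart scene
#'
#' Each term's bar starts where the previous one ended, so the last bar ends
#' at the total score; a score bar spans `[0, total]`, an extra bar marks
#' the maximal score observed in the training set, and risk bars (patient
#' and training maximum) are colored by [risk_thresholds()] bands. Under
#' references other than the observed minimum, contributions can be
#' negative and bars then run leftward as reversed segments.
#'
#' @inheritParams build_contribution_chart
#' @param model The [risk_model()] the profile came from (needed to convert
#'   the maximal observed score to a risk).
#' @param thresholds A [risk_thresholds()].
#' @return A `riskviz_scene` of subclass `cumulative_chart`.
#' @export
build_cumulative_chart <- function(profile, summary, model,
                                   thresholds = risk_thresholds(),
                                   sort = c("model_order", "increasing",
                                            "decreasing")) {
  stopifnot(inherits(profile, "riskviz_profile"),
            inherits(summary, "riskviz_summary"),
            inherits(model, "riskviz_model"),
            inherits(thresholds, "riskviz_thresholds"))
  profile <- sort_terms(profile, match.arg(sort))
  pts <- profile$terms$points
  ends <- cumsum(pts)
  starts <- c(0, ends[-length(ends)])
  bars <- lapply(seq_along(pts), function(i)
    list(term_id = profile$terms$id[i],
         label = profile$terms$label[i],
         start = starts[i], end = ends[i],
         reversed = pts[i] < 0))

  # training score extremes on the profile's reference scale
  shift <- sum(profile$offsets) -
    sum(vapply(summary$terms, `[[`, numeric(1), "min"))
  max_score <- summary$score_max - shift
  max_risk <- risk_from_score(model, summary, summary$score_max,
                              horizon = profile$horizon)

  new_scene("cumulative_chart",
            bars = bars,
            score_bar = list(start = 0, end = profile$total_score),
            max_score_bar = list(start = 0, end = max_score),
            risk_bar = list(risk = profile$risk,
                            color = threshold_color(profile$risk,
                                                    thresholds)),
            max_risk_bar = list(risk = max_risk,
                                color = threshold_color(max_risk,
                                                        thresholds)),
            thresholds = list(cutoffs = thresholds$cutoffs,
                              colors = thresholds$colors),
            total_score = profile$total_score,
            risk = profile$risk,
            policy = profile$policy$mode)
}
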