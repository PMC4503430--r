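#' Linear predictor, links and referenced contributions
#'
#' @description
#' `evaluate_linear_predictor()` computes
#' `z = intercept + sum_t beta_t * f_t(x)` for one patient.
#'
#' `logistic_risk()` converts a linear predictor to a probability through
#' `1 / (1 + exp(-z))`.
#'
#' `cox_survival()` computes `S(t) = S0(t)^exp(z - z_mean)` with `z_mean` the
#' linear predictor at the training-mean predictor values (the intercept
#' cancels between `z` and `z_mean`).
#'
#' @param model A [risk_model()].
#' @param patient Named list of predictor values (see [validate_patient()]).
#' @param out_of_domain Passed to [validate_patient()].
#' @return `evaluate_linear_predictor`: a finite number.
#' @name evaluation
NULL

term_values <- function(term, values) {
  ps <- term$predictors
  if (length(ps) == 2L) list(values[[ps[1L]]], values[[ps[2L]]])
  else values[[ps[1L]]]
}

# raw (unreferenced) contribution beta * f(x); vectorized over rows when
# `values` holds equal-length columns
term_raw <- function(term, values) {
  term$coefficient * eval_transform(term$transformation,
                                    term_values(term, values))
}

#' @rdname evaluation
#' @export
evaluate_linear_predictor <- function(model, patient,
                                      out_of_domain = c("error", "clamp")) {
  vals <- validate_patient(model, patient, out_of_domain)
  z <- model$intercept
  for (term in model$terms) z <- z + term_raw(term, vals)
  z
}

#' @rdname evaluation
#' @param z Finite linear predictor value(s).
#' @export
logistic_risk <- function(z) {
  stopifnot(is.numeric(z))
  stats::plogis(z)
}

#' @rdname evaluation
#' @param horizon Prediction horizon; must be one of the link's tabulated
#'   baseline-survival times.
#' @return `cox_survival`: the survival probability `S(t)`; the associated
#'   risk is `1 - S(t)`.
#' @export
cox_survival <- function(model, patient, horizon,
                         out_of_domain = c("error", "clamp")) {
  if (model$link$family != "cox")
    stop("cox_survival() requires a model with a cox link", call. = FALSE)
  s0 <- baseline_survival_at(model$link, horizon)
  z <- evaluate_linear_predictor(model, patient, out_of_domain)
  z_mean <- lp_unchecked(model, mean_record(model))
  s0^exp(z - z_mean)
}

baseline_survival_at <- function(link, horizon) {
  if (is.null(horizon))
    stop("a horizon is required for cox models", call. = FALSE)
  key <- as.character(as.numeric(horizon))
  tab <- link$baseline_survival
  idx <- match(key, as.character(as.numeric(names(tab))))
  if (is.na(idx))
    stop("horizon ", horizon, " is not tabulated (available: ",
         paste(names(tab), collapse = ", "),
         "); baseline survival is not interpolated", call. = FALSE)
  unname(tab[idx])
}

# the training-mean pseudo-patient used to center the cox linear predictor
mean_record <- function(model) {
  means <- model$link$means
  used <- unique(unlist(lapply(model$terms, `[[`, "predictors")))
  missing_m <- setdiff(used, names(means))
  if (length(missing_m))
    stop("no mean available for predictor(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  out <- as.list(means[used])
  # fill unused predictors too so validation passes
  for (p in model$predictors)
    if (is.null(out[[p$name]]))
      out[[p$name]] <- if (p$kind == "continuous") mean(p$domain)
                       else p$domain[1L]
  out
}

# bypasses domain validation: reference records (means, custom) are trusted
lp_unchecked <- function(model, values) {
  z <- model$intercept
  for (term in model$terms) z <- z + term_raw(term, values)
  z
}

#' Reference policies: where zero points sit
#'
#' Contributions shown on charts are shifted so that a chosen reference
#' scores zero points for every term: the minimal contribution observed in
#' the training data (`observed_min`, the default, in analogy with
#' nomograms), the training-mean predictor values (`mean_reference`), or an
#' arbitrary reference patient (`custom`). The policy changes the displayed
#' points by a patient-independent constant per term; the risk is always
#' computed from the unshifted linear predictor and is identical across
#' policies.
#'
#' @param mode One of `"observed_min"`, `"mean_reference"`, `"custom"`.
#' @param reference For `custom` (required) or `mean_reference` (optional
#'   override of the link means): a named list of predictor values.
#' @return A `riskviz_policy`.
#' @export
reference_policy <- function(mode = c("observed_min", "mean_reference",
                                      "custom"),
                             reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom" && is.null(reference))
    stop("custom policy requires a reference patient record", call. = FALSE)
  structure(list(mode = mode, reference = reference),
            class = "riskviz_policy")
}

# per-term constant subtracted from the raw contribution under a policy
term_reference_offsets <- function(model, summary, policy) {
  ids <- names(model$terms)
  switch(policy$mode,
    observed_min = {
      if (is.null(summary))
        stop("observed_min policy requires a training summary", call. = FALSE)
      missing_t <- setdiff(ids, names(summary$terms))
      if (length(missing_t))
        stop("training summary lacks term(s): ",
             paste(missing_t, collapse = ", "), call. = FALSE)
      vapply(ids, function(id) summary$terms[[id]]$min, numeric(1))
    },
    mean_reference = {
      ref <- policy$reference
      if (is.null(ref)) {
        if (model$link$family != "cox" || is.null(model$link$means))
          stop("mean_reference policy needs link means or an explicit ",
               "reference record", call. = FALSE)
        ref <- mean_record(model)
      }
      vapply(model$terms, term_raw, numeric(1), values = as.list(ref))
    },
    custom = vapply(model$terms, term_raw, numeric(1),
                    values = as.list(policy$reference))
  )
}

#' Referenced contribution of one term
#'
#' The points a patient scores on one term: the raw contribution
#' `beta * f(x)` minus the term's reference value under the active policy
#' (training minimum, contribution at the means, or contribution at a custom
#' reference record). Main effects and interactions are handled identically.
#'
#' @param term An [effect_term()] belonging to `model`.
#' @param patient Named list of predictor values.
#' @param summary A [compute_training_summary()] result (required under
#'   `observed_min`).
#' @param policy A [reference_policy()].
#' @param model The model the term belongs to (needed to resolve means and
#'   validate the patient).
#' @return The referenced contribution (points) as a single number.
#' @export
term_contribution <- function(term, patient, summary,
                              policy = reference_policy("observed_min"),
                              model = NULL) {
  if (is.null(model))
    stop("term_contribution() needs the enclosing model", call. = FALSE)
  vals <- validate_patient(model, patient)
  offs <- term_reference_offsets(model, summary, policy)
  term_raw(term, vals) - offs[[term$id]]
}

#' Summarize a training dataset for charting
#'
#' Computes, per effect term, the minimum and maximum raw contribution
#' `beta * f(x)` over the rows of a training dataset; per continuous
#' predictor, empirical percentiles (linear interpolation between order
#' statistics); and the extremes of the total referenced score under the
#' `observed_min` policy. These summaries anchor the zero-point reference,
#' the whiskers of contribution charts and the score-to-risk bar.
#'
#' @param model A [risk_model()].
#' @param data A data frame whose columns cover all model predictors, one
#'   row per training individual.
#' @param percentiles Percentiles (in 0-100) recorded for each continuous
#'   predictor; default the 5th and 95th.
#' @return A `riskviz_summary` with elements `terms` (per-term `min`, `max`),
#'   `percentiles` (per continuous predictor), `score_min`, `score_max` and
#'   `n`.
#' @export
compute_training_summary <- function(model, data, percentiles = c(5, 95)) {
  if (!is.data.frame(data)) data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("training dataset has no rows", call. = FALSE)
  pnames <- names(model$predictors)
  missing_c <- setdiff(pnames, names(data))
  if (length(missing_c))
    stop("dataset lacks column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  stopifnot(all(percentiles >= 0), all(percentiles <= 100))

  cols <- as.list(data[pnames])
  for (p in model$predictors) {
    if (p$kind == "continuous") {
      v <- suppressWarnings(as.numeric(cols[[p$name]]))
      if (anyNA(v))
        stop("non-numeric value in continuous column '", p$name, "' (row ",
             which(is.na(v))[1L], ")", call. = FALSE)
      cols[[p$name]] <- v
    }
  }

  raw <- vapply(model$terms, term_raw, numeric(nrow(data)), values = cols)
  raw <- matrix(raw, nrow = nrow(data),
                dimnames = list(NULL, names(model$terms)))
  term_stats <- lapply(names(model$terms), function(id)
    list(min = min(raw[, id]), max = max(raw[, id])))
  names(term_stats) <- names(model$terms)

  pct <- list()
  for (p in model$predictors) {
    if (p$kind == "continuous") {
      q <- stats::quantile(cols[[p$name]], probs = percentiles / 100,
                           type = 7, names = FALSE)
      pct[[p$name]] <- stats::setNames(q, as.character(percentiles))
    }
  }

  ref_tot <- rowSums(raw) -
    sum(vapply(term_stats, `[[`, numeric(1), "min"))
  structure(list(terms = term_stats, percentiles = pct,
                 percentile_levels = as.numeric(percentiles),
                 score_min = min(ref_tot), score_max = max(ref_tot),
                 n = nrow(data)),
            class = "riskviz_summary")
}

#' Risk from the model link
#'
#' @keywords internal
link_risk <- function(model, z, horizon = NULL) {
  if (model$link$family == "logistic") return(logistic_risk(z))
  s0 <- baseline_survival_at(model$link, horizon)
  z_mean <- lp_unchecked(model, mean_record(model))
  1 - s0^exp(z - z_mean)
}

# map a total referenced score (observed_min scale) back to a risk:
# z = intercept + score + sum of per-term training minima
risk_from_score <- function(model, summary, score, horizon = NULL) {
  offset <- sum(vapply(summary$terms, `[[`, numeric(1), "min"))
  link_risk(model, model$intercept + score + offset, horizon = horizon)
}

#' Patient contribution profile
#'
#' Assembles, for one patient, the referenced contribution (points) of every
#' effect term in model order, their sum (the score) and the estimated risk.
#' The risk is always computed from the unshifted linear predictor through
#' the model link: reference policies shift the displayed points only and
#' never change the risk.
#'
#' @inheritParams term_contribution
#' @param model A [risk_model()].
#' @param horizon Required for Cox models; must be a tabulated horizon.
#' @param out_of_domain Passed to [validate_patient()].
#' @return A `riskviz_profile` with `terms` (data frame: `id`, `points`,
#'   `label`), `total_score`, `risk`, `policy`, `offsets` (per-term reference
#'   values), `horizon` and `clamped`.
#' @export
contribution_profile <- function(model, patient, summary,
                                 policy = reference_policy("observed_min"),
                                 horizon = NULL,
                                 out_of_domain = c("error", "clamp")) {
  vals <- validate_patient(model, patient, out_of_domain)
  if (model$link$family == "cox" && is.null(horizon))
    stop("a horizon is required for cox models", call. = FALSE)
  offs <- term_reference_offsets(model, summary, policy)
  raw <- vapply(model$terms, term_raw, numeric(1), values = vals)
  points <- raw - offs
  labels <- vapply(model$terms, function(term) {
    paste(vapply(term$predictors,
                 function(p) format(vals[[p]], trim = TRUE), ""),
          collapse = ", ")
  }, "")
  z <- model$intercept + sum(raw)
  risk <- link_risk(model, z, horizon = horizon)
  structure(list(
    terms = data.frame(id = names(model$terms), points = unname(points),
                       label = unname(labels), stringsAsFactors = FALSE),
    total_score = sum(points), risk = unname(risk),
    linear_predictor = unname(z),
    policy = policy, offsets = offs, horizon = horizon,
    clamped = attr(vals, "clamped")),
    class = "riskviz_profile")
}

#' @export
print.riskviz_profile <- function(x, ...) {
  cat("<riskviz_profile>\n")
  print(x$terms, row.names = FALSE)
  cat(sprintf("total score: %.4g   risk: %.4g\n", x$total_score, x$risk))
  invisible(x)
}
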