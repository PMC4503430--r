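#' Declare a model predictor
#'
#' A predictor is binary or categorical (with an ordered set of levels) or
#' continuous (with a closed numeric domain). The domain drives chart axes,
#' patient validation and synthetic-data generation.
#'
#' @param name Predictor identifier.
#' @param kind One of `"binary"`, `"categorical"`, `"continuous"`.
#' @param domain For binary/categorical: character (or coercible) vector of
#'   unique levels, length exactly 2 for binary. For continuous: numeric
#'   `c(lo, hi)` with `lo < hi`.
#' @param unit Display unit, may be `""`.
#' @return A `riskviz_predictor`.
#' @export
predictor <- function(name, kind = c("continuous", "binary", "categorical"),
                      domain, unit = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    domain <- as.numeric(domain)
    if (length(domain) != 2L || !all(is.finite(domain)) ||
        domain[1L] >= domain[2L])
      stop("continuous predictor '", name,
           "' needs a domain c(lo, hi) with lo < hi", call. = FALSE)
  } else {
    domain <- as.character(domain)
    if (length(domain) < 1L || anyDuplicated(domain))
      stop("predictor '", name, "' needs non-empty unique levels",
           call. = FALSE)
    if (kind == "binary" && length(domain) != 2L)
      stop("binary predictor '", name, "' needs exactly 2 levels",
           call. = FALSE)
  }
  structure(list(name = name, kind = kind, domain = domain,
                 unit = as.character(unit)),
            class = "riskviz_predictor")
}

#' Declare an effect term
#'
#' A term contributes `coefficient * f(x)` to the linear predictor, where `f`
#' is a [transformations] object over one predictor (main effect) or two
#' (interaction, with a `transform_product`).
#'
#' @param id Unique term identifier.
#' @param predictors Character vector of 1 or 2 predictor names.
#' @param coefficient Finite real coefficient.
#' @param transformation A `riskviz_transform`; defaults to the identity.
#'   Interactions require a `product_of_two` whose components align with
#'   `predictors` order.
#' @return A `riskviz_term`.
#' @export
effect_term <- function(id, predictors, coefficient,
                        transformation = transform_identity()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(predictors),
            length(predictors) %in% c(1L, 2L),
            inherits(transformation, "riskviz_transform"))
  coefficient <- as.numeric(coefficient)
  if (length(coefficient) != 1L || !is.finite(coefficient))
    stop("term '", id, "': coefficient must be a single finite number",
         call. = FALSE)
  n_needed <- if (transformation$form == "product_of_two") 2L else 1L
  if (length(predictors) != n_needed)
    stop("term '", id, "': ", length(predictors), " predictor(s) but ",
         "transformation expects ", n_needed, call. = FALSE)
  structure(list(id = id, predictors = predictors,
                 coefficient = coefficient,
                 transformation = transformation),
            class = "riskviz_term")
}

is_interaction <- function(term) length(term$predictors) == 2L

#' Link specifications
#'
#' The link maps the linear predictor to a risk. `link_logistic()` applies
#' `1 / (1 + exp(-z))`. `link_cox()` applies the proportional-hazards
#' survival formula `S(t) = S0(t)^exp(z - z_mean)`, where `S0(t)` is the
#' baseline survival at a tabulated horizon and `z_mean` is the linear
#' predictor evaluated at the training-mean predictor values; the risk is
#' `1 - S(t)`. Only tabulated horizons are valid: `S0(t)` is never
#' interpolated between horizons.
#'
#' @param baseline_survival Named numeric vector mapping horizon (as a
#'   number-like name) to `S0(t)` in (0, 1].
#' @param means Named numeric vector of training means, one per predictor
#'   used by the model.
#' @return A `riskviz_link`.
#' @export
link_logistic <- function() {
  structure(list(family = "logistic"), class = "riskviz_link")
}

#' @rdname link_logistic
#' @export
link_cox <- function(baseline_survival, means) {
  baseline_survival <- unlist(baseline_survival)
  means <- unlist(means)
  if (length(baseline_survival) == 0L || is.null(names(baseline_survival)))
    stop("cox link requires a named, non-empty baseline_survival table",
         call. = FALSE)
  if (!all(baseline_survival > 0 & baseline_survival <= 1))
    stop("baseline survival values must lie in (0, 1]", call. = FALSE)
  if (length(means) == 0L || is.null(names(means)))
    stop("cox link requires named predictor means", call. = FALSE)
  structure(list(family = "cox",
                 baseline_survival = baseline_survival,
                 means = means),
            class = "riskviz_link")
}

#' Assemble an additive risk model
#'
#' The model evaluates `z = intercept + sum_t coefficient_t * f_t(x)` and
#' converts `z` to a risk through its link.
#'
#' @param intercept Model intercept (`0` is typical for Cox models, whose
#'   centering absorbs it).
#' @param terms List of [effect_term()] objects with unique ids.
#' @param predictors List of [predictor()] objects covering every name any
#'   term references.
#' @param link A [link_logistic()] or [link_cox()] object. A Cox link must
#'   provide a mean for every predictor used by a term.
#' @return A `riskviz_model`.
#' @export
risk_model <- function(intercept, terms, predictors, link = link_logistic()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept), is.list(terms), is.list(predictors),
            inherits(link, "riskviz_link"))
  for (p in predictors) stopifnot(inherits(p, "riskviz_predictor"))
  for (t in terms) stopifnot(inherits(t, "riskviz_term"))
  pnames <- vapply(predictors, `[[`, "", "name")
  if (anyDuplicated(pnames))
    stop("duplicate predictor names", call. = FALSE)
  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate term ids", call. = FALSE)
  used <- unique(unlist(lapply(terms, `[[`, "predictors")))
  missing_p <- setdiff(used, pnames)
  if (length(missing_p))
    stop("terms reference undeclared predictor(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  if (link$family == "cox") {
    no_mean <- setdiff(used, names(link$means))
    if (length(no_mean))
      stop("cox link lacks a mean for predictor(s): ",
           paste(no_mean, collapse = ", "), call. = FALSE)
  }
  names(predictors) <- pnames
  names(terms) <- ids
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 predictors = predictors, link = link),
            class = "riskviz_model")
}

#' @export
print.riskviz_model <- function(x, ...) {
  n_int <- sum(vapply(x$terms, is_interaction, logical(1)))
  cat(sprintf("<riskviz_model> %s link, intercept %g, %d terms (%d main, %d interaction), %d predictors\n",
              x$link$family, x$intercept, length(x$terms),
              length(x$terms) - n_int, n_int, length(x$predictors)))
  invisible(x)
}

#' Validate (and optionally clamp) a patient record against a model
#'
#' A patient record is a named list/vector mapping every model predictor to a
#' value. Continuous values must lie inside the declared domain; under
#' `out_of_domain = "clamp"` they are clamped to the nearest domain edge and
#' the record is flagged. Binary/categorical values must equal a declared
#' level (matched as character).
#'
#' @param model A `riskviz_model`.
#' @param patient Named list or vector of predictor values.
#' @param out_of_domain `"error"` (default) or `"clamp"`.
#' @return A named list of validated values with attribute `"clamped"`, a
#'   character vector of the predictors that were clamped.
#' @export
validate_patient <- function(model, patient,
                             out_of_domain = c("error", "clamp")) {
  out_of_domain <- match.arg(out_of_domain)
  patient <- as.list(patient)
  clamped <- character(0)
  out <- list()
  for (p in model$predictors) {
    if (is.null(patient[[p$name]]))
      stop("missing value for predictor '", p$name, "'", call. = FALSE)
    v <- patient[[p$name]]
    if (p$kind == "continuous") {
      v <- as.numeric(v)
      if (!is.finite(v))
        stop("non-numeric value for continuous predictor '", p$name, "'",
             call. = FALSE)
      if (v < p$domain[1L] || v > p$domain[2L]) {
        if (out_of_domain == "error")
          stop("value ", v, " outside domain [", p$domain[1L], ", ",
               p$domain[2L], "] of predictor '", p$name, "'", call. = FALSE)
        v <- min(max(v, p$domain[1L]), p$domain[2L])
        clamped <- c(clamped, p$name)
      }
    } else {
      if (!as.character(v) %in% p$domain)
        stop("value '", v, "' is not a level of predictor '", p$name,
             "' (levels: ", paste(p$domain, collapse = ", "), ")",
             call. = FALSE)
    }
    out[[p$name]] <- v
  }
  attr(out, "clamped") <- clamped
  out
}
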