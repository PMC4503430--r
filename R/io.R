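#' Read and write model specifications
#'
#' Models are exchanged as JSON documents of the form
#' ```
#' {"predictors": [{"name", "kind", "domain", "unit"}],
#'  "intercept": number,
#'  "terms": [{"id", "predictors", "coefficient", "transformation"}],
#'  "link": {"family", "baseline_survival"?, "means"?}}
#' ```
#' where a transformation object carries a `form` and its parameters
#' (`c`, `s`, `k`, `level`, or `components` for products). The round trip
#' `read_model(write_model(m, path))` is lossless.
#'
#' @param path JSON file path.
#' @return `read_model`: a [risk_model()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  for (field in c("predictors", "intercept", "terms", "link"))
    if (is.null(doc[[field]]))
      stop("model document missing required field at /", field,
           call. = FALSE)
  preds <- lapply(doc$predictors, function(p) {
    for (f in c("name", "kind", "domain"))
      if (is.null(p[[f]]))
        stop("model document missing field at /predictors/", f,
             call. = FALSE)
    predictor(p$name, p$kind, unlist(p$domain), p$unit %||% "")
  })
  terms <- lapply(doc$terms, function(t) {
    for (f in c("id", "predictors", "coefficient"))
      if (is.null(t[[f]]))
        stop("model document missing field at /terms/", f, call. = FALSE)
    effect_term(t$id, unlist(t$predictors), t$coefficient,
                transform_from_doc(t$transformation))
  })
  link <- if (doc$link$family == "logistic") link_logistic()
  else link_cox(doc$link$baseline_survival, doc$link$means)
  risk_model(doc$intercept, terms, preds, link)
}

transform_from_doc <- function(d) {
  if (is.null(d)) return(transform_identity())
  switch(d$form,
         identity = transform_identity(),
         shifted_power = transform_shifted_power(d$c, d$k),
         scaled_power = transform_scaled_power(d$c, d$s, d$k),
         level_indicator = transform_level_indicator(d$level),
         product_of_two = transform_product(
           transform_from_doc(d$components[[1L]]),
           transform_from_doc(d$components[[2L]])),
         stop("unknown transformation form at /terms/transformation: ",
              d$form, call. = FALSE))
}

transform_to_doc <- function(tf) {
  out <- unclass(tf)
  if (tf$form == "product_of_two")
    out$components <- lapply(tf$components, transform_to_doc)
  out
}

#' @rdname read_model
#' @param model A [risk_model()].
#' @return `write_model`: `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "riskviz_model"))
  doc <- list(
    predictors = lapply(unname(model$predictors), unclass),
    intercept = model$intercept,
    terms = lapply(unname(model$terms), function(t)
      list(id = t$id, predictors = as.list(t$predictors),
           coefficient = t$coefficient,
           transformation = transform_to_doc(t$transformation))),
    link = {
      l <- unclass(model$link)
      if (l$family == "cox") {
        l$baseline_survival <- as.list(l$baseline_survival)
        l$means <- as.list(l$means)
      }
      l
    })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a patient record from JSON
#'
#' A flat JSON object mapping predictor names to values.
#'
#' @param path JSON file path.
#' @return Named list of values.
#' @export
read_patient <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!is.list(doc) || is.null(names(doc)))
    stop("patient document must be a JSON object name -> value",
         call. = FALSE)
  doc
}

#' Read a training dataset from CSV
#'
#' The header row names the predictors; one row per individual. When a
#' model is given, column presence and continuous-column parseability are
#' checked with row/column diagnostics.
#'
#' @param path CSV file path.
#' @param model Optional [risk_model()] to validate against.
#' @return A data frame.
#' @export
read_dataset <- function(path, model = NULL) {
  data <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(data) == 0L)
    stop("dataset has no data rows: ", path, call. = FALSE)
  if (!is.null(model)) {
    missing_c <- setdiff(names(model$predictors), names(data))
    if (length(missing_c))
      stop("dataset lacks column(s): ", paste(missing_c, collapse = ", "),
           call. = FALSE)
    for (p in model$predictors) {
      if (p$kind != "continuous") next
      v <- suppressWarnings(as.numeric(data[[p$name]]))
      if (anyNA(v))
        stop("unparseable value in column '", p$name, "', row ",
             which(is.na(v))[1L], call. = FALSE)
      data[[p$name]] <- v
    }
  }
  data
}

#' Write/read a training summary as JSON
#'
#' @param summary A [compute_training_summary()] result.
#' @param path JSON file path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "riskviz_summary"))
  doc <- unclass(summary)
  # named atomic vectors serialize as arrays; keep names via lists
  doc$percentiles <- lapply(doc$percentiles, as.list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  doc <- jsonlite::read_json(path)
  doc$terms <- lapply(doc$terms, function(t)
    list(min = as.numeric(t$min), max = as.numeric(t$max)))
  doc$percentiles <- lapply(doc$percentiles, function(q)
    stats::setNames(as.numeric(unlist(q)), names(q)))
  doc$percentile_levels <- as.numeric(unlist(doc$percentile_levels))
  doc$score_min <- as.numeric(doc$score_min)
  doc$score_max <- as.numeric(doc$score_max)
  doc$n <- as.integer(doc$n)
  structure(doc, class = "riskviz_summary")
}
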