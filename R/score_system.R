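#' Point-based clinical score systems
#'
#' A score system discretizes a risk model: each predictor value falls into a
#' bin carrying an integer number of points, the points are summed into a
#' score, and an ordered conversion table maps score intervals to risk
#' estimates (the risk is a monotone, non-decreasing function of the score).
#'
#' Bin matches are one of: an exact level (`bin_level`), a single integer
#' value (`bin_value`), a closed integer range (`bin_range`), open-below
#' (`bin_below`, value < a) or open-above (`bin_above`, value > b). Printed
#' score tables report integer-valued measurements, so numeric inputs are
#' floored to an integer before lookup; a reading of 209.5 therefore falls
#' into a 170-209 bin rather than a gap between printed edges.
#'
#' @param level,points,value,a,b Bin definition; `points` must be an integer.
#' @name score_bins
NULL

new_bin <- function(type, points, ...) {
  points <- as.numeric(points)
  if (length(points) != 1L || !is.finite(points) || points != round(points))
    stop("bin points must be a finite integer", call. = FALSE)
  structure(c(list(type = type, points = as.integer(points)), list(...)),
            class = "riskviz_bin")
}

#' @rdname score_bins
#' @export
bin_level <- function(level, points) new_bin("level", points,
                                             level = as.character(level))

#' @rdname score_bins
#' @export
bin_value <- function(value, points) new_bin("value", points,
                                             a = as.numeric(value))

#' @rdname score_bins
#' @export
bin_range <- function(a, b, points) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a > b) stop("bin range bounds must be ordered", call. = FALSE)
  new_bin("range", points, a = a, b = b)
}

#' @rdname score_bins
#' @export
bin_below <- function(a, points) new_bin("below", points, a = as.numeric(a))

#' @rdname score_bins
#' @export
bin_above <- function(b, points) new_bin("above", points, b = as.numeric(b))

bin_matches <- function(bin, value) {
  if (bin$type == "level") return(as.character(value) == bin$level)
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) return(FALSE)
  v <- floor(v)
  switch(bin$type,
         value = v == bin$a,
         range = v >= bin$a && v <= bin$b,
         below = v < bin$a,
         above = v > bin$b)
}

#' Build a score table
#'
#' @param predictors Named list: predictor name -> list of bins (see
#'   [score_bins]).
#' @return A `riskviz_score_table`.
#' @export
score_table <- function(predictors) {
  stopifnot(is.list(predictors), length(predictors) > 0L,
            !is.null(names(predictors)))
  for (nm in names(predictors)) {
    bins <- predictors[[nm]]
    for (b in bins) stopifnot(inherits(b, "riskviz_bin"))
    check_bins(nm, bins)
  }
  structure(list(predictors = predictors), class = "riskviz_score_table")
}

# non-overlap + integer-lattice coverage between consecutive printed edges
check_bins <- function(name, bins) {
  types <- vapply(bins, `[[`, "", "type")
  if (any(types == "level")) {
    if (!all(types == "level"))
      stop("predictor '", name, "': level bins cannot mix with numeric bins",
           call. = FALSE)
    lv <- vapply(bins, `[[`, "", "level")
    if (anyDuplicated(lv))
      stop("predictor '", name, "': duplicate level bins (",
           lv[duplicated(lv)][1L], ")", call. = FALSE)
    return(invisible(TRUE))
  }
  lo <- vapply(bins, function(b) switch(b$type, below = -Inf, above = b$b + 1,
                                        value = b$a, range = b$a), numeric(1))
  hi <- vapply(bins, function(b) switch(b$type, below = b$a - 1, above = Inf,
                                        value = b$a, range = b$b), numeric(1))
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (length(bins) > 1L) {
    for (i in seq_len(length(bins) - 1L)) {
      if (lo[i + 1L] <= hi[i])
        stop("predictor '", name, "': overlapping bins near value ",
             lo[i + 1L], call. = FALSE)
      if (lo[i + 1L] > hi[i] + 1)
        stop("predictor '", name, "': integer gap between bin edges ",
             hi[i], " and ", lo[i + 1L], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a score-to-risk conversion table
#'
#' Entries are ordered by score and map a score interval (open-below, a
#' closed range, or a single score) to a printed risk label such as `"2%"` or
#' `"< 1%"`. Labels carrying a bound return the bound value and its
#' direction; no midpoint is invented. Risk values must be non-decreasing
#' with score.
#'
#' @param entries List of entries, each a list with `scores` (a bin built by
#'   [bin_below()], [bin_range()] or [bin_value()]) and `label`.
#' @return A `riskviz_risk_conversion`.
#' @export
risk_conversion <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0L)
  parsed <- lapply(entries, function(e) {
    stopifnot(inherits(e$scores, "riskviz_bin"), is.character(e$label))
    if (e$scores$type == "level")
      stop("conversion entries take numeric score bins", call. = FALSE)
    pr <- parse_risk_label(e$label)
    list(scores = e$scores, label = e$label, value = pr$value,
         bound = pr$bound)
  })
  check_bins("score", lapply(parsed, `[[`, "scores"))
  # order by interval start
  starts <- vapply(parsed, function(e)
    switch(e$scores$type, below = -Inf, value = e$scores$a,
           range = e$scores$a, above = e$scores$b + 1), numeric(1))
  parsed <- parsed[order(starts)]
  vals <- vapply(parsed, `[[`, numeric(1), "value")
  ok <- !is.na(vals)
  if (any(diff(vals[ok]) < 0))
    stop("risk values must be non-decreasing with score (offending entries: ",
         paste(vapply(parsed[ok][c(which(diff(vals[ok]) < 0),
                                   which(diff(vals[ok]) < 0) + 1L)],
                      `[[`, "", "label"), collapse = " vs "), ")",
         call. = FALSE)
  structure(list(entries = parsed), class = "riskviz_risk_conversion")
}

# "< 1%" -> value 1 bound "<"; "16%" -> 16, exact; "0.16" -> 0.16
parse_risk_label <- function(label) {
  s <- trimws(label)
  bound <- "exact"
  if (grepl("^[<>]", s)) {
    bound <- substr(s, 1L, 1L)
    s <- trimws(substring(s, 2L))
  }
  num <- suppressWarnings(as.numeric(sub("%$", "", s)))
  list(value = num, bound = bound)
}

#' Look up the points for one predictor value
#'
#' @param table A [score_table()].
#' @param predictor Predictor name present in the table.
#' @param value Level or numeric value; numeric values are floored to an
#'   integer before lookup.
#' @return Integer points of the unique matching bin.
#' @export
points_for <- function(table, predictor, value) {
  bins <- table$predictors[[predictor]]
  if (is.null(bins))
    stop("predictor '", predictor, "' is not in the score table",
         call. = FALSE)
  for (b in bins) if (bin_matches(b, value)) return(b$points)
  stop("value '", value, "' of predictor '", predictor,
       "' falls outside every score bin", call. = FALSE)
}

#' Total score of a patient
#'
#' @param table A [score_table()].
#' @param patient Named list covering every table predictor.
#' @return Integer sum of the per-predictor points.
#' @export
total_score <- function(table, patient) {
  patient <- as.list(patient)
  pts <- vapply(names(table$predictors), function(nm) {
    if (is.null(patient[[nm]]))
      stop("patient record lacks predictor '", nm, "'", call. = FALSE)
    points_for(table, nm, patient[[nm]])
  }, integer(1))
  sum(pts)
}

#' Convert a score to a risk estimate
#'
#' Scores beyond the last closed entry of the conversion table (printed
#' tables simply end) are mapped to the last entry's risk and flagged as
#' extrapolated.
#'
#' @param conv A [risk_conversion()].
#' @param score Integer score.
#' @return A list with `label`, `value` (numeric, `NA` if unparseable),
#'   `bound` (`"exact"`, `"<"` or `">"`) and `extrapolated`.
#' @export
risk_for_score <- function(conv, score) {
  for (e in conv$entries) {
    if (bin_matches(e$scores, score))
      return(list(label = e$label, value = e$value, bound = e$bound,
                  extrapolated = FALSE))
  }
  last <- conv$entries[[length(conv$entries)]]
  list(label = last$label, value = last$value, bound = last$bound,
       extrapolated = TRUE)
}

#' Maximum attainable total score of a table
#' @param table A [score_table()].
#' @export
max_attainable_score <- function(table) {
  sum(vapply(table$predictors, function(bins)
    max(vapply(bins, `[[`, integer(1), "points")), integer(1)))
}

#' Parse and validate a score-system document
#'
#' Reads a JSON document of the form
#' `{"predictors": [{"name", "bins": [{"match", "points"}]}],
#'   "conversion": [{"scores", "label"}]}`
#' where `match`/`scores` objects carry a `type` (`level`, `value`, `range`,
#' `below`, `above`) and its parameters. Overlaps, integer gaps and
#' non-monotone risks are rejected at parse time.
#'
#' @param document Path to a JSON file, or an already-parsed list.
#' @return A list with elements `table` ([score_table()]) and `conversion`
#'   ([risk_conversion()]).
#' @export
parse_score_system <- function(document) {
  doc <- if (is.character(document) && length(document) == 1L)
    jsonlite::read_json(document) else document
  if (is.null(doc$predictors) || is.null(doc$conversion))
    stop("score-system document needs 'predictors' and 'conversion'",
         call. = FALSE)
  preds <- list()
  for (p in doc$predictors) {
    bins <- lapply(p$bins, function(b)
      bin_from_match(b$match, b$points))
    preds[[p$name]] <- bins
  }
  entries <- lapply(doc$conversion, function(e)
    list(scores = bin_from_match(e$scores), label = e$label))
  list(table = score_table(preds), conversion = risk_conversion(entries))
}

bin_from_match <- function(m, points = 0L) {
  switch(m$type,
         level = bin_level(m$level, points),
         value = bin_value(m$value, points),
         range = bin_range(m$a, m$b, points),
         below = bin_below(m$a, points),
         above = bin_above(m$b, points),
         stop("unknown bin match type: ", m$type, call. = FALSE))
}

bin_to_match <- function(bin) {
  switch(bin$type,
         level = list(type = "level", level = bin$level),
         value = list(type = "value", value = bin$a),
         range = list(type = "range", a = bin$a, b = bin$b),
         below = list(type = "below", a = bin$a),
         above = list(type = "above", b = bin$b))
}

#' Serialize a score system to the JSON document form
#'
#' Inverse of [parse_score_system()]; round-trips losslessly.
#'
#' @param table A [score_table()].
#' @param conversion A [risk_conversion()].
#' @param path Optional file to write to.
#' @return The document list, invisibly when `path` is given.
#' @export
write_score_system <- function(table, conversion, path = NULL) {
  doc <- list(
    predictors = lapply(names(table$predictors), function(nm) list(
      name = nm,
      bins = lapply(table$predictors[[nm]], function(b)
        list(match = bin_to_match(b), points = b$points)))),
    conversion = lapply(conversion$entries, function(e)
      list(scores = bin_to_match(e$scores), label = e$label)))
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(doc))
  }
  doc
}
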