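#' Predictor transformations
#'
#' Effect terms apply a deterministic transformation to the raw predictor
#' value(s) before multiplication by the term coefficient. Five forms are
#' supported: the identity, a shifted power `(x - c)^k`, a scaled power
#' `((x - c) / s)^k`, a level indicator (1 when a categorical predictor equals
#' a given level, 0 otherwise), and the product of two sub-transformations
#' (one per predictor of an interaction term).
#'
#' @param c Shift constant.
#' @param k Exponent.
#' @param s Scale divisor (non-zero).
#' @param level Level that the indicator matches.
#' @param first,second Sub-transformations applied to the first and second
#'   predictor of an interaction term, in term order.
#' @return A `riskviz_transform` object.
#' @examples
#' tf <- transform_shifted_power(c = 60, k = 2)
#' eval_transform(tf, 62)  # (62 - 60)^2 = 4
#' @name transformations
NULL

new_transform <- function(form, ...) {
  structure(c(list(form = form), list(...)), class = "riskviz_transform")
}

#' @rdname transformations
#' @export
transform_identity <- function() new_transform("identity")

#' @rdname transformations
#' @export
transform_shifted_power <- function(c, k) {
  stopifnot(is.numeric(c), is.numeric(k), is.finite(c), is.finite(k))
  new_transform("shifted_power", c = as.numeric(c), k = as.numeric(k))
}

#' @rdname transformations
#' @export
transform_scaled_power <- function(c, s, k) {
  stopifnot(is.numeric(c), is.numeric(s), is.numeric(k), s != 0)
  new_transform("scaled_power", c = as.numeric(c), s = as.numeric(s),
                k = as.numeric(k))
}

#' @rdname transformations
#' @export
transform_level_indicator <- function(level) {
  stopifnot(length(level) == 1L)
  new_transform("level_indicator", level = as.character(level))
}

#' @rdname transformations
#' @export
transform_product <- function(first, second) {
  stopifnot(inherits(first, "riskviz_transform"),
            inherits(second, "riskviz_transform"))
  if (first$form == "product_of_two" || second$form == "product_of_two")
    stop("product transformations cannot be nested", call. = FALSE)
  new_transform("product_of_two", components = list(first, second))
}

#' Evaluate a transformation
#'
#' @param tf A `riskviz_transform`.
#' @param x Value(s) of the predictor; for `product_of_two`, a list of two
#'   vectors (one per involved predictor, in term order).
#' @return Numeric vector of transformed values.
#' @export
eval_transform <- function(tf, x) {
  stopifnot(inherits(tf, "riskviz_transform"))
  switch(tf$form,
    identity        = as.numeric(x),
    shifted_power   = (as.numeric(x) - tf$c)^tf$k,
    scaled_power    = ((as.numeric(x) - tf$c) / tf$s)^tf$k,
    level_indicator = as.numeric(as.character(x) == tf$level),
    product_of_two  = {
      stopifnot(is.list(x), length(x) == 2L)
      eval_transform(tf$components[[1L]], x[[1L]]) *
        eval_transform(tf$components[[2L]], x[[2L]])
    },
    stop("unknown transformation form: ", tf$form, call. = FALSE)
  )
}

#' @export
print.riskviz_transform <- function(x, ...) {
  desc <- switch(x$form,
    identity        = "x",
    shifted_power   = sprintf("(x - %g)^%g", x$c, x$k),
    scaled_power    = sprintf("((x - %g)/%g)^%g", x$c, x$s, x$k),
    level_indicator = sprintf("1[x == %s]", x$level),
    product_of_two  = "f1(x1) * f2(x2)")
  cat("<transform>", desc, "\n")
  invisible(x)
}
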