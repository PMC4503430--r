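#' Color map specifications
#'
#' Contributions are encoded by color. Two families are supported:
#'
#' * `sequential`: a perceptually ordered map for one-signed contributions
#'   (the default chart situation, where the observed-minimum reference makes
#'   all points non-negative). Anchors must have strictly monotone lightness;
#'   rainbow-style palettes, whose lightness cycles and introduces apparent
#'   sharp changes, are rejected at construction.
#' * `diverging`: a map with a well-defined midpoint, for referenced
#'   contributions that can be negative or positive (mean or custom
#'   reference). Requires an odd anchor count so a middle anchor exists.
#'
#' Colors are quantized into `steps` equal bins so a color can be read back
#' through a legend to its contribution within one color-step quantum.
#'
#' The default sequential palette runs dark green to light green to ecru
#' (low to high contribution), a colorblind- and print-safe ramp; its anchor
#' hexes are package constants.
#'
#' @param family `"sequential"` or `"diverging"`.
#' @param anchors Ordered anchor colors (hex or R color names); defaults per
#'   family.
#' @param steps Number of discrete color bins, integer >= 2.
#' @return A `riskviz_colormap`.
#' @export
colormap <- function(family = c("sequential", "diverging"), anchors = NULL,
                     steps = 64L) {
  family <- match.arg(family)
  if (is.null(anchors))
    anchors <- if (family == "sequential") sequential_anchors
               else diverging_anchors
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 2L)
    stop("steps must be an integer >= 2", call. = FALSE)
  if (length(anchors) < 2L)
    stop("at least 2 anchor colors are required", call. = FALSE)
  L <- anchor_lightness(anchors)
  if (family == "sequential") {
    d <- diff(L)
    if (!(all(d > 0) || all(d < 0)))
      stop("sequential anchors must have strictly monotone lightness; ",
           "rainbow-style palettes are not supported", call. = FALSE)
  } else {
    if (length(anchors) %% 2L == 0L)
      stop("diverging maps need an odd number of anchors (explicit middle)",
           call. = FALSE)
  }
  ramp <- grDevices::colorRamp(anchors, space = "Lab")
  structure(list(family = family, anchors = toupper(as_hex(anchors)),
                 steps = steps, ramp = ramp),
            class = "riskviz_colormap")
}

# dark green -> light green -> ecru (low -> high contribution)
sequential_anchors <- c("#00441B", "#41AB5D", "#A1D99B", "#F5F0DC")
# blue -> near-white -> red, midpoint at the middle anchor
diverging_anchors <- c("#2166AC", "#F7F7F7", "#B2182B")

as_hex <- function(cols) {
  m <- grDevices::col2rgb(cols)
  grDevices::rgb(m[1L, ], m[2L, ], m[3L, ], maxColorValue = 255)
}

anchor_lightness <- function(cols) {
  rgbm <- t(grDevices::col2rgb(cols)) / 255
  grDevices::convertColor(rgbm, from = "sRGB", to = "Lab")[, 1L]
}

# position in [0,1] -> quantized hex color
cmap_color_at <- function(cmap, t) {
  bin <- pmin(pmax(floor(t * cmap$steps), 0), cmap$steps - 1L)
  tq <- (bin + 0.5) / cmap$steps
  m <- cmap$ramp(tq)
  grDevices::rgb(m[, 1L], m[, 2L], m[, 3L], maxColorValue = 255)
}

#' Map a contribution value to a color
#'
#' Sequential maps place `lo` at the first anchor and `hi` at the last,
#' monotonically; diverging maps send `midpoint` to the middle anchor, with
#' the two half-ranges filling each side of the palette. Values outside the
#' range are clamped and flagged; a degenerate range (`lo == hi`) yields the
#' mid-palette color with a flag.
#'
#' @param value Numeric contribution value(s).
#' @param range `c(lo, hi)` of contributions the scale spans.
#' @param cmap A [colormap()].
#' @param midpoint Contribution mapped to the middle anchor (diverging only);
#'   default 0.
#' @return Hex color(s), with attributes `clamped` (logical vector) and
#'   `degenerate` (flag).
#' @export
map_contribution_to_color <- function(value, range, cmap = colormap(),
                                      midpoint = 0) {
  stopifnot(is.numeric(value), length(range) == 2L)
  lo <- range[1L]; hi <- range[2L]
  if (lo > hi) stop("range must satisfy lo <= hi", call. = FALSE)
  if (lo == hi) {
    out <- cmap_color_at(cmap, rep(0.5, length(value)))
    attr(out, "clamped") <- rep(FALSE, length(value))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  clamped <- value < lo | value > hi
  v <- pmin(pmax(value, lo), hi)
  if (cmap$family == "sequential") {
    t <- (v - lo) / (hi - lo)
  } else {
    if (midpoint < lo || midpoint > hi)
      stop("diverging midpoint must lie inside the range", call. = FALSE)
    t <- ifelse(v <= midpoint,
                if (midpoint > lo) 0.5 * (v - lo) / (midpoint - lo) else 0.5,
                if (hi > midpoint) 0.5 + 0.5 * (v - midpoint) / (hi - midpoint)
                else 0.5)
  }
  out <- cmap_color_at(cmap, t)
  attr(out, "clamped") <- clamped
  attr(out, "degenerate") <- FALSE
  out
}

#' Read a legend color back to a contribution
#'
#' Inverse lookup through the quantized scale: returns the center
#' contribution of the color bin a value's color falls in, so
#' `legend_lookup(map_contribution_to_color(x, r, cm), r, cm)` recovers `x`
#' within one color-step quantum.
#'
#' @param color Hex color produced by [map_contribution_to_color()].
#' @param range `c(lo, hi)` of the legend.
#' @param cmap The [colormap()] used.
#' @inheritParams map_contribution_to_color
#' @return Contribution value at the matched bin center.
#' @export
legend_lookup <- function(color, range, cmap = colormap(), midpoint = 0) {
  centers <- (seq_len(cmap$steps) - 0.5) / cmap$steps
  palette <- cmap_color_at(cmap, centers)
  idx <- match(toupper(color), toupper(palette))
  if (anyNA(idx))
    stop("color not on the legend scale", call. = FALSE)
  t <- centers[idx]
  lo <- range[1L]; hi <- range[2L]
  if (cmap$family == "sequential") {
    lo + t * (hi - lo)
  } else {
    ifelse(t <= 0.5, lo + (t / 0.5) * (midpoint - lo),
           midpoint + ((t - 0.5) / 0.5) * (hi - midpoint))
  }
}
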