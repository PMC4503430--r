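#' Chart scenes
#'
#' All chart builders return a `riskviz_scene`: a backend-independent,
#' JSON-serializable description of bars, color segments, markers, legends
#' and annotation lines. Renderers turn scenes into SVG or PNG files;
#' serialized scenes double as golden files in structural tests.
#'
#' @name scenes
NULL

new_scene <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "riskviz_scene")
}

#' @export
print.riskviz_scene <- function(x, ...) {
  cat(sprintf("<riskviz_scene:%s> %d bar(s), %d panel(s)\n", x$kind,
              length(x$bars),
              if (is.null(x$panels)) 0L else length(x$panels)))
  invisible(x)
}

#' Serialize a scene to JSON
#'
#' @param scene A `riskviz_scene`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param digits Number of significant digits kept for numeric fields
#'   (golden-file comparisons are tolerant of the last digit).
#' @return JSON string (invisibly when written to `path`).
#' @export
scene_to_json <- function(scene, path = NULL, digits = 10) {
  stopifnot(inherits(scene, "riskviz_scene"))
  json <- jsonlite::toJSON(unclass(scene), auto_unbox = TRUE,
                           digits = digits, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

## ---- layout: scene -> drawing primitives --------------------------------

prim_rect <- function(x, y, w, h, fill, stroke = "none") {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke)
}
prim_line <- function(x1, y1, x2, y2, stroke = "#000000", dash = FALSE) {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
       dash = dash)
}
prim_poly <- function(xs, ys, fill) {
  list(kind = "poly", xs = xs, ys = ys, fill = fill)
}
prim_text <- function(x, y, text, size = 11, anchor = "start",
                      fill = "#000000") {
  list(kind = "text", x = x, y = y, text = text, size = size,
       anchor = anchor, fill = fill)
}

# shared layout constants (pt)
.lay <- list(width = 760, margin = 40, bar_h = 26, gap = 34, label_w = 170,
             legend_w = 26, panel = 180)

scene_primitives <- function(scene) {
  switch(scene$kind,
         model_chart        = prims_model_chart(scene),
         score_system_chart = prims_model_chart(scene),
         contribution_chart = prims_contribution_chart(scene),
         cumulative_chart   = prims_cumulative_chart(scene),
         stop("cannot render scene of kind '", scene$kind, "'",
              call. = FALSE))
}

bar_track <- function() {
  x0 <- .lay$margin + .lay$label_w
  c(x0, .lay$width - .lay$margin - .lay$legend_w - 40)
}

# x position of a predictor value on a bar
value_pos <- function(bar, value, track) {
  if (!is.null(bar$kind) && bar$kind == "continuous") {
    lo <- bar$domain[1L]; hi <- bar$domain[2L]
    f <- (as.numeric(value) - lo) / (hi - lo)
  } else if (!is.null(bar$positions)) {
    i <- match(as.character(value), as.character(bar$positions))
    f <- (i - 0.5) / length(bar$positions)
  } else f <- 0.5
  track[1L] + max(0, min(1, f)) * diff(track)
}

prims_model_chart <- function(scene) {
  prims <- list()
  track <- bar_track()
  y <- .lay$margin
  bar_y <- c()
  for (b in scene$bars) {
    nm <- if (!is.null(b$predictor)) b$predictor else b$term_id
    prims[[length(prims) + 1L]] <-
      prim_text(.lay$margin, y + .lay$bar_h - 8, nm)
    n <- length(b$colors)
    w <- diff(track) / n
    for (i in seq_len(n))
      prims[[length(prims) + 1L]] <-
        prim_rect(track[1L] + (i - 1) * w, y, w, .lay$bar_h, b$colors[i])
    # integer point labels for score-system bars
    if (!is.null(b$labels))
      for (i in seq_len(n))
        prims[[length(prims) + 1L]] <-
          prim_text(track[1L] + (i - 0.5) * w, y + .lay$bar_h - 8,
                    b$labels[i], size = 10, anchor = "middle")
    # domain annotation under the bar
    dom <- if (!is.null(b$domain) && is.numeric(b$domain))
      sprintf("%g - %g %s", b$domain[1L], b$domain[2L],
              if (nzchar(b$unit %||% "")) b$unit else "")
    else NULL
    if (!is.null(dom))
      prims[[length(prims) + 1L]] <-
        prim_text(track[1L], y + .lay$bar_h + 12, trimws(dom), size = 9)
    bar_y[length(bar_y) + 1L] <- y
    names(bar_y)[length(bar_y)] <-
      if (!is.null(b$term_id)) b$term_id else b$predictor
    y <- y + .lay$bar_h + .lay$gap
  }

  panel_xy <- list()
  for (p in (scene$panels %||% list())) {
    prims[[length(prims) + 1L]] <-
      prim_text(.lay$margin, y + 12, paste(p$predictors, collapse = " x "))
    px <- track[1L]; py <- y + 20
    nc <- ncol(p$colors); nr <- nrow(p$colors)
    cw <- .lay$panel / nr; ch <- .lay$panel / nc
    for (i in seq_len(nr)) for (j in seq_len(nc))
      prims[[length(prims) + 1L]] <-
        prim_rect(px + (i - 1) * cw, py + (nc - j) * ch, cw, ch,
                  p$colors[i, j])
    panel_xy[[p$term_id]] <- list(x = px, y = py, p = p)
    y <- y + .lay$panel + .lay$gap + 20
  }

  # legend ruler on the right
  if (!is.null(scene$legend)) {
    lx <- .lay$width - .lay$margin - .lay$legend_w
    lh <- max(140, y - 2 * .lay$margin)
    n <- length(scene$legend$colors)
    for (i in seq_len(n))
      prims[[length(prims) + 1L]] <-
        prim_rect(lx, .lay$margin + lh - i * lh / n, .lay$legend_w, lh / n,
                  scene$legend$colors[i])
    prims[[length(prims) + 1L]] <-
      prim_text(lx, .lay$margin + lh + 12,
                sprintf("%.3g", scene$legend$range[1L]), size = 9)
    prims[[length(prims) + 1L]] <-
      prim_text(lx, .lay$margin - 6,
                sprintf("%.3g", scene$legend$range[2L]), size = 9)
  }

  # score-to-risk bar
  sb <- scene$score_bar
  sb_y <- y
  if (!is.null(sb)) {
    prims[[length(prims) + 1L]] <- prim_text(.lay$margin, y + .lay$bar_h - 8,
                                             "score -> risk")
    n <- length(sb$colors)
    w <- diff(track) / n
    for (i in seq_len(n))
      prims[[length(prims) + 1L]] <-
        prim_rect(track[1L] + (i - 1) * w, y, w, .lay$bar_h, sb$colors[i])
    if (!is.null(sb$labels))
      for (i in seq_len(n))
        prims[[length(prims) + 1L]] <-
          prim_text(track[1L] + (i - 0.5) * w, y + .lay$bar_h + 12,
                    sb$labels[i], size = 8, anchor = "middle")
    if (!is.null(sb$scores)) {
      prims[[length(prims) + 1L]] <-
        prim_text(track[1L], y + .lay$bar_h + 12,
                  sprintf("%.3g", sb$scores[1L]), size = 9)
      prims[[length(prims) + 1L]] <-
        prim_text(track[2L], y + .lay$bar_h + 12,
                  sprintf("%.3g", sb$scores[length(sb$scores)]), size = 9,
                  anchor = "end")
    }
    y <- y + .lay$bar_h + .lay$gap
  }

  # percentile dashed lines
  for (ln in (scene$percentile_lines %||% list())) {
    key <- ln$term_id %||% ln$predictor
    if (!key %in% names(bar_y)) next
    b <- scene$bars[[match(key, names(bar_y))]]
    x <- value_pos(b, ln$value, track)
    prims[[length(prims) + 1L]] <-
      prim_line(x, bar_y[[key]] - 4, x, bar_y[[key]] + .lay$bar_h + 4,
                stroke = "#888888", dash = TRUE)
  }

  # patient markers
  for (m in (scene$markers %||% list())) {
    if (m$target == "bar") {
      key <- m$term_id %||% m$predictor
      if (!key %in% names(bar_y)) next
      b <- scene$bars[[match(key, names(bar_y))]]
      x <- value_pos(b, m$value, track)
      yb <- bar_y[[key]]
      prims[[length(prims) + 1L]] <-
        prim_poly(c(x - 5, x + 5, x), c(yb - 8, yb - 8, yb), "#1F3B99")
    } else if (m$target == "panel" && !is.null(panel_xy[[m$term_id]])) {
      pp <- panel_xy[[m$term_id]]
      fx <- panel_frac(pp$p$x_kind, pp$p$x_domain, pp$p$x_positions,
                       m$value[[1L]])
      fy <- panel_frac(pp$p$y_kind, pp$p$y_domain, pp$p$y_positions,
                       m$value[[2L]])
      cx <- pp$x + fx * .lay$panel
      cy <- pp$y + (1 - fy) * .lay$panel
      prims[[length(prims) + 1L]] <-
        prim_poly(c(cx, cx + 5, cx, cx - 5), c(cy - 5, cy, cy + 5, cy),
                  "#1F3B99")
    } else if (m$target == "score_bar" && !is.null(sb)) {
      f <- if (!is.null(sb$scores)) {
        rng <- range(sb$scores)
        if (diff(rng) > 0) (m$value - rng[1L]) / diff(rng) else 0.5
      } else 0.5
      f <- max(0, min(1, f))
      x <- track[1L] + f * diff(track)
      prims[[length(prims) + 1L]] <-
        prim_poly(c(x - 5, x + 5, x), c(sb_y - 8, sb_y - 8, sb_y), "#1F3B99")
    }
  }

  attr(prims, "size") <- c(.lay$width, y + .lay$margin)
  prims
}

panel_frac <- function(kind, domain, positions, value) {
  if (kind == "continuous") {
    f <- (as.numeric(value) - domain[1L]) / (domain[2L] - domain[1L])
  } else {
    i <- match(as.character(value), as.character(positions))
    f <- (i - 0.5) / length(positions)
  }
  max(0, min(1, f))
}

prims_contribution_chart <- function(scene) {
  prims <- list()
  track <- bar_track()
  rng <- range(0, unlist(lapply(scene$bars, `[[`, "whisker")),
               vapply(scene$bars, `[[`, numeric(1), "points"))
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  to_x <- function(v) track[1L] + (v - rng[1L]) / diff(rng) * diff(track)
  y <- .lay$margin
  for (b in scene$bars) {
    prims[[length(prims) + 1L]] <-
      prim_text(.lay$margin, y + .lay$bar_h - 8, b$term_id)
    x0 <- to_x(min(0, b$points)); x1 <- to_x(max(0, b$points))
    prims[[length(prims) + 1L]] <-
      prim_rect(x0, y, max(x1 - x0, 0.5), .lay$bar_h, "#9E9E9E")
    # whisker: training min/max of this term's referenced contribution
    wx <- to_x(b$whisker)
    ym <- y + .lay$bar_h / 2
    prims[[length(prims) + 1L]] <- prim_line(wx[1L], ym, wx[2L], ym)
    for (wxx in wx)
      prims[[length(prims) + 1L]] <-
        prim_line(wxx, y + 4, wxx, y + .lay$bar_h - 4)
    prims[[length(prims) + 1L]] <-
      prim_text(track[2L] + 8, y + .lay$bar_h - 8, b$label,
                fill = "#1F3B99", size = 10)
    y <- y + .lay$bar_h + 12
  }
  y <- y + 10
  prims[[length(prims) + 1L]] <-
    prim_text(.lay$margin, y,
              sprintf("score: %.4g   risk: %.4g", scene$total_score,
                      scene$risk))
  attr(prims, "size") <- c(.lay$width, y + .lay$margin)
  prims
}

prims_cumulative_chart <- function(scene) {
  prims <- list()
  track <- bar_track()
  ends <- vapply(scene$bars, `[[`, numeric(1), "end")
  starts <- vapply(scene$bars, `[[`, numeric(1), "start")
  rng <- range(0, starts, ends, scene$max_score_bar$end)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  to_x <- function(v) track[1L] + (v - rng[1L]) / diff(rng) * diff(track)
  y <- .lay$margin
  for (b in scene$bars) {
    prims[[length(prims) + 1L]] <-
      prim_text(.lay$margin, y + .lay$bar_h - 8, b$term_id)
    x0 <- to_x(min(b$start, b$end)); x1 <- to_x(max(b$start, b$end))
    fill <- if (isTRUE(b$reversed)) "#BDBDBD" else "#9E9E9E"
    prims[[length(prims) + 1L]] <-
      prim_rect(x0, y, max(x1 - x0, 0.5), .lay$bar_h, fill)
    prims[[length(prims) + 1L]] <-
      prim_text(track[2L] + 8, y + .lay$bar_h - 8, b$label,
                fill = "#1F3B99", size = 10)
    y <- y + .lay$bar_h + 8
  }
  rows <- list(
    list(lab = "score", x0 = scene$score_bar$start,
         x1 = scene$score_bar$end, fill = "#616161"),
    list(lab = "max score", x0 = scene$max_score_bar$start,
         x1 = scene$max_score_bar$end, fill = "#616161"),
    list(lab = sprintf("risk %.3g", scene$risk_bar$risk), x0 = rng[1L],
         x1 = rng[1L] + scene$risk_bar$risk /
           max(scene$risk_bar$risk, scene$max_risk_bar$risk) * diff(rng),
         fill = scene$risk_bar$color),
    list(lab = sprintf("max risk %.3g", scene$max_risk_bar$risk),
         x0 = rng[1L], x1 = rng[2L], fill = scene$max_risk_bar$color))
  y <- y + 10
  for (r in rows) {
    prims[[length(prims) + 1L]] <-
      prim_text(.lay$margin, y + .lay$bar_h - 8, r$lab)
    prims[[length(prims) + 1L]] <-
      prim_rect(to_x(min(r$x0, r$x1)), y,
                max(to_x(max(r$x0, r$x1)) - to_x(min(r$x0, r$x1)), 0.5),
                .lay$bar_h, r$fill)
    y <- y + .lay$bar_h + 8
  }
  attr(prims, "size") <- c(.lay$width, y + .lay$margin)
  prims
}

## ---- output backends -----------------------------------------------------

#' Render a scene to SVG or PNG
#'
#' SVG output is written directly from the scene's drawing primitives and is
#' byte-stable: rendering the same scene twice yields identical files. PNG
#' output rasterizes the same primitives through the `grid` engine.
#'
#' @param scene A `riskviz_scene` with at least one bar or panel.
#' @param path Output file path.
#' @param format `"svg"` or `"png"` (default: from the file extension).
#' @param dpi Raster resolution for PNG (default 96).
#' @return `path`, invisibly.
#' @export
render <- function(scene, path, format = NULL, dpi = 96) {
  stopifnot(inherits(scene, "riskviz_scene"))
  n_items <- length(scene$bars) +
    length(scene$panels %||% list())
  if (n_items == 0L)
    stop("scene has no bars or panels to render", call. = FALSE)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("svg", "png"))
  prims <- scene_primitives(scene)
  size <- attr(prims, "size")
  if (format == "svg") write_svg(prims, size, path)
  else write_png(prims, size, path, dpi)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.2f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

write_svg <- function(prims, size, path) {
  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
           'height="%s" viewBox="0 0 %s %s">'),
    fmt_num(size[1L]), fmt_num(size[2L]), fmt_num(size[1L]),
    fmt_num(size[2L])),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
            fmt_num(size[1L]), fmt_num(size[2L])))
  for (p in prims) {
    out <- c(out, switch(p$kind,
      rect = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
        fmt_num(p$x), fmt_num(p$y), fmt_num(p$w), fmt_num(p$h), p$fill,
        if (p$stroke != "none")
          sprintf(' stroke="%s"', p$stroke) else ""),
      line = sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"%s/>',
        fmt_num(p$x1), fmt_num(p$y1), fmt_num(p$x2), fmt_num(p$y2),
        p$stroke,
        if (isTRUE(p$dash)) ' stroke-dasharray="4 3"' else ""),
      poly = sprintf('<polygon points="%s" fill="%s"/>',
        paste(sprintf("%s,%s", fmt_num(p$xs), fmt_num(p$ys)),
              collapse = " "), p$fill),
      text = sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="%s" fill="%s">%s</text>',
        fmt_num(p$x), fmt_num(p$y), fmt_num(p$size),
        c(start = "start", middle = "middle", end = "end")[[p$anchor]],
        p$fill, xml_escape(p$text))))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_png <- function(prims, size, path, dpi) {
  grDevices::png(path, width = size[1L] / 72 * dpi,
                 height = size[2L] / 72 * dpi, res = dpi, bg = "white")
  on.exit(grDevices::dev.off())
  grid::grid.newpage()
  # y grows downward to match the SVG coordinate system
  vp <- grid::viewport(xscale = c(0, size[1L]), yscale = c(size[2L], 0))
  grid::pushViewport(vp)
  for (p in prims) {
    switch(p$kind,
      rect = grid::grid.rect(
        x = grid::unit(p$x, "native"), y = grid::unit(p$y + p$h, "native"),
        width = grid::unit(p$w, "native"),
        height = grid::unit(p$h, "native"),
        just = c("left", "bottom"),
        gp = grid::gpar(fill = p$fill, col = if (p$stroke == "none") NA
                        else p$stroke)),
      line = grid::grid.lines(
        x = grid::unit(c(p$x1, p$x2), "native"),
        y = grid::unit(c(p$y1, p$y2), "native"),
        gp = grid::gpar(col = p$stroke,
                        lty = if (isTRUE(p$dash)) "dashed" else "solid")),
      poly = grid::grid.polygon(
        x = grid::unit(p$xs, "native"), y = grid::unit(p$ys, "native"),
        gp = grid::gpar(fill = p$fill, col = NA)),
      text = grid::grid.text(
        p$text, x = grid::unit(p$x, "native"),
        y = grid::unit(p$y, "native"),
        just = switch(p$anchor, start = c("left", "bottom"),
                      middle = c("centre", "bottom"),
                      end = c("right", "bottom")),
        gp = grid::gpar(fontsize = p$size, col = p$fill)))
  }
  grid::popViewport()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
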