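# structural fingerprint of a scene, compared against checked-in golden
# JSON: element counts, identities and labels, not colors or geometry
scene_structure <- function(scene) {
  null_or <- function(x) if (is.null(x)) NULL else x
  list(
    kind = scene$kind,
    bars = lapply(scene$bars, function(b) {
      out <- list(id = if (!is.null(b$term_id)) b$term_id else b$predictor,
                  segments = length(b$colors))
      if (!is.null(b$labels)) out$labels <- as.list(b$labels)
      out
    }),
    panels = lapply(scene$panels, function(p)
      list(id = p$term_id, dim = as.list(dim(p$colors)))),
    legend_steps = null_or(scene$legend$steps),
    score_segments = null_or(length(scene$score_bar$colors)),
    marker_targets = if (is.null(scene$markers)) NULL else
      as.list(vapply(scene$markers, `[[`, "", "target")),
    percentile_lines = if (is.null(scene$percentile_lines)) NULL else
      length(scene$percentile_lines))
}
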