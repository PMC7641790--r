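# Time belts: one horizontal row per session, color-coded segments with
# widths proportional to duration. Gaps render as unfilled space (idle time).

timebelt_palette <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
  "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
  "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
  "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5"
)

#' Assign stable colors to task labels
#'
#' Labels are sorted and mapped against a fixed 20-color qualitative
#' palette (cycling beyond 20), so the same label always receives the same
#' color for a given label set, across rows and across runs.
#'
#' @param labels Character vector of task labels.
#' @return Named character vector label -> hex color.
#' @export
task_colors <- function(labels) {
  labels <- sort(unique(labels))
  idx <- ((seq_along(labels) - 1L) %% length(timebelt_palette)) + 1L
  stats::setNames(timebelt_palette[idx], labels)
}

#' Lay out time belts for one or more sessions
#'
#' Converts sessions to drawing geometry: each segment becomes a bar at
#' `x_offset = start_s * scale` with `width = duration_s * scale`; identical
#' task labels share a color across all rows.
#'
#' @param sessions List of [session()] objects (a single session is
#'   accepted).
#' @param scale Drawing units per second; must be positive.
#' @return Object of class `timebelt_layout`: list with `bars` (data.frame
#'   `session_id`, `task_label`, `x_offset`, `width`, `color_key`), `rows`
#'   (data.frame `session_id`, `total_width`), `legend` (data.frame
#'   `task_label`, `color_key`) and `scale`.
#' @export
layout_timebelt <- function(sessions, scale = 1) {
  if (inherits(sessions, "ehr_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L, is.numeric(scale), scale > 0)
  labels <- unique(unlist(lapply(sessions, function(s) s$segments$task)))
  cols <- task_colors(labels)
  bars <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(
      session_id = s$session_id,
      task_label = s$segments$task,
      x_offset = s$segments$start_s * scale,
      width = s$segments$duration_s * scale,
      color_key = unname(cols[s$segments$task]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(bars) <- NULL
  rows <- data.frame(
    session_id = vapply(sessions, function(s) s$session_id, character(1)),
    total_width = vapply(sessions, function(s) max(s$segments$end_s) * scale,
                         numeric(1)),
    stringsAsFactors = FALSE
  )
  legend <- data.frame(task_label = names(cols), color_key = unname(cols),
                       stringsAsFactors = FALSE)
  structure(list(bars = bars, rows = rows, legend = legend, scale = scale),
            class = "timebelt_layout")
}

#' @export
print.timebelt_layout <- function(x, ...) {
  cat(sprintf("<timebelt_layout> %d row(s), %d bar(s), %d task label(s)\n",
              nrow(x$rows), nrow(x$bars), nrow(x$legend)))
  invisible(x)
}

#' Render a time belt layout as SVG
#'
#' One rectangle per bar, rows stacked vertically with the session id as a
#' left-hand label, idle gaps left unfilled, and a color legend underneath.
#' Identical input yields byte-identical output.
#'
#' @param layout A [layout_timebelt()] result.
#' @param row_height Bar height, px.
#' @param row_gap Vertical gap between rows, px.
#' @param label_width Width reserved for row labels, px.
#' @param legend Logical; draw the legend.
#' @return SVG document as a single character string.
#' @export
render_timebelt <- function(layout, row_height = 24, row_gap = 10,
                            label_width = 90, legend = TRUE) {
  rows <- layout$rows
  bars <- layout$bars
  belt_w <- max(rows$total_width, 1)
  n <- nrow(rows)
  legend_h <- if (legend) 22 * ceiling(nrow(layout$legend) / 3) + 10 else 0
  height <- n * (row_height + row_gap) + legend_h + 10
  width <- label_width + belt_w + 20

  body <- character(0)
  for (r in seq_len(n)) {
    y <- 5 + (r - 1L) * (row_height + row_gap)
    body <- c(body, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="11" text-anchor="end">%s</text>',
      fmt(label_width - 6), fmt(y + row_height / 2 + 4),
      xml_escape(rows$session_id[r])
    ))
    rb <- bars[bars$session_id == rows$session_id[r], , drop = FALSE]
    for (i in seq_len(nrow(rb))) {
      body <- c(body, sprintf(
        '<rect class="belt-bar" x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s</title></rect>',
        fmt(label_width + rb$x_offset[i]), fmt(y), fmt(rb$width[i]),
        fmt(row_height), rb$color_key[i], xml_escape(rb$task_label[i])
      ))
    }
  }
  if (legend) {
    y0 <- n * (row_height + row_gap) + 15
    for (i in seq_len(nrow(layout$legend))) {
      cx <- label_width + ((i - 1L) %% 3L) * (belt_w / 3)
      cy <- y0 + ((i - 1L) %/% 3L) * 22
      body <- c(body,
        sprintf('<rect x="%s" y="%s" width="14" height="14" fill="%s"/>',
                fmt(cx), fmt(cy), layout$legend$color_key[i]),
        sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="11">%s</text>',
                fmt(cx + 18), fmt(cy + 11),
                xml_escape(layout$legend$task_label[i]))
      )
    }
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            fmt(width), fmt(height), fmt(width), fmt(height)),
    paste(body, collapse = "\n"),
    "\n</svg>\n"
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
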