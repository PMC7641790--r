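# Radial partition layout: concentric rings are hierarchy levels, angular
# sectors are sibling items. Ring index = depth - 1; the root is the center
# disc (ring -1 by convention).

#' Compute sunburst geometry for a navigation tree
#'
#' Assigns every node an angular interval: the root spans the full circle,
#' and each node's interval is partitioned among its children either equally
#' (`equal_split`) or proportionally to the number of leaf descendants
#' (`leaf_weighted`, default — bushy subtrees get more arc). Child intervals
#' are laid out in sibling order; the last child's end is pinned to the
#' parent's end so children always partition the parent exactly.
#'
#' @param tree A [nav_tree()].
#' @param weighting `"leaf_weighted"` or `"equal_split"`.
#' @return data.frame of class `sunburst_layout`: one row per node with
#'   `node_id`, `ring` (depth - 1; -1 marks the root/center disc),
#'   `start_angle_deg`, `end_angle_deg`, `fill_class` (`"target"` for
#'   flagged nodes, else `"default"`).
#' @export
layout_sunburst <- function(tree, weighting = c("leaf_weighted", "equal_split")) {
  weighting <- match.arg(weighting)
  validate_nav_tree(tree)
  ids <- preorder_ids(tree)
  seg <- data.frame(
    node_id = ids,
    ring = vapply(tree$nodes[ids], function(n) n$depth, integer(1)) - 1L,
    start_angle_deg = NA_real_, end_angle_deg = NA_real_,
    fill_class = ifelse(
      vapply(tree$nodes[ids], function(n) n$is_target, logical(1)),
      "target", "default"),
    stringsAsFactors = FALSE
  )
  rownames(seg) <- seg$node_id
  assign_arc <- function(id, a0, a1) {
    seg[id, "start_angle_deg"] <<- a0
    seg[id, "end_angle_deg"] <<- a1
    kids <- tree$nodes[[id]]$children
    if (!length(kids)) return(invisible())
    w <- switch(weighting,
      equal_split = rep(1, length(kids)),
      leaf_weighted = vapply(kids, function(k) as.numeric(n_leaf_descendants(tree, k)),
                             numeric(1))
    )
    bounds <- a0 + (a1 - a0) * cumsum(w) / sum(w)
    bounds[length(bounds)] <- a1   # pin: children partition the parent exactly
    starts <- c(a0, bounds[-length(bounds)])
    for (i in seq_along(kids)) assign_arc(kids[[i]], starts[[i]], bounds[[i]])
  }
  assign_arc(tree$root_id, 0, 360)
  class(seg) <- c("sunburst_layout", class(seg))
  seg
}

#' Highlight a traced pathway on a sunburst layout
#'
#' Marks every segment whose node lies on the pathway (including the root
#' screen the pathway starts from) with `fill_class = "highlight"`. Targets
#' not on the pathway keep their `"target"` class; all other segments are
#' unchanged. Repeated calls highlight the union of the pathways.
#'
#' @param segments A [layout_sunburst()] result.
#' @param pathway A [trace_pathway()] result.
#' @return The layout with updated `fill_class`.
#' @export
highlight_pathway <- function(segments, pathway) {
  if (nrow(pathway$steps) == 0L && length(pathway$target_order) == 0L) {
    return(segments)
  }
  ids <- unique(c(pathway$steps$node_id, pathway$target_order))
  root_row <- which(segments$ring == -1L)
  if (length(root_row)) ids <- unique(c(segments$node_id[root_row], ids))
  missing <- setdiff(ids, segments$node_id)
  if (length(missing)) {
    stop("pathway node(s) without a segment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  segments$fill_class[segments$node_id %in% ids] <- "highlight"
  segments
}

sunburst_palette <- c(
  default = "#d4d4d4",
  target = "#000000",      # task-relevant elements shaded black
  highlight = "#2ca02c",   # traced pathway in green
  irrelevant = "#f5f5f5"
)

polar_xy <- function(cx, cy, r, deg) {
  # 0 deg at 12 o'clock, increasing clockwise
  rad <- (deg - 90) * pi / 180
  c(cx + r * cos(rad), cy + r * sin(rad))
}

fmt <- function(x) sprintf("%.3f", x)

annular_sector_path <- function(cx, cy, r0, r1, a0, a1) {
  if (a1 - a0 >= 360 - 1e-9) {
    # full ring: outer circle minus inner circle, even-odd fill
    circ <- function(r) {
      p1 <- polar_xy(cx, cy, r, 0); p2 <- polar_xy(cx, cy, r, 180)
      sprintf("M %s %s A %s %s 0 1 1 %s %s A %s %s 0 1 1 %s %s Z",
              fmt(p1[1]), fmt(p1[2]), fmt(r), fmt(r), fmt(p2[1]), fmt(p2[2]),
              fmt(r), fmt(r), fmt(p1[1]), fmt(p1[2]))
    }
    return(paste(circ(r1), circ(r0)))
  }
  large <- if (a1 - a0 > 180) 1L else 0L
  o0 <- polar_xy(cx, cy, r1, a0); o1 <- polar_xy(cx, cy, r1, a1)
  i1 <- polar_xy(cx, cy, r0, a1); i0 <- polar_xy(cx, cy, r0, a0)
  sprintf(
    "M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
    fmt(o0[1]), fmt(o0[2]), fmt(r1), fmt(r1), large, fmt(o1[1]), fmt(o1[2]),
    fmt(i1[1]), fmt(i1[2]), fmt(r0), fmt(r0), large, fmt(i0[1]), fmt(i0[2])
  )
}

#' Render a sunburst layout as SVG
#'
#' Draws the root as a center disc and every other segment as an annular
#' sector, colored by `fill_class` through a fixed palette. Output is a
#' self-contained SVG 1.1 document; identical input yields byte-identical
#' output.
#'
#' @param segments A [layout_sunburst()] result.
#' @param size Canvas width/height in pixels.
#' @param palette Named vector of fill colors for the fill classes.
#' @param center_radius Radius of the root disc, px.
#' @return SVG document as a single character string.
#' @export
render_sunburst <- function(segments, size = 600,
                            palette = sunburst_palette,
                            center_radius = 40) {
  cx <- size / 2; cy <- size / 2
  n_rings <- max(c(segments$ring, 0L)) + 1L
  thick <- (size / 2 - 10 - center_radius) / max(n_rings, 1L)
  col <- function(cls) {
    v <- palette[cls]
    ifelse(is.na(v), palette[["default"]], v)
  }
  body <- character(0)
  root_row <- which(segments$ring == -1L)
  if (length(root_row)) {
    body <- c(body, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#ffffff" stroke-width="1"/>',
      fmt(cx), fmt(cy), fmt(center_radius),
      col(segments$fill_class[root_row[1L]])
    ))
  }
  sect <- segments[segments$ring >= 0L, , drop = FALSE]
  if (nrow(sect)) {
    for (i in seq_len(nrow(sect))) {
      r0 <- center_radius + sect$ring[i] * thick
      r1 <- r0 + thick
      body <- c(body, sprintf(
        '<path d="%s" fill="%s" fill-rule="evenodd" stroke="#ffffff" stroke-width="1"/>',
        annular_sector_path(cx, cy, r0, r1, sect$start_angle_deg[i],
                            sect$end_angle_deg[i]),
        col(sect$fill_class[i])
      ))
    }
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">\n',
            as.integer(size), as.integer(size), as.integer(size),
            as.integer(size)),
    paste(body, collapse = "\n"),
    "\n</svg>\n"
  )
}

#' Re-root a sunburst on a subtree
#'
#' Drill-down: extracts the subtree under `id` and lays it out as its own
#' sunburst, with `id` as the new center disc.
#'
#' @param tree A `nav_tree`.
#' @param id Node to re-root on.
#' @param ... Passed to [layout_sunburst()].
#' @return A `sunburst_layout` for the subtree.
#' @export
layout_sunburst_subtree <- function(tree, id, ...) {
  if (!id %in% node_ids(tree)) stop("unknown node id: ", id, call. = FALSE)
  keep <- character(0)
  walk <- function(x) {
    keep <<- c(keep, x)
    for (ch in tree$nodes[[x]]$children) walk(ch)
  }
  walk(id)
  sub_nodes <- tree$nodes[keep]
  sub_nodes[[id]]$parent_id <- NA_character_
  sub <- nav_tree(sub_nodes, id)
  layout_sunburst(sub, ...)
}

#' Write an SVG document to disk
#'
#' @param svg Character scalar returned by a renderer.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(svg), con)
  invisible(path)
}
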