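#' Detect pogo-sticking in a session
#'
#' Pogo-sticking is repeated back-and-forth navigation between two elements
#' or sections — e.g. checking the same two items three times each. The
#' session's segment sequence (screen ids when recorded, task labels
#' otherwise, with consecutive repeats collapsed) is scanned for maximal
#' alternating runs X, Y, X, Y, ...; a run is reported when each member
#' occurs at least `min_repeats` times.
#'
#' @param session An [session()] object.
#' @param min_repeats Minimum visits to each member of the pair.
#' @param on `"auto"` (screen ids when any are recorded, else task labels),
#'   `"screen_id"` or `"task"`.
#' @return data.frame with one row per finding: `label_a`, `label_b`,
#'   `count_a`, `count_b`, `window_start_s`, `window_end_s`,
#'   `window_time_s` (time actually spent in segments of the window).
#'   Zero rows when no alternation qualifies.
#' @export
detect_pogo_sticking <- function(session, min_repeats = 3L,
                                 on = c("auto", "screen_id", "task")) {
  on <- match.arg(on)
  seg <- session$segments
  use_screen <- switch(on,
    auto = any(!is.na(seg$screen_id)),
    screen_id = TRUE,
    task = FALSE
  )
  key <- if (use_screen) as.character(seg$screen_id) else seg$task

  # collapse consecutive repeats: staying put is not navigation
  keep <- c(TRUE, key[-1L] != key[-length(key)])
  key <- key[keep]
  first_idx <- which(keep)
  last_idx <- c(first_idx[-1L] - 1L, nrow(seg))

  empty <- data.frame(
    label_a = character(0), label_b = character(0),
    count_a = integer(0), count_b = integer(0),
    window_start_s = numeric(0), window_end_s = numeric(0),
    window_time_s = numeric(0), stringsAsFactors = FALSE
  )
  m <- length(key)
  if (m < 3L) return(empty)

  out <- empty
  i <- 1L
  while (i <= m - 2L) {
    j <- i + 2L
    if (key[j] != key[i]) { i <- i + 1L; next }
    while (j + 1L <= m && key[j + 1L] == key[j - 1L]) j <- j + 1L
    len <- j - i + 1L
    count_first <- as.integer(ceiling(len / 2))
    count_second <- len - count_first
    if (min(count_first, count_second) >= min_repeats) {
      s0 <- first_idx[i]; s1 <- last_idx[j]
      out <- rbind(out, data.frame(
        label_a = key[i], label_b = key[i + 1L],
        count_a = count_first, count_b = count_second,
        window_start_s = seg$start_s[s0], window_end_s = seg$end_s[s1],
        window_time_s = sum(seg$duration_s[s0:s1]),
        stringsAsFactors = FALSE
      ))
    }
    i <- j - 1L   # last two entries may seed the next alternation
  }
  rownames(out) <- NULL
  out
}

#' Build a combined fragmentation report
#'
#' Assembles display-fragmentation results (DFI breakdowns and, with two
#' trees, their comparison), task-fragmentation results (per-session ACT and
#' PPI summaries), pogo-sticking findings with juxtaposition suggestions,
#' and the sunburst / time belt figures, into one deterministic bundle. All
#' numbers are taken directly from the underlying operations — nothing is
#' recomputed.
#'
#' @param trees List of up to two [nav_tree()] objects (named names are used
#'   as system labels).
#' @param sessions List of [session()] objects.
#' @param policy A [multiplier_policy()].
#' @param routing Pathway routing, see [trace_pathway()].
#' @param weighting Sunburst weighting, see [layout_sunburst()].
#' @param min_repeats Pogo-sticking threshold, see [detect_pogo_sticking()].
#' @param scale Time belt scale (drawing units per second).
#' @return Object of class `fragmentation_report`: list with elements
#'   `dfi` (breakdowns, optional `comparison`), `tasks` (per-session
#'   summaries), `pogo` (findings + `suggestions` ranked by recoverable
#'   window time) and `figures` (named SVG strings).
#' @export
build_report <- function(trees = list(), sessions = list(),
                         policy = multiplier_policy(),
                         routing = c("lca", "root"),
                         weighting = c("leaf_weighted", "equal_split"),
                         min_repeats = 3L, scale = 1) {
  routing <- match.arg(routing)
  weighting <- match.arg(weighting)
  if (inherits(trees, "nav_tree")) trees <- list(trees)
  if (inherits(sessions, "ehr_session")) sessions <- list(sessions)
  if (length(trees) == 0L && length(sessions) == 0L) {
    stop("empty report: supply at least one tree or one session",
         call. = FALSE)
  }
  if (length(trees) > 2L) stop("at most two trees are compared", call. = FALSE)
  if (is.null(names(trees)) && length(trees)) {
    names(trees) <- paste0("system_", seq_along(trees))
  }

  report <- list(dfi = NULL, tasks = NULL, pogo = NULL, figures = list())

  if (length(trees)) {
    breakdowns <- lapply(trees, function(tr) {
      dfi(tr, policy = policy, routing = routing)
    })
    report$dfi <- list(breakdowns = breakdowns)
    if (length(trees) == 2L) {
      report$dfi$comparison <- compare_systems(breakdowns[[1L]],
                                               breakdowns[[2L]])
    }
    for (nm in names(trees)) {
      lay <- layout_sunburst(trees[[nm]], weighting = weighting)
      lay <- highlight_pathway(lay, attr(breakdowns[[nm]], "pathway"))
      report$figures[[paste0("sunburst_", nm)]] <- render_sunburst(lay)
    }
  }

  if (length(sessions)) {
    report$tasks <- lapply(sessions, task_summary)
    names(report$tasks) <- vapply(sessions, function(s) s$session_id,
                                  character(1))
    findings <- lapply(sessions, detect_pogo_sticking,
                       min_repeats = min_repeats)
    names(findings) <- names(report$tasks)
    all_f <- do.call(rbind, lapply(names(findings), function(sid) {
      f <- findings[[sid]]
      if (nrow(f)) cbind(session_id = sid, f, stringsAsFactors = FALSE) else
        NULL
    }))
    suggestions <- if (!is.null(all_f) && nrow(all_f)) {
      s <- all_f[order(-all_f$window_time_s), , drop = FALSE]
      rownames(s) <- NULL
      data.frame(
        session_id = s$session_id,
        juxtapose_a = s$label_a, juxtapose_b = s$label_b,
        recoverable_window_s = s$window_time_s,
        rationale = sprintf(
          "co-displaying '%s' and '%s' removes %d back-and-forth visits",
          s$label_a, s$label_b, s$count_a + s$count_b),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(session_id = character(0), juxtapose_a = character(0),
                 juxtapose_b = character(0),
                 recoverable_window_s = numeric(0),
                 rationale = character(0), stringsAsFactors = FALSE)
    }
    report$pogo <- list(findings = findings, suggestions = suggestions)
    report$figures$timebelt <- render_timebelt(
      layout_timebelt(sessions, scale = scale)
    )
  }

  structure(report, class = "fragmentation_report")
}

#' @export
print.fragmentation_report <- function(x, ...) {
  cat("<fragmentation_report>\n")
  if (!is.null(x$dfi)) {
    for (nm in names(x$dfi$breakdowns)) {
      cat(" ", nm, ": ", format_dfi(x$dfi$breakdowns[[nm]]), "\n", sep = "")
    }
    if (!is.null(x$dfi$comparison) && !is.na(x$dfi$comparison$ratio)) {
      cat(sprintf("  comparison ratio: %.3f\n", x$dfi$comparison$ratio))
    }
  }
  if (!is.null(x$tasks)) {
    cat(sprintf("  task summaries for %d session(s)\n", length(x$tasks)))
  }
  if (!is.null(x$pogo)) {
    cat(sprintf("  pogo-sticking suggestions: %d\n",
                nrow(x$pogo$suggestions)))
  }
  cat(sprintf("  figures: %s\n", paste(names(x$figures), collapse = ", ")))
  invisible(x)
}

report_to_list <- function(report) {
  out <- list()
  if (!is.null(report$dfi)) {
    out$dfi <- list(breakdowns = lapply(report$dfi$breakdowns, dfi_to_list))
    if (!is.null(report$dfi$comparison)) {
      cmp <- report$dfi$comparison
      out$dfi$comparison <- list(
        deltas = as.list(cmp$deltas),
        ratio = if (is.na(cmp$ratio)) NULL else cmp$ratio,
        total_a = cmp$total_a, total_b = cmp$total_b
      )
    }
  }
  if (!is.null(report$tasks)) out$tasks <- report$tasks
  if (!is.null(report$pogo)) {
    out$pogo <- list(findings = report$pogo$findings,
                     suggestions = report$pogo$suggestions)
  }
  out$figures <- names(report$figures)
  out
}

#' Write a fragmentation report to disk
#'
#' Emits `report.json` (all numeric results), one `.svg` file per figure and
#' a minimal `index.html` linking them.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  for (nm in names(report$figures)) {
    write_svg(report$figures[[nm]], file.path(dir, paste0(nm, ".svg")))
  }
  figs <- paste(sprintf(
    '<figure><img src="%s.svg" alt="%s"/><figcaption>%s</figcaption></figure>',
    names(report$figures), names(report$figures), names(report$figures)
  ), collapse = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
    "<title>Fragmentation report</title></head><body>\n",
    "<h1>Fragmentation report</h1>\n",
    "<p>Numeric results: <a href=\"report.json\">report.json</a></p>\n",
    figs, "\n</body></html>\n"
  )
  writeLines(html, file.path(dir, "index.html"))
  invisible(dir)
}
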