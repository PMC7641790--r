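#' Construct a session from task segments
#'
#' A session is one recorded encounter with the system: an ordered,
#' non-overlapping sequence of time-stamped task segments (seconds from
#' session start). Total EHR time is the sum of segment durations — idle
#' gaps between segments are not time spent in the system — unless
#' `total = "span"` is requested, in which case it is last end minus first
#' start.
#'
#' @param session_id Token identifying the session.
#' @param segments data.frame with columns `task` (label), `start_s`,
#'   `end_s` (numeric seconds, `end_s > start_s >= 0`) and optionally
#'   `screen_id`.
#' @param total `"active"` (default, sum of durations) or `"span"`.
#' @return An object of class `ehr_session`: list with `session_id`,
#'   `segments` (sorted, with a `duration_s` column) and `total_time_s`.
#' @export
session <- function(session_id, segments, total = c("active", "span")) {
  total <- match.arg(total)
  stopifnot(is.data.frame(segments),
            all(c("task", "start_s", "end_s") %in% names(segments)))
  if (nrow(segments) == 0L) stop("session has no segments", call. = FALSE)
  segments$task <- as.character(segments$task)
  segments$start_s <- as.numeric(segments$start_s)
  segments$end_s <- as.numeric(segments$end_s)
  if (!"screen_id" %in% names(segments)) segments$screen_id <- NA_character_
  bad <- which(!(segments$end_s > segments$start_s & segments$start_s >= 0))
  if (length(bad)) {
    stop("malformed segment(s) (need end_s > start_s >= 0) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(segments$start_s, segments$end_s)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1L) {
    ov <- which(segments$start_s[-1L] < segments$end_s[-nrow(segments)])
    if (length(ov)) {
      stop(sprintf(
        "overlapping segments in session %s: rows %d and %d ([%g, %g) vs [%g, %g))",
        session_id, ov[1L], ov[1L] + 1L,
        segments$start_s[ov[1L]], segments$end_s[ov[1L]],
        segments$start_s[ov[1L] + 1L], segments$end_s[ov[1L] + 1L]
      ), call. = FALSE)
    }
  }
  segments$duration_s <- segments$end_s - segments$start_s
  total_time <- if (total == "active") sum(segments$duration_s) else
    segments$end_s[nrow(segments)] - segments$start_s[1L]
  structure(
    list(session_id = as.character(session_id), segments = segments,
         total_time_s = total_time),
    class = "ehr_session"
  )
}

#' @export
print.ehr_session <- function(x, ...) {
  cat(sprintf("<ehr_session> %s: %d segments, %d task label(s), %.1f s\n",
              x$session_id, nrow(x$segments),
              length(unique(x$segments$task)), x$total_time_s))
  invisible(x)
}

#' Parse a tabular session event log
#'
#' Reads rows of the session-log dialect (`session_id`, `task`, `start_s`,
#' `end_s`, optional `screen_id`; times in seconds from session start),
#' groups them by session in order of first appearance, sorts and validates
#' each session, and computes durations and total EHR time.
#'
#' @param rows data.frame with the columns above.
#' @param total Passed to [session()].
#' @return A list of `ehr_session` objects (empty list for empty input).
#' @export
parse_session_log <- function(rows, total = c("active", "span")) {
  total <- match.arg(total)
  if (is.null(rows) || nrow(rows) == 0L) return(list())
  stopifnot(all(c("session_id", "task", "start_s", "end_s") %in% names(rows)))
  ids <- unique(as.character(rows$session_id))
  out <- lapply(ids, function(sid) {
    seg <- rows[as.character(rows$session_id) == sid,
                intersect(c("task", "start_s", "end_s", "screen_id"),
                          names(rows)),
                drop = FALSE]
    session(sid, seg, total = total)
  })
  stats::setNames(out, ids)
}

#' Read / write the session-log CSV dialect
#'
#' @param path File path.
#' @param sessions A list of `ehr_session` objects (or a single one).
#' @param ... Passed to [parse_session_log()].
#' @return `read_session_csv` returns a list of sessions;
#'   `write_session_csv` returns `path` invisibly.
#' @export
read_session_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  parse_session_log(df, ...)
}

#' @rdname read_session_csv
#' @export
write_session_csv <- function(sessions, path) {
  if (inherits(sessions, "ehr_session")) sessions <- list(sessions)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(session_id = s$session_id, task = s$segments$task,
               start_s = s$segments$start_s, end_s = s$segments$end_s,
               screen_id = s$segments$screen_id, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Segment a session into task instances
#'
#' A task instance is a maximal run of consecutive segments sharing a task
#' label. Abutting same-label segments (zero gap) merge into one instance;
#' any time gap, or an interleaved segment of another task, starts a new
#' instance. Instances are the bands visible in a time belt: the more
#' instances a task is split into, the more fragmented it is.
#'
#' @param session An `ehr_session`.
#' @param split_on_gap Logical; if `FALSE`, consecutive same-label segments
#'   merge across idle gaps as well (the gap itself is still excluded from
#'   the instance duration bookkeeping only via `end - start`; default
#'   `TRUE`, any gap splits).
#' @return Named list mapping each task label (first-appearance order) to a
#'   data.frame with columns `start_s`, `end_s`, `duration_s` — one row per
#'   instance, where `duration_s` sums the member segments' durations.
#' @export
segment_instances <- function(session, split_on_gap = TRUE) {
  seg <- session$segments
  n <- nrow(seg)
  new_run <- c(TRUE, vapply(seq_len(n - 1L) + 1L, function(i) {
    seg$task[i] != seg$task[i - 1L] ||
      (split_on_gap && seg$start_s[i] > seg$end_s[i - 1L])
  }, logical(1)))
  if (n == 1L) new_run <- TRUE
  run_id <- factor(cumsum(new_run), levels = unique(cumsum(new_run)))
  runs <- data.frame(
    task = tapply(seg$task, run_id, `[`, 1L),
    start_s = as.numeric(tapply(seg$start_s, run_id, min)),
    end_s = as.numeric(tapply(seg$end_s, run_id, max)),
    duration_s = as.numeric(tapply(seg$duration_s, run_id, sum)),
    stringsAsFactors = FALSE
  )
  labels <- unique(seg$task)
  out <- lapply(labels, function(lab) {
    r <- runs[runs$task == lab, c("start_s", "end_s", "duration_s"),
              drop = FALSE]
    rownames(r) <- NULL
    r
  })
  stats::setNames(out, labels)
}
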