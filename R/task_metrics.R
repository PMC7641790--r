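#' Average continuous time of a task
#'
#' ACT is the mean uninterrupted duration of a task's instances within a
#' session. The longer the ACT, the less fragmented the task: splitting the
#' same total task time into more instances lowers it.
#'
#' @param session An [session()] object.
#' @param task_label Task to evaluate.
#' @param ... Passed to [segment_instances()].
#' @return Mean instance duration in seconds.
#' @export
average_continuous_time <- function(session, task_label, ...) {
  inst <- segment_instances(session, ...)[[task_label]]
  if (is.null(inst)) {
    stop("task '", task_label, "' does not occur in session ",
         session$session_id, call. = FALSE)
  }
  mean(inst$duration_s)
}

#' Proportion per instance of a task
#'
#' PPI relates time on task to how often the task had to be resumed,
#' normalized by total EHR time so that longer sessions do not inflate the
#' measure:
#'
#' \deqn{PPI = \frac{T_{task}}{n_{instances} \times T_{total}}}
#'
#' Equivalently, PPI is the task's average continuous time as a fraction of
#' total EHR time. A lower value denotes more fragmented subtasks; a task
#' occupying the whole session in a single instance scores 1.
#'
#' @inheritParams average_continuous_time
#' @return Dimensionless proportion in (0, 1].
#' @export
proportion_per_instance <- function(session, task_label, ...) {
  if (!session$total_time_s > 0) {
    stop("undefined measure: session total time is zero", call. = FALSE)
  }
  inst <- segment_instances(session, ...)[[task_label]]
  if (is.null(inst)) {
    stop("task '", task_label, "' does not occur in session ",
         session$session_id, call. = FALSE)
  }
  sum(inst$duration_s) / (nrow(inst) * session$total_time_s)
}

#' Per-task fragmentation summary for a session
#'
#' One row per distinct task label (first-appearance order) with total time,
#' instance count, average continuous time and proportion per instance.
#' Internally consistent by construction: `act_s * n_instances =
#' total_time_s` and `ppi = act_s / session total`.
#'
#' @inheritParams average_continuous_time
#' @return data.frame with columns `task_label`, `total_time_s`,
#'   `n_instances`, `act_s`, `ppi`.
#' @export
task_summary <- function(session, ...) {
  inst <- segment_instances(session, ...)
  labels <- names(inst)
  totals <- vapply(inst, function(d) sum(d$duration_s), numeric(1))
  counts <- vapply(inst, nrow, integer(1))
  act <- totals / counts
  data.frame(
    task_label = labels,
    total_time_s = unname(totals),
    n_instances = unname(counts),
    act_s = unname(act),
    ppi = unname(totals / (counts * session$total_time_s)),
    stringsAsFactors = FALSE
  )
}
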