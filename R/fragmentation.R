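#' Trace a measurement pathway through target elements
#'
#' Simulates the "main obvious navigation path" a user follows to visit every
#' task-relevant element of an interface, starting from the root screen.
#' Between consecutive targets the pathway climbs to a bounce point and
#' descends again: with `routing = "lca"` (default) the bounce point is the
#' lowest common ancestor of the two targets, so the path never climbs higher
#' than the hierarchy forces it to; with `routing = "root"` every leg returns
#' to the top-level screen, re-entering (and re-counting) all intermediate
#' screens — the maximal-ascent convention.
#'
#' Steps are generated on descents only:
#' \itemize{
#'   \item entering a non-target screen: one `visit_screen_transition`;
#'   \item entering a menu item (a same-screen choice): one
#'     `click_same_level`;
#'   \item arriving at a target (data element, or a screen flagged as a
#'     target): one `reach_element`;
#'   \item any entry into a screen flagged `is_scrolling_screen`: two
#'     `scroll` steps (the average over variable screen lengths).
#' }
#' Each step carries the level (depth) of the node acted on.
#'
#' @param tree A [nav_tree()].
#' @param targets Character vector of target node ids (defaults to the
#'   tree's flagged targets). Visited in tree document order unless
#'   `in_order = TRUE`, in which case the supplied order is kept.
#' @param routing `"lca"` or `"root"`, see Details.
#' @param in_order Logical; keep the supplied target order.
#' @return An object of class `nav_pathway`: a list with `steps` (data.frame
#'   `node_id`, `action`, `level`), `target_order` (ids in visit order) and
#'   `routing`.
#' @export
trace_pathway <- function(tree, targets = nav_targets(tree),
                          routing = c("lca", "root"), in_order = FALSE) {
  routing <- match.arg(routing)
  validate_nav_tree(tree)
  if (length(targets) == 0L) {
    stop("empty targets: at least one target id is required", call. = FALSE)
  }
  missing <- setdiff(targets, node_ids(tree))
  if (length(missing)) {
    stop("missing node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  targets <- unique(targets)
  if (!in_order) {
    ord <- preorder_ids(tree)
    targets <- ord[ord %in% targets]
  }

  step_node <- character(0); step_action <- character(0); step_level <- integer(0)
  add_step <- function(id, action) {
    step_node[[length(step_node) + 1L]] <<- id
    step_action[[length(step_action) + 1L]] <<- action
    step_level[[length(step_level) + 1L]] <<- tree$nodes[[id]]$depth
  }

  reached <- character(0)
  visit_order <- character(0)
  enter <- function(id, is_goal) {
    n <- tree$nodes[[id]]
    if (is_goal || (n$is_target && !id %in% reached)) {
      add_step(id, "reach_element")
      reached <<- c(reached, id)
      visit_order <<- c(visit_order, id)
    } else if (n$is_target) {
      # already-reached target screen passed through: no action counted
    } else if (n$kind == "menu_item") {
      add_step(id, "click_same_level")
    } else {
      add_step(id, "visit_screen_transition")
    }
    if (n$is_scrolling_screen) {
      add_step(id, "scroll"); add_step(id, "scroll")
    }
  }

  prev <- NULL
  for (t in targets) {
    if (t %in% reached) next   # picked up en route to an earlier target
    bounce <- if (is.null(prev)) tree$root_id
      else if (routing == "root") tree$root_id
      else lca_id(tree, prev, t)
    full <- path_from_root(tree, t)
    if (t == bounce) {
      # target is an ancestor of the previous one (custom orders only):
      # it is reached on arrival while climbing, no descent needed
      enter(t, is_goal = TRUE)
    } else {
      from <- match(bounce, full)
      for (id in full[(from + 1L):length(full)]) enter(id, is_goal = id == t)
    }
    prev <- t
  }

  structure(
    list(
      steps = data.frame(node_id = step_node, action = step_action,
                         level = step_level, stringsAsFactors = FALSE),
      target_order = visit_order,
      routing = routing
    ),
    class = "nav_pathway"
  )
}

#' @export
print.nav_pathway <- function(x, ...) {
  cat(sprintf("<nav_pathway> %d steps, %d targets, routing = %s\n",
              nrow(x$steps), length(x$target_order), x$routing))
  print(table(x$steps$action))
  invisible(x)
}

#' Tally navigation actions along a pathway
#'
#' Buckets the pathway's steps by the level of the node acted on and
#' accumulates the menu-length burden. Every screen transition is also
#' counted as one click (selecting the menu entry that causes it); explicit
#' `click_same_level` steps add further clicks. Menu length is summed once
#' per distinct decision point on the pathway — a traversed parent offering a
#' real choice (effective menu length of at least 2).
#'
#' @param pathway A `nav_pathway` from [trace_pathway()] (or constructed to
#'   the same shape).
#' @param tree The `nav_tree` the pathway runs through.
#' @return An object of class `action_tally`: list with integer `E`, named
#'   per-level vectors `IS_by_level`, `C_by_level`, `SS_by_level`, and
#'   integer `ML`.
#' @export
tally_actions <- function(pathway, tree) {
  steps <- pathway$steps
  unknown <- setdiff(unique(steps$node_id), node_ids(tree))
  if (length(unknown)) {
    stop("pathway references node(s) absent from tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  by_level <- function(sel) {
    if (!any(sel)) return(stats::setNames(integer(0), character(0)))
    tab <- table(steps$level[sel])
    stats::setNames(as.integer(tab), names(tab))
  }
  is_sel <- steps$action == "visit_screen_transition"
  c_sel <- is_sel | steps$action == "click_same_level"
  ss_sel <- steps$action == "scroll"

  entered <- unique(steps$node_id)
  parents <- unique(stats::na.omit(vapply(
    tree$nodes[entered], function(n) n$parent_id, character(1)
  )))
  mls <- vapply(parents, function(p) menu_length(tree, p), integer(1))
  ml <- sum(mls[mls >= 2L])

  structure(
    list(
      E = sum(steps$action == "reach_element"),
      IS_by_level = by_level(is_sel),
      C_by_level = by_level(c_sel),
      SS_by_level = by_level(ss_sel),
      ML = as.integer(ml)
    ),
    class = "action_tally"
  )
}

#' @export
print.action_tally <- function(x, ...) {
  fmt <- function(v) if (!length(v)) "0" else
    paste(sprintf("L%s:%d", names(v), v), collapse = " ")
  cat(sprintf("<action_tally> E=%d  IS[%s]  C[%s]  SS[%s]  ML=%d\n",
              x$E, fmt(x$IS_by_level), fmt(x$C_by_level), fmt(x$SS_by_level),
              x$ML))
  invisible(x)
}

#' Level multiplier policy for the fragmentation index
#'
#' The index weights transition, click and scroll counts by a multiplier
#' reflecting how many levels were traversed. `"depth_weighted"` (default)
#' weights an action at level l by l, so actions deep in the hierarchy cost
#' more; `"constant"` applies the same weight everywhere (value 1 reduces the
#' weighted terms to raw counts).
#'
#' @param mode `"depth_weighted"` or `"constant"`.
#' @param constant_value Positive number used when `mode = "constant"`.
#' @return An object of class `multiplier_policy`.
#' @export
multiplier_policy <- function(mode = c("depth_weighted", "constant"),
                              constant_value = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(constant_value), length(constant_value) == 1L,
            constant_value > 0)
  structure(list(mode = mode, constant_value = constant_value),
            class = "multiplier_policy")
}

policy_weight <- function(policy, level) {
  if (policy$mode == "constant") rep(policy$constant_value, length(level))
  else as.numeric(level)
}

#' Compute the Display Fragmentation Index
#'
#' DFI = E + IS(X_IS) + C(X_C) + SS(X_SS) + ML: the number of data elements
#' reached (unweighted — elements must be accessed wherever they live), plus
#' level-weighted intermediate screen transitions, clicks and scroll actions,
#' plus the accumulated menu length over decision points. Higher values mean
#' the task's information is more fragmented across the interface.
#'
#' @param tally An [tally_actions()] result.
#' @param policy A [multiplier_policy()]; defaults to depth weighting.
#' @return An object of class `dfi_breakdown` with fields `E_term`,
#'   `IS_term`, `C_term`, `SS_term`, `ML_term` and `total` (their exact sum).
#' @export
compute_dfi <- function(tally, policy = multiplier_policy()) {
  stopifnot(inherits(tally, "action_tally"),
            inherits(policy, "multiplier_policy"))
  weighted <- function(v) {
    if (!length(v)) return(0)
    sum(policy_weight(policy, as.integer(names(v))) * as.numeric(v))
  }
  out <- list(
    E_term = as.numeric(tally$E),
    IS_term = weighted(tally$IS_by_level),
    C_term = weighted(tally$C_by_level),
    SS_term = weighted(tally$SS_by_level),
    ML_term = as.numeric(tally$ML)
  )
  out$total <- out$E_term + out$IS_term + out$C_term + out$SS_term +
    out$ML_term
  out$policy <- policy
  structure(out, class = "dfi_breakdown")
}

#' Format the index as its component sum
#'
#' @param x A `dfi_breakdown`.
#' @return A single string, e.g. `"DFI = 36 + 136 + 136 + 0 + 39 = 347"`
#'   (terms in E, IS, C, SS, ML order).
#' @export
format_dfi <- function(x) {
  num <- function(v) sprintf("%g", v)
  sprintf("DFI = %s + %s + %s + %s + %s = %s",
          num(x$E_term), num(x$IS_term), num(x$C_term), num(x$SS_term),
          num(x$ML_term), num(x$total))
}

#' @export
print.dfi_breakdown <- function(x, ...) {
  cat(format_dfi(x), "\n")
  invisible(x)
}

#' One-call fragmentation index for a tree
#'
#' Convenience wrapper: traces the pathway through the tree's targets,
#' tallies actions and computes the index.
#'
#' @inheritParams trace_pathway
#' @param policy A [multiplier_policy()].
#' @return A `dfi_breakdown`; the pathway and tally are attached as
#'   attributes `"pathway"` and `"tally"`.
#' @export
dfi <- function(tree, targets = nav_targets(tree),
                policy = multiplier_policy(), routing = c("lca", "root"),
                in_order = FALSE) {
  pw <- trace_pathway(tree, targets, routing = routing, in_order = in_order)
  tally <- tally_actions(pw, tree)
  out <- compute_dfi(tally, policy)
  attr(out, "pathway") <- pw
  attr(out, "tally") <- tally
  out
}

#' Compare the fragmentation of two systems
#'
#' @param a,b `dfi_breakdown` objects for the reference and comparison
#'   system, respectively.
#' @return An object of class `dfi_comparison`: per-term differences
#'   (`b - a`) and `ratio = b$total / a$total` (`NA` unless both totals are
#'   positive).
#' @export
compare_systems <- function(a, b) {
  stopifnot(inherits(a, "dfi_breakdown"), inherits(b, "dfi_breakdown"))
  terms <- c("E_term", "IS_term", "C_term", "SS_term", "ML_term", "total")
  deltas <- stats::setNames(
    vapply(terms, function(t) b[[t]] - a[[t]], numeric(1)), terms
  )
  ratio <- if (a$total > 0 && b$total > 0) b$total / a$total else NA_real_
  structure(list(deltas = deltas, ratio = ratio,
                 total_a = a$total, total_b = b$total),
            class = "dfi_comparison")
}

#' @export
print.dfi_comparison <- function(x, ...) {
  cat(sprintf("<dfi_comparison> totals %s vs %s",
              formatC(x$total_a, format = "g"),
              formatC(x$total_b, format = "g")))
  if (!is.na(x$ratio)) cat(sprintf("  (ratio %.3f)", x$ratio))
  cat("\n  per-term deltas (b - a):\n")
  print(round(x$deltas, 4))
  invisible(x)
}

dfi_to_list <- function(x) {
  list(E = x$E_term, IS = x$IS_term, C = x$C_term, SS = x$SS_term,
       ML = x$ML_term, total = x$total,
       multiplier = list(mode = x$policy$mode,
                         constant_value = x$policy$constant_value))
}
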