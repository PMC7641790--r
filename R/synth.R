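# Synthetic walkthrough structures and session logs with controllable
# fragmentation, standing in for cognitive-walkthrough and screen-capture
# data. Each generator draws from its own seeded RNG stream and restores the
# caller's RNG state, so fixtures are byte-reproducible.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a complete synthetic navigation tree
#'
#' Builds a complete tree of screens of the given depth and branching, with
#' `n_targets` task-relevant data elements placed uniformly at random among
#' the leaves and scroll flags drawn independently per screen. The result
#' emulates the annotated hierarchy a modified cognitive walkthrough of a
#' menu-based interface produces.
#'
#' @param depth Positive integer; leaves sit at this depth (root = 0).
#' @param branching Positive integer, or a vector of length `depth` giving
#'   per-level branching.
#' @param n_targets Number of leaves to flag as targets (at least 1, at most
#'   the leaf count).
#' @param p_scroll Probability that an internal screen is a scrolling
#'   screen.
#' @param seed Integer seed; identical seeds give identical trees.
#' @return A [nav_tree()]; internal nodes are screens, leaves are data
#'   elements.
#' @export
generate_nav_tree <- function(depth, branching = 2L, n_targets = 1L,
                              p_scroll = 0, seed = 1L) {
  stopifnot(depth >= 1L, all(branching >= 1L),
            p_scroll >= 0, p_scroll <= 1)
  b <- if (length(branching) == 1L) rep(as.integer(branching), depth) else
    as.integer(branching)
  if (length(b) != depth) {
    stop("branching must be scalar or length `depth`", call. = FALSE)
  }
  n_leaves <- prod(b)
  if (n_targets > n_leaves) {
    stop("capacity error: n_targets (", n_targets,
         ") exceeds leaf count (", n_leaves, ")", call. = FALSE)
  }
  if (n_targets < 1L) stop("n_targets must be positive", call. = FALSE)

  with_local_seed(seed, {
    nodes <- list()
    next_id <- 0L
    grow <- function(level, label) {
      next_id <<- next_id + 1L
      id <- paste0("n", next_id)
      is_leaf <- level == depth
      n <- nav_node(id, label, kind = if (is_leaf) "data_element" else "screen")
      if (!is_leaf && stats::runif(1) < p_scroll) n$is_scrolling_screen <- TRUE
      if (!is_leaf) {
        n$children <- vapply(seq_len(b[[level + 1L]]), function(i) {
          grow(level + 1L, paste0(label, ".", i))
        }, character(1))
      }
      nodes[[id]] <<- n
      id
    }
    root_id <- grow(0L, "root")
    leaf_ids <- names(nodes)[vapply(nodes, function(n) n$kind == "data_element",
                                    logical(1))]
    picked <- sample(leaf_ids, n_targets)
    for (id in picked) nodes[[id]]$is_target <- TRUE
    nav_tree(nodes, root_id)
  })
}

#' Generate a synthetic session log
#'
#' Task labels evolve as a Markov switching process: at each step the label
#' switches with probability `p_switch` to a uniformly chosen *other* label,
#' and the step becomes an abutting segment of `step_s` seconds. Higher
#' `p_switch` yields more, shorter task instances — i.e. more task
#' fragmentation — which is what the ACT and PPI measures should recover.
#'
#' @param task_labels Character vector of at least one task label.
#' @param total_steps Number of steps (segments) in the session.
#' @param step_s Seconds per step.
#' @param p_switch Per-step probability of switching task.
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @return An [session()] object.
#' @export
generate_session <- function(task_labels, total_steps = 60L, step_s = 5,
                             p_switch = 0.3, seed = 1L,
                             session_id = "synthetic") {
  stopifnot(length(task_labels) >= 1L, total_steps >= 1L, step_s > 0,
            p_switch >= 0, p_switch <= 1)
  task_labels <- as.character(task_labels)
  with_local_seed(seed, {
    lab <- character(total_steps)
    lab[1L] <- sample(task_labels, 1L)
    if (total_steps > 1L) {
      for (i in 2L:total_steps) {
        if (length(task_labels) > 1L && stats::runif(1) < p_switch) {
          lab[i] <- sample(setdiff(task_labels, lab[i - 1L]), 1L)
        } else {
          lab[i] <- lab[i - 1L]
        }
      }
    }
    starts <- (seq_len(total_steps) - 1L) * step_s
    session(session_id, data.frame(
      task = lab, start_s = starts, end_s = starts + step_s,
      screen_id = paste0("scr_", lab), stringsAsFactors = FALSE
    ))
  })
}

#' Built-in example interfaces with known fragmentation indices
#'
#' Two small synthetic EHR navigation structures used throughout the
#' documentation and tests, shaped like the walkthrough maps of a dense
#' conventional interface and a flatter, better-integrated one. Under the
#' default depth-weighted multipliers and LCA routing their traced pathways
#' give the worked breakdowns
#' `DFI = 36 + 136 + 136 + 0 + 39 = 347` (`"dense"`) and
#' `DFI = 19 + 47 + 47 + 0 + 19 = 132` (`"integrated"`), a ratio of about
#' one-third.
#'
#' @param which `"dense"` or `"integrated"`.
#' @return A [nav_tree()] with targets flagged.
#' @export
demo_nav_tree <- function(which = c("dense", "integrated")) {
  which <- match.arg(which)
  element <- function(lab) list(label = lab, kind = "data_element",
                                is_target = TRUE)
  if (which == "dense") {
    # Chart-review spine of 16 screens; three menus of 12 relevant elements
    # hang at depths 5, 10 and 16.
    elements <- function(pre) lapply(sprintf("%s %02d", pre, 1:12), element)
    spine <- list(label = "Archive viewer", kind = "screen",
                  children = list())                       # depth 16 tail
    spine$children <- c(elements("Archived result"),
                        list(list(label = "Export options", kind = "screen",
                                  children = list())))
    for (d in 15:1) {
      wrap <- list(label = sprintf("Section level %02d", d), kind = "screen",
                   children = list(spine))
      if (d == 5) {
        wrap$label <- "Results review"
        wrap$children <- c(elements("Lab panel"), list(spine))
      }
      if (d == 10) {
        wrap$label <- "Notes browser"
        wrap$children <- c(elements("Clinical note"), list(spine))
      }
      spine <- wrap
    }
    root <- list(label = "Main screen", kind = "screen",
                 children = list(spine))
  } else {
    # Flat review screen at depth 10 holding 18 relevant elements; the
    # summary screen at depth 8 is itself task-relevant.
    inner <- list(label = "Case review board", kind = "screen",
                  children = c(
                    lapply(sprintf("Widget %02d", 1:18), element),
                    list(list(label = "Settings", kind = "screen",
                              children = list()))
                  ))
    spine <- list(label = "Review workspace", kind = "screen",
                  children = list(inner))                  # depth 9
    for (d in 8:1) {
      wrap <- list(label = sprintf("Navigation level %02d", d),
                   kind = "screen", children = list(spine))
      if (d == 8) {
        wrap$label <- "Patient summary"
        wrap$is_target <- TRUE
      }
      spine <- wrap
    }
    root <- list(label = "Main screen", kind = "screen",
                 children = list(spine))
  }
  nav_tree_from_list(root)
}
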