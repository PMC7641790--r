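#' @keywords internal
"_PACKAGE"

NODE_KINDS <- c("screen", "menu_item", "data_element")

#' Create a navigation node
#'
#' A node of the annotated navigation hierarchy recorded during a modified
#' cognitive walkthrough of an interface: a screen, a menu item on a screen,
#' or a clinical data element reached at the end of a menu path.
#'
#' @param id Unique opaque token identifying the node.
#' @param label Display text of the screen, menu entry or element.
#' @param kind One of `"screen"`, `"menu_item"`, `"data_element"`.
#' @param is_target Logical; `TRUE` when the node holds information relevant
#'   to the clinical task under analysis. Only screens and data elements may
#'   be targets.
#' @param is_scrolling_screen Logical; `TRUE` when the screen requires
#'   scrolling to expose its content. Each visit to such a screen is counted
#'   as two scroll actions (an average over variable screen lengths).
#' @param menu_length_override Positive integer or `NA`. Number of parallel
#'   menu items actually displayed on this node when it differs from the
#'   number of modelled children (real screens often show items that are not
#'   part of the analysed hierarchy).
#' @return A list of class `nav_node`. `depth`, `parent_id` and `children`
#'   are filled in when the node is assembled into a [nav_tree()].
#' @export
nav_node <- function(id, label, kind = "screen", is_target = FALSE,
                     is_scrolling_screen = FALSE,
                     menu_length_override = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(label), length(label) == 1L)
  kind <- match.arg(kind, NODE_KINDS)
  if (!is.na(menu_length_override)) {
    menu_length_override <- as.integer(menu_length_override)
    if (menu_length_override < 1L) {
      stop("menu_length_override must be a positive integer", call. = FALSE)
    }
  }
  structure(
    list(
      id = id, label = label, kind = kind,
      depth = NA_integer_, parent_id = NA_character_,
      children = character(0),
      is_target = isTRUE(is_target),
      is_scrolling_screen = isTRUE(is_scrolling_screen),
      menu_length_override = menu_length_override
    ),
    class = "nav_node"
  )
}

#' Assemble a navigation tree
#'
#' Builds a validated navigation tree from a set of nodes and parent/child
#' links. Depths are computed from the root (depth 0 is the highest-level
#' screen), and all structural invariants are checked: unique ids, a single
#' root, acyclic connected parent/child links, and target flags restricted to
#' screens and data elements.
#'
#' @param nodes List of [nav_node()] objects. Each node's `children` field
#'   must already list its child ids in display order; alternatively supply
#'   `edges`.
#' @param root_id Id of the root (top-level) screen.
#' @param edges Optional two-column data.frame (`parent`, `child`) used to
#'   set the links; child order within a parent follows row order.
#' @return A list of class `nav_tree` with fields `nodes` (named list),
#'   `root_id` and `max_depth`.
#' @export
nav_tree <- function(nodes, root_id, edges = NULL) {
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(nodes) <- ids
  if (!root_id %in% ids) stop("root_id not among nodes", call. = FALSE)
  if (!is.null(edges)) {
    for (i in seq_along(nodes)) nodes[[i]]$children <- character(0)
    for (k in seq_len(nrow(edges))) {
      p <- as.character(edges$parent[k]); ch <- as.character(edges$child[k])
      nodes[[p]]$children <- c(nodes[[p]]$children, ch)
    }
  }
  # set parent links and depths by breadth-first descent from the root
  nodes[[root_id]]$depth <- 0L
  nodes[[root_id]]$parent_id <- NA_character_
  queue <- root_id
  seen <- character(0)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% seen) stop("cycle detected at node ", cur, call. = FALSE)
    seen <- c(seen, cur)
    for (ch in nodes[[cur]]$children) {
      if (!ch %in% ids) stop("unknown child id: ", ch, call. = FALSE)
      nodes[[ch]]$parent_id <- cur
      nodes[[ch]]$depth <- nodes[[cur]]$depth + 1L
      queue <- c(queue, ch)
    }
  }
  if (length(seen) != length(ids)) {
    stop("nodes unreachable from root: ",
         paste(setdiff(ids, seen), collapse = ", "), call. = FALSE)
  }
  tree <- structure(
    list(
      nodes = nodes,
      root_id = root_id,
      max_depth = max(vapply(nodes, function(n) n$depth, integer(1)))
    ),
    class = "nav_tree"
  )
  validate_nav_tree(tree)
  tree
}

#' Validate navigation-tree invariants
#'
#' @param tree A `nav_tree`.
#' @return `tree`, invisibly; errors if any invariant is violated.
#' @export
validate_nav_tree <- function(tree) {
  stopifnot(inherits(tree, "nav_tree"))
  nodes <- tree$nodes
  for (n in nodes) {
    if (!n$kind %in% NODE_KINDS) stop("bad kind for ", n$id, call. = FALSE)
    if (n$is_target && n$kind == "menu_item") {
      stop("node ", n$id, ": menu items cannot be targets", call. = FALSE)
    }
    for (ch in n$children) {
      if (nodes[[ch]]$depth != n$depth + 1L) {
        stop("depth invariant broken at edge ", n$id, " -> ", ch,
             call. = FALSE)
      }
      if (!identical(nodes[[ch]]$parent_id, n$id)) {
        stop("parent link broken at ", ch, call. = FALSE)
      }
    }
  }
  if (tree$max_depth != max(vapply(nodes, function(n) n$depth, integer(1)))) {
    stop("max_depth inconsistent", call. = FALSE)
  }
  n_roots <- sum(vapply(nodes, function(n) is.na(n$parent_id), logical(1)))
  if (n_roots != 1L) stop("tree must have exactly one root", call. = FALSE)
  invisible(tree)
}

# ---- small accessors used throughout -------------------------------------

node_ids <- function(tree) names(tree$nodes)

#' @export
print.nav_tree <- function(x, ...) {
  kinds <- table(vapply(x$nodes, function(n) n$kind, character(1)))
  cat(sprintf(
    "<nav_tree> %d nodes, max depth %d, %d target(s)\n",
    length(x$nodes), x$max_depth,
    sum(vapply(x$nodes, function(n) n$is_target, logical(1)))
  ))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of nodes in a navigation tree
#' @param tree A `nav_tree`.
#' @return Integer node count.
#' @export
nav_size <- function(tree) length(tree$nodes)

#' Ids of task-relevant (target) nodes in document order
#' @param tree A `nav_tree`.
#' @return Character vector of node ids.
#' @export
nav_targets <- function(tree) {
  ord <- preorder_ids(tree)
  ord[vapply(tree$nodes[ord], function(n) n$is_target, logical(1))]
}

# depth-first preorder following stored sibling order
preorder_ids <- function(tree) {
  out <- character(0)
  walk <- function(id) {
    out[[length(out) + 1L]] <<- id
    for (ch in tree$nodes[[id]]$children) walk(ch)
  }
  walk(tree$root_id)
  out
}

# root ... id inclusive
path_from_root <- function(tree, id) {
  path <- character(0)
  cur <- id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$nodes[[cur]]$parent_id
  }
  path
}

lca_id <- function(tree, a, b) {
  pa <- path_from_root(tree, a)
  pb <- path_from_root(tree, b)
  k <- min(length(pa), length(pb))
  common <- which(pa[seq_len(k)] == pb[seq_len(k)])
  pa[max(common)]
}

#' Effective menu length at a node
#'
#' The number of parallel items displayed adjacently on the node: the
#' recorded override when present, otherwise the number of modelled children.
#'
#' @param tree A `nav_tree`.
#' @param id Node id.
#' @return Integer menu length (possibly 0 for childless nodes without an
#'   override).
#' @export
menu_length <- function(tree, id) {
  n <- tree$nodes[[id]]
  if (is.null(n)) stop("unknown node id: ", id, call. = FALSE)
  if (!is.na(n$menu_length_override)) return(as.integer(n$menu_length_override))
  length(n$children)
}

n_leaf_descendants <- function(tree, id) {
  n <- tree$nodes[[id]]
  if (!length(n$children)) return(1L)
  sum(vapply(n$children, function(ch) n_leaf_descendants(tree, ch), integer(1)))
}

#' Compare two navigation trees structurally
#'
#' Ids are opaque tokens, so equality is judged on what the trees describe:
#' labels, sibling order, kinds, target/scroll flags and menu-length
#' overrides, position by position in depth-first order.
#'
#' @param a,b `nav_tree` objects.
#' @return Logical scalar.
#' @export
nav_tree_identical <- function(a, b) {
  sig <- function(tree) {
    lapply(preorder_ids(tree), function(id) {
      n <- tree$nodes[[id]]
      list(n$label, n$kind, n$depth, n$is_target, n$is_scrolling_screen,
           if (is.na(n$menu_length_override)) -1L else n$menu_length_override,
           length(n$children))
    })
  }
  identical(sig(a), sig(b))
}

# ---- tabular (path-per-row) dialect --------------------------------------

#' Parse a path-per-row navigation table
#'
#' Reads the tabular dialect used to record a modified cognitive walkthrough:
#' one row per recorded node, columns `level_1 ... level_k` giving the label
#' path from the root, plus annotation columns `kind`, `is_target`,
#' `is_scrolling` and `menu_length_override`. Rows sharing a label prefix
#' merge into shared ancestor nodes; sibling order follows first appearance.
#' Trailing blank level cells denote shorter paths; a blank cell followed by
#' a non-blank one is rejected as ambiguous.
#'
#' @param rows A data.frame with the columns described above. Booleans may be
#'   given as 0/1, "true"/"false" or logicals; blanks take defaults
#'   (kind `"screen"`, flags off, no override).
#' @return A validated [nav_tree()].
#' @export
parse_nav_table <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("empty input: no navigation rows to parse", call. = FALSE)
  }
  lev_cols <- grep("^level_[0-9]+$", names(rows), value = TRUE)
  lev_cols <- lev_cols[order(as.integer(sub("^level_", "", lev_cols)))]
  if (!length(lev_cols)) stop("no level_* columns found", call. = FALSE)

  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  get_col <- function(nm) if (nm %in% names(rows)) rows[[nm]] else rep(NA, nrow(rows))
  kinds <- as.character(get_col("kind"))
  targets <- get_col("is_target")
  scrolls <- get_col("is_scrolling")
  overrides <- get_col("menu_length_override")

  as_flag <- function(x) {
    if (is.logical(x)) return(isTRUE(x))
    x <- tolower(trimws(as.character(x)))
    if (is.na(x) || !nzchar(x)) return(FALSE)
    x %in% c("1", "true", "t", "yes")
  }

  nodes <- list()          # id -> nav_node
  child_map <- list()      # id -> named character (label -> child id)
  explicit <- character(0) # ids that received explicit row annotations
  next_id <- 0L
  new_node <- function(label) {
    next_id <<- next_id + 1L
    id <- paste0("n", next_id)
    nodes[[id]] <<- nav_node(id, label)
    child_map[[id]] <<- character(0)
    id
  }

  root_id <- NULL
  for (i in seq_len(nrow(rows))) {
    cells <- vapply(lev_cols, function(cn) as.character(rows[[cn]][i]), character(1))
    bl <- blank(cells)
    if (all(bl)) stop("row ", i, ": no labels", call. = FALSE)
    last <- max(which(!bl))
    if (any(bl[seq_len(last)])) {
      stop("row ", i, ": internal blank level cell (ragged path)", call. = FALSE)
    }
    labels <- trimws(cells[seq_len(last)])
    if (is.null(root_id)) {
      root_id <- new_node(labels[[1L]])
    } else if (!identical(nodes[[root_id]]$label, labels[[1L]])) {
      stop("row ", i, ": root label '", labels[[1L]],
           "' conflicts with '", nodes[[root_id]]$label, "'", call. = FALSE)
    }
    cur <- root_id
    for (lab in labels[-1L]) {
      hit <- child_map[[cur]][lab]
      if (is.na(hit)) {
        ch <- new_node(lab)
        nodes[[cur]]$children <- c(nodes[[cur]]$children, ch)
        child_map[[cur]][lab] <- ch
        cur <- ch
      } else {
        cur <- unname(hit)
      }
    }
    ann <- list(
      kind = if (blank(kinds[i])) "screen" else match.arg(trimws(kinds[i]), NODE_KINDS),
      is_target = as_flag(targets[i]),
      is_scrolling_screen = as_flag(scrolls[i]),
      menu_length_override = if (blank(overrides[i])) NA_integer_ else
        as.integer(overrides[i])
    )
    if (cur %in% explicit) {
      n <- nodes[[cur]]
      same <- identical(n$kind, ann$kind) &&
        identical(n$is_target, ann$is_target) &&
        identical(n$is_scrolling_screen, ann$is_scrolling_screen) &&
        identical(n$menu_length_override, ann$menu_length_override)
      if (!same) {
        stop("conflicting annotations for path: ",
             paste(labels, collapse = " / "), call. = FALSE)
      }
    } else {
      nodes[[cur]]$kind <- ann$kind
      nodes[[cur]]$is_target <- ann$is_target
      nodes[[cur]]$is_scrolling_screen <- ann$is_scrolling_screen
      nodes[[cur]]$menu_length_override <- ann$menu_length_override
      explicit <- c(explicit, cur)
    }
  }
  nav_tree(nodes, root_id)
}

default_annotation <- function(n) {
  n$kind == "screen" && !n$is_target && !n$is_scrolling_screen &&
    is.na(n$menu_length_override)
}

#' Serialize a navigation tree to the path-per-row table
#'
#' Inverse of [parse_nav_table()]: emits one row per leaf plus one row for
#' every internal node carrying non-default annotations, in depth-first
#' order, so that re-parsing reproduces the tree exactly (labels, sibling
#' order and annotations). Sibling labels must be unique within a parent for
#' this dialect; trees with duplicate sibling labels round-trip through the
#' nested JSON dialect instead.
#'
#' @param tree A `nav_tree`.
#' @return A data.frame with columns `level_1 ... level_k`, `kind`,
#'   `is_target`, `is_scrolling`, `menu_length_override` (booleans as 0/1).
#' @export
serialize_nav_table <- function(tree) {
  validate_nav_tree(tree)
  for (n in tree$nodes) {
    labs <- vapply(tree$nodes[n$children], function(c) c$label, character(1))
    if (anyDuplicated(labs)) {
      stop("duplicate sibling labels under '", n$label,
           "'; use the nested JSON dialect", call. = FALSE)
    }
  }
  k <- tree$max_depth + 1L
  ord <- preorder_ids(tree)
  emit <- vapply(tree$nodes[ord], function(n) {
    length(n$children) == 0L || !default_annotation(n)
  }, logical(1))
  ids <- ord[emit]
  mat <- matrix("", nrow = length(ids), ncol = k)
  for (r in seq_along(ids)) {
    path <- path_from_root(tree, ids[[r]])
    mat[r, seq_along(path)] <-
      vapply(tree$nodes[path], function(n) n$label, character(1))
  }
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- paste0("level_", seq_len(k))
  out$kind <- vapply(tree$nodes[ids], function(n) n$kind, character(1))
  out$is_target <- as.integer(vapply(tree$nodes[ids], function(n) n$is_target,
                                     logical(1)))
  out$is_scrolling <- as.integer(vapply(tree$nodes[ids],
                                        function(n) n$is_scrolling_screen,
                                        logical(1)))
  out$menu_length_override <- vapply(tree$nodes[ids], function(n) {
    if (is.na(n$menu_length_override)) "" else
      as.character(n$menu_length_override)
  }, character(1))
  out
}

#' Read / write the navigation CSV dialect
#'
#' Thin wrappers around [parse_nav_table()] / [serialize_nav_table()] using
#' UTF-8 CSV with a header row.
#'
#' @param path File path.
#' @param tree A `nav_tree`.
#' @return `read_nav_csv` returns a `nav_tree`; `write_nav_csv` returns
#'   `path` invisibly.
#' @export
read_nav_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8")
  parse_nav_table(df)
}

#' @rdname read_nav_csv
#' @export
write_nav_csv <- function(tree, path) {
  utils::write.csv(serialize_nav_table(tree), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- nested (JSON) dialect -----------------------------------------------

#' Build a navigation tree from a nested list
#'
#' Programmatic mirror of the node fields with children inline: each element
#' is a list with `label` and optionally `id`, `kind`, `is_target`,
#' `is_scrolling_screen`, `menu_length_override` and `children` (a list of
#' the same shape). Unspecified kinds default to `"screen"` for internal
#' nodes and `"data_element"` for leaves.
#'
#' @param x Nested list describing the root.
#' @return A validated [nav_tree()].
#' @export
nav_tree_from_list <- function(x) {
  nodes <- list()
  next_id <- 0L
  walk <- function(spec) {
    next_id <<- next_id + 1L
    id <- if (!is.null(spec$id)) as.character(spec$id) else paste0("n", next_id)
    kids <- spec$children
    kind <- if (!is.null(spec$kind)) spec$kind else
      if (length(kids)) "screen" else "data_element"
    n <- nav_node(
      id, as.character(spec$label), kind,
      is_target = isTRUE(spec$is_target),
      is_scrolling_screen = isTRUE(spec$is_scrolling_screen),
      menu_length_override = if (is.null(spec$menu_length_override))
        NA_integer_ else as.integer(spec$menu_length_override)
    )
    n$children <- vapply(kids, walk, character(1))
    nodes[[id]] <<- n
    id
  }
  root_id <- walk(x)
  nav_tree(nodes, root_id)
}

nav_tree_to_list <- function(tree, id = tree$root_id) {
  n <- tree$nodes[[id]]
  out <- list(id = n$id, label = n$label, kind = n$kind,
              is_target = n$is_target,
              is_scrolling_screen = n$is_scrolling_screen)
  if (!is.na(n$menu_length_override)) {
    out$menu_length_override <- n$menu_length_override
  }
  out$children <- lapply(n$children, function(ch) nav_tree_to_list(tree, ch))
  out
}

#' Read / write the nested JSON dialect
#'
#' @param path File path.
#' @param tree A `nav_tree`.
#' @return `read_nav_json` returns a `nav_tree`; `write_nav_json` returns
#'   `path` invisibly.
#' @export
read_nav_json <- function(path) {
  nav_tree_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname read_nav_json
#' @export
write_nav_json <- function(tree, path) {
  jsonlite::write_json(nav_tree_to_list(tree), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
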