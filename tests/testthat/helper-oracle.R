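# Independent oracles, deliberately written against the raw tree structure
# with their own traversal code (BFS over an undirected adjacency list), not
# via the package's pathway machinery.

oracle_depths <- function(tree) {
  depth <- stats::setNames(rep(NA_integer_, length(tree$nodes)),
                           names(tree$nodes))
  depth[tree$root_id] <- 0L
  q <- tree$root_id
  while (length(q)) {
    u <- q[[1L]]; q <- q[-1L]
    for (v in tree$nodes[[u]]$children) {
      depth[v] <- depth[u] + 1L
      q <- c(q, v)
    }
  }
  depth
}

oracle_preorder <- function(tree) {
  out <- character(0)
  stack <- tree$root_id
  while (length(stack)) {
    u <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, u)
    stack <- c(tree$nodes[[u]]$children, stack)
  }
  out
}

# unique simple path between two nodes on the tree, via BFS on the
# undirected adjacency
oracle_path <- function(tree, from, to) {
  adj <- lapply(tree$nodes, function(n) n$children)
  for (id in names(tree$nodes)) {
    p <- tree$nodes[[id]]$parent_id
    if (!is.na(p)) adj[[id]] <- c(adj[[id]], p)
  }
  if (from == to) return(from)
  prev <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  seen <- from
  q <- from
  while (length(q)) {
    u <- q[[1L]]; q <- q[-1L]
    for (v in adj[[u]]) {
      if (v %in% seen) next
      prev[v] <- u
      if (v == to) {
        path <- to
        while (path[[1L]] != from) path <- c(prev[path[[1L]]], path)
        return(path)
      }
      seen <- c(seen, v)
      q <- c(q, v)
    }
  }
  stop("no path found (tree disconnected?)")
}

# brute-force action counts for a traced pathway over the given tree and
# targets (document order), mirroring the published counting rules
oracle_counts <- function(tree, targets, routing = "lca") {
  depth <- oracle_depths(tree)
  ord <- oracle_preorder(tree)
  targets <- ord[ord %in% targets]

  E <- 0L
  lev_count <- function() integer(0)
  bump <- function(v, l, k = 1L) {
    l <- as.character(l)
    v[l] <- (if (is.na(v[l])) 0L else v[l]) + k
    v
  }
  IS <- lev_count(); C <- lev_count(); SS <- lev_count()
  reached <- character(0)
  entered <- character(0)

  enter <- function(v, goal) {
    n <- tree$nodes[[v]]
    entered <<- unique(c(entered, v))
    if (goal || (n$is_target && !v %in% reached)) {
      E <<- E + 1L
      reached <<- c(reached, v)
    } else if (n$is_target) {
      # pass-through of an already-reached target: nothing
    } else if (n$kind == "menu_item") {
      C <<- bump(C, depth[v])
    } else {
      IS <<- bump(IS, depth[v])
      C <<- bump(C, depth[v])
    }
    if (n$is_scrolling_screen) SS <<- bump(SS, depth[v], 2L)
  }

  pos <- tree$root_id
  for (t in targets) {
    if (t %in% reached) { pos <- t; next }
    legs <- if (routing == "root" && pos != tree$root_id) {
      list(oracle_path(tree, pos, tree$root_id),
           oracle_path(tree, tree$root_id, t))
    } else {
      list(oracle_path(tree, pos, t))
    }
    for (path in legs) {
      if (length(path) < 2L) next
      for (i in 2L:length(path)) {
        u <- path[[i - 1L]]; v <- path[[i]]
        if (depth[v] > depth[u]) enter(v, goal = v == t)
      }
    }
    pos <- t
  }

  parents <- unique(stats::na.omit(vapply(tree$nodes[entered],
                                          function(n) n$parent_id,
                                          character(1))))
  ml <- 0L
  for (p in parents) {
    n <- tree$nodes[[p]]
    m <- if (!is.na(n$menu_length_override)) n$menu_length_override else
      length(n$children)
    if (m >= 2L) ml <- ml + m
  }
  list(E = E, IS_by_level = IS, C_by_level = C, SS_by_level = SS,
       ML = as.integer(ml))
}

norm_levels <- function(v) {
  v <- v[v != 0L]
  if (!length(v)) return(stats::setNames(integer(0), character(0)))
  v <- v[order(as.integer(names(v)))]
  stats::setNames(as.integer(v), names(v))
}

expect_tally_equal <- function(tally, oracle) {
  expect_identical(tally$E, oracle$E)
  expect_identical(norm_levels(tally$IS_by_level),
                   norm_levels(oracle$IS_by_level))
  expect_identical(norm_levels(tally$C_by_level),
                   norm_levels(oracle$C_by_level))
  expect_identical(norm_levels(tally$SS_by_level),
                   norm_levels(oracle$SS_by_level))
  expect_identical(tally$ML, oracle$ML)
}

# random annotated tree for property sweeps: node count <= max_nodes
random_tree <- function(max_nodes = 30L, p_menu = 0.2, p_scroll = 0.15) {
  n <- sample(2:max_nodes, 1L)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample(i - 1L, 1L),
                                  integer(1)))
  specs <- lapply(seq_len(n), function(i) {
    nav_node(paste0("v", i), paste0("v", i), kind = "screen")
  })
  nodes <- stats::setNames(specs, paste0("v", seq_len(n)))
  for (i in 2:n) {
    p <- paste0("v", parent[i])
    nodes[[p]]$children <- c(nodes[[p]]$children, paste0("v", i))
  }
  leaves <- setdiff(paste0("v", seq_len(n)),
                    paste0("v", parent[!is.na(parent)]))
  for (id in leaves) nodes[[id]]$kind <- "data_element"
  internal <- setdiff(paste0("v", 2:n), leaves)
  for (id in internal) {
    if (stats::runif(1) < p_menu) nodes[[id]]$kind <- "menu_item"
    else if (stats::runif(1) < p_scroll) nodes[[id]]$is_scrolling_screen <- TRUE
  }
  nav_tree(nodes, "v1")
}

# run-length-encoding oracle for task instances (gap-aware)
oracle_instances <- function(session) {
  seg <- session$segments
  n <- nrow(seg)
  split_here <- c(TRUE, (seg$task[-1L] != seg$task[-n]) |
                    (seg$start_s[-1L] > seg$end_s[-n]))
  ids <- cumsum(split_here)
  counts <- table(factor(seg$task[!duplicated(ids)],
                         levels = unique(seg$task)))
  stats::setNames(as.integer(counts), names(counts))
}

# quadratic alternation scanner: returns each maximal alternating window as
# "i:j" over the collapsed sequence, for runs with >= min_repeats of each
oracle_pogo_windows <- function(key, min_repeats = 3L) {
  keep <- c(TRUE, key[-1L] != key[-length(key)])
  key <- key[keep]
  m <- length(key)
  found <- character(0)
  for (i in seq_len(max(m - 2L, 0L))) {
    j <- i + 1L
    while (j + 1L <= m && key[j + 1L] == key[j - 1L]) j <- j + 1L
    len <- j - i + 1L
    if (len >= 3L && min(ceiling(len / 2), floor(len / 2)) >= min_repeats) {
      # only maximal runs: a run is left-extensible iff key[i-1] == key[i+1]
      if (i == 1L || key[i - 1L] != key[i + 1L]) {
        found <- c(found, paste0(i, ":", j))
      }
    }
  }
  found
}
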