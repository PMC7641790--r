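test_that("a deep chain requires one transition per intermediate screen", {
  tree <- chain_tree(9)          # root + 9 screens + target element
  pw <- trace_pathway(tree)
  expect_equal(sum(pw$steps$action == "visit_screen_transition"), 9L)
  expect_equal(sum(pw$steps$action == "reach_element"), 1L)
  expect_equal(length(pw$target_order), 1L)
})

test_that("an element on the top screen needs no navigation", {
  tree <- nav_tree_from_list(list(
    label = "root", kind = "screen",
    children = list(list(label = "vital signs", kind = "data_element",
                         is_target = TRUE))
  ))
  pw <- trace_pathway(tree)
  expect_equal(pw$steps$action, "reach_element")
  tally <- tally_actions(pw, tree)
  expect_equal(tally$E, 1L)
  expect_equal(sum(tally$IS_by_level), 0L)
})

test_that("unknown or empty target sets raise errors", {
  tree <- chain_tree(2)
  expect_error(trace_pathway(tree, targets = "nope"), "missing node")
  expect_error(trace_pathway(tree, targets = character(0)), "empty targets")
})

test_that("scrolling screens count two scroll actions per entry", {
  leaf <- list(label = "e", kind = "data_element", is_target = TRUE)
  tree <- nav_tree_from_list(list(
    label = "root", kind = "screen",
    children = list(list(label = "long screen", kind = "screen",
                         is_scrolling_screen = TRUE,
                         children = list(leaf)))
  ))
  tally <- tally_actions(trace_pathway(tree), tree)
  expect_equal(unname(tally$SS_by_level["1"]), 2L)
})

test_that("empty pathways tally to zero and compute a zero index", {
  tree <- chain_tree(2)
  empty <- structure(list(
    steps = data.frame(node_id = character(0), action = character(0),
                       level = integer(0)),
    target_order = character(0), routing = "lca"
  ), class = "nav_pathway")
  tally <- tally_actions(empty, tree)
  expect_equal(tally$E, 0L)
  expect_equal(tally$ML, 0L)
  bd <- compute_dfi(tally)
  expect_equal(bd$total, 0)
})

test_that("menu items on the route count as clicks, not transitions", {
  tree <- nav_tree_from_list(list(
    label = "root", kind = "screen",
    children = list(list(
      label = "tab", kind = "menu_item",
      children = list(list(
        label = "panel", kind = "screen",
        children = list(list(label = "e", kind = "data_element",
                             is_target = TRUE))
      ))
    ))
  ))
  tally <- tally_actions(trace_pathway(tree), tree)
  expect_equal(sum(tally$IS_by_level), 1L)   # panel only
  expect_equal(sum(tally$C_by_level), 2L)    # tab click + panel transition
})

test_that("multiplier policies weight level counts as declared", {
  tally <- structure(list(
    E = 3L,
    IS_by_level = c(`1` = 2L, `3` = 1L),
    C_by_level = c(`1` = 2L, `3` = 1L),
    SS_by_level = c(`2` = 2L),
    ML = 5L
  ), class = "action_tally")
  dw <- compute_dfi(tally, multiplier_policy("depth_weighted"))
  expect_equal(dw$IS_term, 1 * 2 + 3 * 1)
  expect_equal(dw$SS_term, 2 * 2)
  expect_equal(dw$total, 3 + 5 + 5 + 4 + 5)
  ct <- compute_dfi(tally, multiplier_policy("constant", constant_value = 2))
  expect_equal(ct$IS_term, 2 * 3)
  expect_equal(ct$E_term, 3)                 # E never weighted
  # linearity: scaling every count by k scales every weighted term by k
  k <- 3L
  scaled <- tally
  scaled$E <- tally$E * k
  scaled$IS_by_level <- tally$IS_by_level * k
  scaled$C_by_level <- tally$C_by_level * k
  scaled$SS_by_level <- tally$SS_by_level * k
  scaled$ML <- tally$ML * k
  ds <- compute_dfi(scaled, multiplier_policy("depth_weighted"))
  for (term in c("E_term", "IS_term", "C_term", "SS_term", "ML_term")) {
    expect_equal(ds[[term]], k * dw[[term]])
  }
})

test_that("single-target chains follow the closed form 1 + 2(d-1)", {
  # constant unit weights, unit menus, no scrolling: one element reach,
  # d - 1 intermediate screens each also counted as a click, no menu burden
  for (d in 1:10) {
    tree <- chain_tree(d - 1L)   # element sits at depth d
    bd <- dfi(tree, policy = multiplier_policy("constant", 1))
    expect_equal(bd$total, 1 + 2 * (d - 1))
  }
})

test_that("pathway counts match the brute-force route walker", {
  set.seed(101)
  for (rep in 1:60) {
    tree <- random_tree(30L)
    leaves <- names(tree$nodes)[vapply(tree$nodes,
                                       function(n) n$kind == "data_element",
                                       logical(1))]
    k <- sample(seq_len(min(4L, length(leaves))), 1L)
    targets <- sample(leaves, k)
    for (routing in c("lca", "root")) {
      tally <- tally_actions(
        trace_pathway(tree, targets, routing = routing), tree)
      expect_tally_equal(tally, oracle_counts(tree, targets, routing))
    }
  }
})

test_that("adding a target element never decreases the index", {
  set.seed(202)
  for (rep in 1:20) {
    tree <- random_tree(25L)
    leaves <- names(tree$nodes)[vapply(tree$nodes,
                                       function(n) n$kind == "data_element",
                                       logical(1))]
    if (length(leaves) < 2L) next
    base_t <- sample(leaves, 1L)
    extra <- sample(setdiff(leaves, base_t), 1L)
    for (routing in c("lca", "root")) {
      b0 <- dfi(tree, base_t, routing = routing)
      b1 <- dfi(tree, c(base_t, extra), routing = routing)
      for (term in c("E_term", "IS_term", "C_term", "SS_term", "ML_term")) {
        expect_gte(b1[[term]], b0[[term]])
      }
      expect_gte(b1$total, b0$total)
    }
  }
})

test_that("system comparison reports deltas and a total ratio", {
  t1 <- structure(list(E = 5L, IS_by_level = c(`1` = 5L),
                       C_by_level = c(`1` = 5L),
                       SS_by_level = stats::setNames(integer(0), character(0)),
                       ML = 5L), class = "action_tally")
  a <- compute_dfi(t1, multiplier_policy("constant", 1))
  b <- compute_dfi(t1, multiplier_policy("constant", 1))
  same <- compare_systems(a, b)
  expect_equal(same$ratio, 1)
  expect_true(all(same$deltas == 0))

  zero <- compute_dfi(structure(list(
    E = 0L, IS_by_level = integer(0), C_by_level = integer(0),
    SS_by_level = integer(0), ML = 0L), class = "action_tally"))
  degenerate <- compare_systems(zero, a)
  expect_true(is.na(degenerate$ratio))
  expect_equal(unname(degenerate$deltas["total"]), a$total)
})

test_that("the index prints as its component sum", {
  bd <- dfi(demo_nav_tree("dense"))
  expect_equal(format_dfi(bd), "DFI = 36 + 136 + 136 + 0 + 39 = 347")
})
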