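two_leaf_tree <- function() {
  nav_tree_from_list(list(
    label = "root", kind = "screen",
    children = list(list(label = "L", kind = "data_element"),
                    list(label = "R", kind = "data_element"))
  ))
}

test_that("angular extents split equally or by leaf weight", {
  lay <- layout_sunburst(two_leaf_tree(), weighting = "equal_split")
  kids <- lay[lay$ring == 0L, ]
  expect_equal(kids$end_angle_deg - kids$start_angle_deg, c(180, 180))

  # children with 1 and 3 leaf descendants -> 90 and 270 degrees
  tree <- nav_tree_from_list(list(
    label = "root", kind = "screen",
    children = list(
      list(label = "thin", kind = "screen",
           children = list(list(label = "a", kind = "data_element"))),
      list(label = "wide", kind = "screen",
           children = lapply(c("b", "c", "d"), function(l)
             list(label = l, kind = "data_element")))
    )
  ))
  lay <- layout_sunburst(tree, weighting = "leaf_weighted")
  kids <- lay[lay$ring == 0L, ]
  expect_equal(kids$end_angle_deg - kids$start_angle_deg, c(90, 270))

  # a pure chain: every segment spans the full circle
  lay <- layout_sunburst(chain_tree(4))
  expect_true(all(lay$end_angle_deg - lay$start_angle_deg == 360))
})

test_that("children partition their parent's extent exactly", {
  set.seed(31)
  for (weighting in c("equal_split", "leaf_weighted")) {
    for (rep in 1:10) {
      tree <- random_tree(25L)
      lay <- layout_sunburst(tree, weighting = weighting)
      rownames(lay) <- lay$node_id
      for (id in names(tree$nodes)) {
        kids <- tree$nodes[[id]]$children
        if (!length(kids)) next
        expect_identical(lay[kids[1L], "start_angle_deg"],
                         lay[id, "start_angle_deg"])
        expect_identical(lay[kids[length(kids)], "end_angle_deg"],
                         lay[id, "end_angle_deg"])
        if (length(kids) > 1L) {
          expect_identical(lay[kids[-length(kids)], "end_angle_deg"],
                           lay[kids[-1L], "start_angle_deg"])
        }
        expect_true(all(lay[kids, "end_angle_deg"] >
                          lay[kids, "start_angle_deg"]))
      }
      # ring index = depth - 1 for every segment
      expect_equal(lay[names(tree$nodes), "ring"],
                   unname(oracle_depths(tree)) - 1L)
    }
  }
})

test_that("pathway highlighting marks exactly the traversed nodes", {
  tree <- chain_tree(9)
  lay <- layout_sunburst(tree)
  pw <- trace_pathway(tree)
  hi <- highlight_pathway(lay, pw)
  # 11-node chain: root + 9 screens + element, all on the pathway
  expect_equal(sum(hi$fill_class == "highlight"), 11L)

  # empty pathway leaves the layout untouched
  empty <- structure(list(
    steps = data.frame(node_id = character(0), action = character(0),
                       level = integer(0)),
    target_order = character(0), routing = "lca"
  ), class = "nav_pathway")
  expect_identical(highlight_pathway(lay, empty), lay)

  # two disjoint highlights accumulate to the union
  tree2 <- demo_nav_tree("dense")
  lay2 <- layout_sunburst(tree2)
  t_all <- nav_targets(tree2)
  pw_a <- trace_pathway(tree2, t_all[1])
  pw_b <- trace_pathway(tree2, t_all[length(t_all)])
  both <- highlight_pathway(highlight_pathway(lay2, pw_a), pw_b)
  want <- unique(c(tree2$root_id, pw_a$steps$node_id, pw_b$steps$node_id))
  expect_setequal(both$node_id[both$fill_class == "highlight"], want)

  # pathway over nodes missing from the layout is an inconsistency
  ghost <- structure(list(
    steps = data.frame(node_id = "not-a-node",
                       action = "visit_screen_transition", level = 1L),
    target_order = character(0), routing = "lca"
  ), class = "nav_pathway")
  expect_error(highlight_pathway(lay, ghost), "without a segment")
})

test_that("rendering is deterministic with one sector path per node", {
  tree <- two_leaf_tree()
  lay <- layout_sunburst(tree)
  svg <- render_sunburst(lay)
  expect_identical(svg, render_sunburst(lay))              # byte-identical
  expect_equal(lengths(regmatches(svg, gregexpr("<path ", svg))), 2L)
  expect_equal(lengths(regmatches(svg, gregexpr("<circle ", svg))), 1L)

  set.seed(33)
  for (rep in 1:5) {
    tree <- random_tree(20L)
    svg <- render_sunburst(layout_sunburst(tree))
    expect_equal(lengths(regmatches(svg, gregexpr("<path ", svg))),
                 nav_size(tree) - 1L)
  }
})

test_that("drill-down re-roots a subtree as its own sunburst", {
  tree <- demo_nav_tree("dense")
  mid <- trace_pathway(tree)$steps$node_id[5]
  sub <- layout_sunburst_subtree(tree, mid)
  expect_equal(sum(sub$ring == -1L), 1L)
  expect_equal(sub$node_id[sub$ring == -1L], mid)
})
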