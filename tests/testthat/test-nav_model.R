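test_that("path-per-row parsing merges prefixes and preserves sibling order", {
  rows <- data.frame(
    level_1 = c("A", "A", "A"),
    level_2 = c("B", "C", "B"),
    level_3 = c("", "", "D"),
    kind = c("screen", "data_element", "data_element"),
    is_target = c(0, 1, 1),
    is_scrolling = c(0, 0, 0),
    menu_length_override = c("", "", ""),
    stringsAsFactors = FALSE
  )
  tree <- parse_nav_table(rows)
  expect_s3_class(tree, "nav_tree")
  expect_equal(nav_size(tree), 4L)
  root <- tree$nodes[[tree$root_id]]
  labs <- vapply(tree$nodes[root$children], `[[`, "", "label")
  expect_equal(unname(labs), c("B", "C"))   # first-appearance order
  b_id <- root$children[[1L]]
  expect_length(tree$nodes[[b_id]]$children, 1L)
  expect_equal(tree$max_depth, 2L)
})

test_that("single-branch and degenerate tables parse to chains", {
  # one row per leaf: a root-to-element path across 11 labels
  labs <- c("root", paste0("S", 1:9), "element")
  rows <- as.data.frame(as.list(labs), stringsAsFactors = FALSE)
  names(rows) <- paste0("level_", 1:11)
  rows$kind <- "data_element"; rows$is_target <- 1
  rows$is_scrolling <- 0; rows$menu_length_override <- ""
  tree <- parse_nav_table(rows)
  expect_equal(nav_size(tree), 11L)
  expect_equal(tree$max_depth, 10L)

  one <- data.frame(level_1 = "root", kind = "screen", is_target = 0,
                    is_scrolling = 0, menu_length_override = "")
  root_only <- parse_nav_table(one)
  expect_equal(nav_size(root_only), 1L)
  expect_equal(root_only$max_depth, 0L)
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(parse_nav_table(data.frame()), "empty input")
  ragged <- data.frame(level_1 = "A", level_2 = "", level_3 = "C",
                       kind = "screen", stringsAsFactors = FALSE)
  expect_error(parse_nav_table(ragged), "ragged")
  conflict <- data.frame(
    level_1 = c("A", "A"), level_2 = c("B", "B"),
    kind = c("data_element", "screen"), is_target = c(1, 1),
    is_scrolling = c(0, 0), stringsAsFactors = FALSE
  )
  expect_error(parse_nav_table(conflict), "conflicting annotations.*A / B")
})

test_that("tabular and JSON dialects round-trip trees exactly", {
  # structured cases
  for (tr in list(chain_tree(9), demo_nav_tree("dense"),
                  demo_nav_tree("integrated"))) {
    back <- parse_nav_table(serialize_nav_table(tr))
    expect_true(nav_tree_identical(tr, back))
  }
  # one-row serializations of degenerate trees
  expect_equal(nrow(serialize_nav_table(
    nav_tree_from_list(list(label = "root", kind = "screen")))), 1L)
  expect_equal(nrow(serialize_nav_table(chain_tree(9))), 1L)

  # randomized sweep, CSV file dialect and JSON dialect
  set.seed(42)
  for (rep in 1:20) {
    tr <- random_tree(20L)
    csv <- tempfile(fileext = ".csv")
    json <- tempfile(fileext = ".json")
    write_nav_csv(tr, csv); write_nav_json(tr, json)
    expect_true(nav_tree_identical(tr, read_nav_csv(csv)))
    expect_true(nav_tree_identical(tr, read_nav_json(json)))
    unlink(c(csv, json))
  }
})

test_that("tree invariants hold: depths, unique root, reachability", {
  set.seed(7)
  for (rep in 1:10) {
    tr <- random_tree(25L)
    depth <- oracle_depths(tr)
    for (id in names(tr$nodes)) {
      expect_identical(tr$nodes[[id]]$depth, depth[[id]])
    }
    expect_equal(tr$max_depth, max(depth))
    expect_setequal(oracle_preorder(tr), names(tr$nodes))
  }
  # complete-tree node count: (b^(d+1) - 1) / (b - 1)
  tr <- generate_nav_tree(depth = 3, branching = 3, n_targets = 2, seed = 1)
  expect_equal(nav_size(tr), (3^4 - 1) / (3 - 1))
})

test_that("structural errors are caught at construction", {
  a <- nav_node("a", "a"); b <- nav_node("b", "b")
  a$children <- "b"; b$children <- "a"
  expect_error(nav_tree(list(a, b), "a"), "cycle")
  orphan <- nav_node("c", "c")
  expect_error(nav_tree(list(nav_node("a", "a"), orphan), "a"),
               "unreachable")
  mi <- nav_node("m", "m", kind = "menu_item", is_target = TRUE)
  root <- nav_node("r", "r"); root$children <- "m"
  expect_error(nav_tree(list(root, mi), "r"), "menu items cannot be targets")
})
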