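test_that("the six-point line builds two branches merging at an all-frame root", {
  tr <- build_tree(six_points(), epsilon_schedule(0.05, 0.05, minpts = 2))
  expect_true(tr$complete)
  expect_true(validate_tree(tr)$valid)
  leaves <- tree_leaves(tr)
  expect_length(leaves, 2L)
  leaf_sets <- lapply(leaves, node_members, tree = tr)
  expect_setequal(vapply(leaf_sets, length, integer(1)), 3L)
  expect_setequal(unlist(leaf_sets), 0:5)
  expect_equal(sort(node_members(tr, tr$root_id)), 0:5)
  # the root is born when the 4.75-unit gap becomes bridgeable
  root_eps <- tr$nodes$eps_first[tr$nodes$node_id == tr$root_id]
  expect_gte(root_eps, 4.75 - 1e-9)
})

test_that("a single well yields a pure path with one leaf", {
  set.seed(21)
  x <- matrix(rnorm(200 * 2, sd = 0.5), 200, 2)
  # eps_init on the scale of typical point spacing, so the well is
  # density-connected the moment clusters first form
  tr <- build_tree(x, epsilon_schedule(0.4, 0.1, minpts = 4))
  expect_true(tr$complete)
  expect_length(tree_leaves(tr), 1L)
  # no level ever holds two clusters: children counts never exceed one
  kids <- table(tr$nodes$parent_id)
  expect_true(all(kids <= 1))
})

test_that("degenerate and undersized inputs behave as documented", {
  same <- matrix(1, 4, 2)  # n = minpts identical points
  tr <- build_tree(same, epsilon_schedule(0.3, 0.1, minpts = 4))
  expect_true(tr$complete)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(tr$nodes$level_first, 0L)
  expect_equal(tr$nodes$eps_first, 0.3)

  expect_error(build_tree(matrix(1, 2, 2), epsilon_schedule(1, 1, minpts = 4)),
               "fewer frames")
  expect_error(epsilon_schedule(0, 0.1), "eps_init")
})

test_that("an exhausted level cap returns a flagged forest, not a truncation", {
  tr <- build_tree(six_points(),
                   epsilon_schedule(0.05, 0.05, minpts = 2, max_levels = 3))
  expect_false(tr$complete)
  expect_true(is.na(tr$root_id))
  expect_gt(sum(is.na(tr$nodes$parent_id)), 1L)
  expect_error(tree_newick(tr), "incomplete")
  rep <- validate_tree(tr)
  expect_equal(rep$containment_fraction, 1)
})

test_that("trees on separated wells recover the well count, purity and merge order", {
  gaps <- c(2.0, 2.8, 3.8)           # distinct gaps, >= 8x the 0.25 width
  spec <- line_well_spec(gaps, width = 0.25)
  s <- sample_gaussian_wells(spec, 800, seed = 31)
  x <- sample_points(s)
  tr <- build_tree(x, epsilon_schedule(0.25, 0.1, minpts = 4))
  expect_true(tr$complete)
  expect_equal(validate_tree(tr)$containment_fraction, 1)

  leaves <- tree_leaves(tr)
  expect_length(leaves, nrow(spec$centers))
  frames_by_well <- lapply(seq_len(nrow(spec$centers)),
                           function(w) s$frame_index[s$well == w])
  for (id in leaves) {
    wl <- s$well[match(node_members(tr, id), s$frame_index)]
    expect_gte(max(table(wl)) / length(wl), 0.95)
  }

  # closer well pairs merge at strictly smaller epsilon
  merge_eps <- well_merge_eps(tr, frames_by_well)
  expect_lt(merge_eps[1, 2], merge_eps[2, 3])
  expect_lt(merge_eps[2, 3], merge_eps[3, 4])
  # and the event sequence matches the single-linkage oracle
  mo <- expected_merge_order(spec)
  ev <- vapply(seq_len(nrow(mo)), function(i) {
    a <- match(mo$group_a[[i]][1], spec$labels)
    b <- match(mo$group_b[[i]][1], spec$labels)
    merge_eps[a, b]
  }, numeric(1))
  expect_true(all(diff(ev) > 0))
})

test_that("validation rejects hand-corrupted trees and accepts trivial ones", {
  tr <- build_tree(six_points(), epsilon_schedule(0.05, 0.05, minpts = 2))
  bad <- tr
  i <- which(!is.na(bad$nodes$parent_id))[1]
  bad$nodes$members[[i]] <- c(bad$nodes$members[[i]], 999L)
  expect_error(validate_tree(bad), "validation-error")
  expect_false(validate_tree(bad, strict = FALSE)$valid)

  # overlapping siblings
  bad2 <- tr
  leaves <- tree_leaves(bad2)
  shared <- node_members(bad2, leaves[1])[1]
  j <- match(leaves[2], bad2$nodes$node_id)
  bad2$nodes$members[[j]] <- sort(c(bad2$nodes$members[[j]], shared))
  # make the extended leaf still a subset of the root so only disjointness fails
  expect_error(validate_tree(bad2), "share")

  single <- build_tree(matrix(1, 4, 2), epsilon_schedule(1, 1, minpts = 4))
  expect_true(validate_tree(single)$valid)
})

test_that("newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  tr <- build_tree(six_points(), epsilon_schedule(0.05, 0.05, minpts = 2))
  nwk <- tree_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), length(tree_leaves(tr)))
  expect_setequal(ph$tip.label, paste0("n", tree_leaves(tr)))
  # branch lengths are the epsilon spans between child and parent births
  expect_true(all(ph$edge.length >= 0))
})

test_that("node tables and DOT graphs serialise the full hierarchy", {
  tr <- build_tree(six_points(), epsilon_schedule(0.05, 0.05, minpts = 2))
  tf <- tempfile(fileext = ".tsv")
  write_tree_nodes(tr, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), nrow(tr$nodes))
  expect_equal(sort(as.integer(strsplit(
    tab$members[tab$node_id == tr$root_id], ",")[[1]])), 0:5)

  td <- tempfile(fileext = ".dot")
  write_tree_dot(tr, td)
  dot <- readLines(td)
  expect_equal(sum(grepl("->", dot)),
               sum(!is.na(tr$nodes$parent_id)))
})
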