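test_that("node intensity follows the logarithmic scale with a display floor", {
  expect_equal(node_intensity(1000, 1000), 1.0)
  expect_equal(node_intensity(2, 2, min_display = 1), 1.0)
  expect_equal(node_intensity(10, 1000), 1 / 3)
  expect_equal(node_intensity(4, 1000), 0)   # below the floor of 5
  expect_equal(node_intensity(5, 1000), log10(5) / 3)
  expect_equal(node_intensity(0, 100), 0)
  # monotone in count for fixed total
  counts <- 0:50
  expect_true(all(diff(node_intensity(counts, 50)) >= 0))
  expect_error(node_intensity(1, 1), "total_of_type")
  expect_error(node_intensity(7, 5), "count_in_node")
})

two_well_fixture <- function(seed = 41) {
  spec <- line_well_spec(3, width = 0.3)
  s <- sample_gaussian_wells(spec, 400, seed = seed)
  tr <- build_tree(sample_points(s), epsilon_schedule(0.1, 0.1, minpts = 4))
  labels <- tibble::tibble(frame_index = s$frame_index,
                           simulation_id = "demo",
                           well_label = s$well_label,
                           frame_time = as.numeric(s$frame_index))
  list(spec = spec, sample = s, tree = tr, labels = labels)
}

test_that("categorical annotation conserves counts down the hierarchy", {
  fx <- two_well_fixture()
  ann <- annotate_tree(fx$tree, fx$labels, "well_label")

  # root carries the global totals at full intensity
  root <- dplyr::filter(ann, node_id == fx$tree$root_id)
  expect_equal(root$count, root$total)
  expect_equal(root$intensity, rep(1, nrow(root)))

  # child counts never exceed parent counts, per label value
  nd <- fx$tree$nodes
  joined <- dplyr::inner_join(
    ann,
    dplyr::select(nd, node_id, parent_id),
    by = "node_id")
  parent_counts <- dplyr::select(ann, parent_id = node_id, value,
                                 parent_count = count)
  cmp <- dplyr::inner_join(joined, parent_counts,
                           by = c("parent_id", "value"))
  expect_true(all(cmp$count <= cmp$parent_count))

  # pure leaves count zero for the other value
  for (id in tree_leaves(fx$tree)) {
    leaf <- dplyr::filter(ann, node_id == id)
    expect_equal(sum(leaf$count == 0), 1L)
  }

  # per-value counts on a node sum to the node member count
  per_node <- dplyr::summarise(dplyr::group_by(ann, node_id),
                               total_count = sum(count))
  expect_equal(per_node$total_count[match(nd$node_id, per_node$node_id)],
               nd$n_members)

  expect_error(annotate_tree(fx$tree, fx$labels[-1, ], "well_label"),
               "missing-label")
})

test_that("numeric annotation discretises by terciles or explicit cuts", {
  fx <- two_well_fixture()
  set.seed(5)
  fx$labels$uniform <- runif(nrow(fx$labels))
  ann <- annotate_numeric(fx$tree, fx$labels, "uniform")
  cuts <- attr(ann, "breaks")
  expect_equal(cuts, c(1 / 3, 2 / 3), tolerance = 0.08)
  expect_setequal(unique(ann$value), c("T1", "T2", "T3"))

  # an already 3-valued covariate with explicit interior cuts matches the
  # categorical route
  fx$labels$threeval <- rep(c(1, 5, 9), length.out = nrow(fx$labels))
  ann3 <- annotate_numeric(fx$tree, fx$labels, "threeval", breaks = c(3, 7))
  fx$labels$as_cat <- paste0("T", match(fx$labels$threeval, c(1, 5, 9)))
  cat3 <- annotate_tree(fx$tree, fx$labels, "as_cat")
  expect_equal(ann3$count, cat3$count)
  expect_equal(ann3$intensity, cat3$intensity)

  fx$labels$flat <- 1
  expect_error(annotate_numeric(fx$tree, fx$labels, "flat"),
               "degenerate-breaks")
})

test_that("representatives are the latest frames with deterministic ties", {
  fx <- two_well_fixture()
  tr <- fx$tree
  # hand times: member with time 7 wins over 3 and 5
  some_node <- tree_leaves(tr)[1]
  members <- node_members(tr, some_node)
  tt <- rep(0, tr$n_points)
  tt[members[1:3] + 1L] <- c(3, 7, 5)
  rep1 <- select_representative(tr, some_node, tt)
  expect_equal(rep1$frame_index, members[2])

  # tie at the maximum: lowest frame index wins
  tt[members[1:2] + 1L] <- c(7, 7)
  rep2 <- select_representative(tr, some_node, tt)
  expect_equal(rep2$frame_index, min(members[1:2]))

  # re-running selection is bit-identical
  expect_identical(select_representative(tr, some_node, tt),
                   select_representative(tr, some_node, tt))
  expect_error(select_representative(tr, 9999, tt), "unknown node")
})

test_that("rmsd obeys identity, symmetry and superposition contracts", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_coords(a, a), 0, tolerance = 1e-12)
  expect_lt(rmsd_coords(a, a + 5), 1e-10)                 # translation removed
  rot <- random_rotation(12)
  expect_lt(rmsd_coords(a, a %*% t(rot), superpose = TRUE), 1e-8)

  b <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_coords(a, b), rmsd_coords(b, a), tolerance = 1e-10)
  expect_lte(rmsd_coords(a, b, superpose = TRUE),
             rmsd_coords(a, b, superpose = FALSE) + 1e-12)

  # two atoms at distance d vs a coincident pair, no superposition: d/sqrt(2)
  d <- 1.3
  pair <- rbind(c(0, 0, 0), c(d, 0, 0))
  coincident <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(rmsd_coords(pair, coincident, superpose = FALSE), d / sqrt(2))

  expect_error(rmsd_coords(a, b[1:5, ]), "equal-sized")
})

test_that("node representative RMSD compares the latest branch structures", {
  spec <- demo_well_spec()
  s <- sample_gaussian_wells(spec, 300, seed = 13)
  ens <- conf_ensemble(sample_points(s))
  sup <- superpose_frames(ens)
  fit <- fit_pca(sup, k = 3)
  proj <- project_frames(fit, sup)
  tr <- build_tree(proj, epsilon_schedule(0.3, 0.1, minpts = 4))
  leaves <- tree_leaves(tr)
  expect_length(leaves, 2L)
  rr <- representative_rmsd(tr, leaves[1], leaves[2], sup)
  # the wells differ by an 8 nm displacement of one of three atoms; after
  # superposition the deformation RMSD stays of that order
  expect_gt(rr$rmsd, 1)
  expect_lt(rr$rmsd, 8)
  expect_equal(rr$rmsd,
               rmsd_coords(matrix(sup$coords[rr$frame_a + 1, ], ncol = 3,
                                  byrow = TRUE),
                           matrix(sup$coords[rr$frame_b + 1, ], ncol = 3,
                                  byrow = TRUE)))
})

test_that("colour mixing is additive on white", {
  ann <- tibble::tibble(node_id = c(1, 1), intensity = c(1, 1),
                        color = c("#00ffff", "#ff00ff"))
  expect_equal(node_color_mix(ann)$color, "#0000FF")  # cyan + magenta = blue
  half <- tibble::tibble(node_id = 2, intensity = 0.5, color = "#00ffff")
  expect_equal(node_color_mix(half)$color, "#80FFFF")
})
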