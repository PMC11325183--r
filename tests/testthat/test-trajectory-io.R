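test_that("multi-model PDB parsing yields frames x atoms in nm", {
  pdb <- c(
    "MODEL        1",
    "ATOM      1  CA  GLY     1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY     2       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  GLY     3       3.000   1.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY     1       1.000   0.000   1.000  1.00  0.00",
    "ATOM      2  CA  GLY     2       2.000   0.000   1.000  1.00  0.00",
    "ATOM      3  CA  GLY     3       3.000   1.000   1.000  1.00  0.00",
    "ENDMDL", "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(pdb, tf)
  ens <- load_ensemble(tf)
  expect_equal(n_frames(ens), 2L)
  expect_equal(n_atoms(ens), 3L)
  expect_equal(ens$coords[1, 1], 0.1)  # 1 Angstrom -> 0.1 nm

  ca_only <- load_ensemble(tf, atom_select = "CA")
  expect_equal(n_atoms(ca_only), 3L)
  expect_error(load_ensemble(tf, atom_select = "CB"), "matched no atoms")
})

test_that("coordinate-matrix parsing enforces the 3N column convention", {
  tf <- tempfile(fileext = ".tsv")
  m <- matrix(round(rnorm(36), 3), 4, 9)
  write.table(m, tf, sep = "\t", row.names = FALSE, col.names = FALSE)
  ens <- load_ensemble(tf)
  expect_equal(n_frames(ens), 4L)
  expect_equal(n_atoms(ens), 3L)
  expect_equal(unname(ens$coords), m)

  # ragged row
  writeLines(c(paste(1:9, collapse = "\t"), paste(1:8, collapse = "\t")), tf)
  expect_error(load_ensemble(tf), "inconsistent column counts")

  # not divisible by 3
  writeLines(paste(1:8, collapse = "\t"), tf)
  expect_error(load_ensemble(tf), "3N columns")

  # csv with header also parses
  tfc <- tempfile(fileext = ".csv")
  writeLines(c(paste(paste0("c", 1:6), collapse = ","),
               "0,0,0,1,1,1", "0,0,1,1,1,0"), tfc)
  expect_equal(n_frames(load_ensemble(tfc)), 2L)
})

test_that("matrix write/load round trip preserves coordinates", {
  ens <- random_ensemble(5, 4, seed = 42)
  tf <- tempfile(fileext = ".tsv")
  write_ensemble_matrix(ens, tf)
  back <- load_ensemble(tf)
  expect_equal(back$coords, ens$coords, tolerance = 1e-6)

  tp <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, tp)
  backp <- load_ensemble(tp)
  expect_equal(backp$coords, ens$coords, tolerance = 1e-3)  # PDB: 3 decimals in Angstrom
})

test_that("concatenation preserves order, counts and source ids", {
  a <- random_ensemble(10, 3, seed = 1)
  b <- random_ensemble(10, 3, seed = 2)
  cc <- concatenate_ensembles(list(a, b), c("wt", "mut"))
  expect_equal(n_frames(cc$ensemble), 20L)
  expect_equal(as.integer(table(cc$labels$simulation_id)[c("wt", "mut")]),
               c(10L, 10L))
  expect_equal(cc$ensemble$coords[1:10, ], a$coords)
  expect_equal(cc$ensemble$coords[11:20, ], b$coords)

  one <- concatenate_ensembles(list(a), "solo")
  expect_equal(one$ensemble$coords, a$coords)
  expect_equal(unique(one$labels$simulation_id), "solo")

  c99 <- random_ensemble(4, 2, seed = 3)
  expect_error(concatenate_ensembles(list(a, c99), c("x", "y")),
               "atom-count mismatch")
  expect_error(concatenate_ensembles(list(a, b), c("x", "x")))
})

test_that("superposition removes rigid motion and never increases RMSD", {
  ens <- random_ensemble(8, 10, seed = 9)
  ref <- ens$coords[1, ]

  sup <- superpose_frames(ens, reference = 0L)
  expect_equal(sup$coords[1, ], ref, tolerance = 1e-8)

  # a rotated + translated copy of the reference superposes back exactly
  rot <- random_rotation(4)
  moved <- rigid_transform(ens, rot, shift = c(1, -2, 3))
  sup2 <- superpose_frames(
    conf_ensemble(rbind(ref, moved$coords[1, ])), reference = 0L)
  expect_lt(sqrt(mean((sup2$coords[2, ] - ref)^2) * 3), 1e-8)

  # post-superposition RMSD <= pre-superposition RMSD for every frame
  pre <- rmsd_to_ref(ens$coords, ref)
  post <- rmsd_to_ref(sup$coords, ref)
  expect_true(all(post <= pre + 1e-10))

  expect_error(superpose_frames(ens, reference = 99), "out of range")
  flat <- conf_ensemble(matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 1))
  expect_error(superpose_frames(flat), "collinear")
})

test_that("label tables round-trip with their header convention", {
  lab <- tibble::tibble(frame_index = 0:4, simulation_id = "wt",
                        mutation = c("none", "none", "R418W", "R418W", "none"),
                        vlcfa = c(0.1, 0.4, 0.2, 0.9, 0.5))
  tf <- tempfile(fileext = ".tsv")
  write_label_table(lab, tf)
  expect_match(readLines(tf, n = 1), "0-based")
  back <- read_label_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(lab))
  expect_error(write_label_table(lab[, -1], tf))
})
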