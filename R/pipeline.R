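#' Run the full conformational-tree pipeline
#'
#' Orchestrates load -> superpose -> PCA -> project -> adaptive tree ->
#' annotate -> representatives over one or more input trajectories, writing
#' every artifact plus a JSON manifest (package version, parameters, seed,
#' input checksums, per-stage counts) into `out_dir`. The manifest contains
#' no timestamps, so two runs with identical inputs and configuration
#' produce bit-identical outputs.
#'
#' @param inputs Character vector of trajectory paths (multi-model PDB or
#'   coordinate-matrix TSV/CSV, see [load_ensemble()]).
#' @param out_dir Output directory (created if needed).
#' @param ids Simulation id per input; defaults to file base names.
#' @param format,atom_select Passed to [load_ensemble()].
#' @param reference 0-based reference frame for superposition.
#' @param n_components Retained PCA dimensions (default 10).
#' @param eps_init,delta_eps,minpts,max_levels Schedule for [build_tree()].
#' @param label_file Optional label-table TSV (see [read_label_table()]);
#'   when absent, annotation uses the source simulation id.
#' @param label_name Label column to project (default `"simulation_id"`).
#' @param min_display Display floor for [node_intensity()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs were simulated).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with `ensemble`, `pca`, `projected`, `tree`,
#'   `annotation`, `representatives`, `validation` and `manifest`.
#' @export
run_pipeline <- function(inputs, out_dir, ids = NULL,
                         format = "auto", atom_select = NULL,
                         reference = 0L, n_components = 10L,
                         eps_init = 0.5, delta_eps = 0.05, minpts = 4L,
                         max_levels = 10000L,
                         label_file = NULL, label_name = "simulation_id",
                         min_display = 5L, seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[conftree] ", sprintf(...))
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("config error: input not found: ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  if (!is.null(label_file) && !file.exists(label_file)) {
    stop("config error: label file not found: ", label_file, call. = FALSE)
  }
  labels_in <- if (!is.null(label_file)) read_label_table(label_file)
  known_cols <- if (is.null(labels_in)) {
    c("frame_index", "simulation_id", "frame_time")
  } else {
    names(labels_in)
  }
  if (!label_name %in% known_cols) {
    stop("config error: label column '", label_name,
         "' absent from the label table", call. = FALSE)
  }
  if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(inputs))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ensembles <- purrr::map2(inputs, ids, function(p, id) {
    load_ensemble(p, format = format, atom_select = atom_select,
                  source_id = id)
  })
  cc <- concatenate_ensembles(ensembles, ids)
  say("loaded %d frames x %d atoms from %d input(s)",
      n_frames(cc$ensemble), n_atoms(cc$ensemble), length(inputs))

  sup <- superpose_frames(cc$ensemble, reference = reference)
  say("superposed onto frame %d", reference)

  k <- min(n_components, n_frames(sup) - 1L, 3L * n_atoms(sup))
  pca <- fit_pca(sup, k = k)
  say("PCA: %d components, explained ratio %.3f", k, explained_ratio(pca))
  projected <- project_frames(pca, sup)

  tree <- build_tree(projected,
                     epsilon_schedule(eps_init, delta_eps, minpts,
                                      max_levels))
  say("tree: %d nodes, %d leaves over %d levels%s",
      nrow(tree$nodes), length(tree_leaves(tree)), tree$n_levels,
      if (tree$complete) "" else " (incomplete)")
  validation <- validate_tree(tree)

  labels <- if (is.null(labels_in)) cc$labels else labels_in
  annotation <- annotate_tree(tree, labels, label_name,
                              min_display = min_display)
  reps <- dplyr::bind_rows(lapply(tree_leaves(tree), function(id) {
    select_representative(tree, id, projected)
  }))
  say("annotated %d nodes; %d leaf representatives", nrow(tree$nodes),
      nrow(reps))

  out <- function(f) file.path(out_dir, f)
  write_ensemble_matrix(sup, out("superposed.tsv"))
  write_pca_model(pca, out("pca_model.json"))
  utils::write.table(projected, out("projection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tree_nodes(tree, out("tree_nodes.tsv"))
  if (tree$complete) tree_newick(tree, out("tree.nwk"))
  write_tree_dot(tree, out("tree.dot"), annotation = annotation)
  write_annotation(annotation, out("annotation.tsv"))
  utils::write.table(reps, out("representatives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rep_rows <- sort(reps$frame_index) + 1L  # frame order, for time monotonicity
  rep_coords <- conf_ensemble(
    cc$ensemble$coords[rep_rows, , drop = FALSE],
    frame_time = cc$ensemble$frame_time[rep_rows],
    source_id = cc$ensemble$source_id[rep_rows])
  write_ensemble_matrix(rep_coords, out("representatives_coords.tsv"))

  manifest <- list(
    package = "conftree",
    version = as.character(utils::packageVersion("conftree")),
    parameters = list(
      inputs = inputs, ids = ids, format = format,
      atom_select = atom_select, reference = reference,
      n_components = k, eps_init = eps_init, delta_eps = delta_eps,
      minpts = minpts, max_levels = max_levels,
      label_file = label_file, label_name = label_name,
      min_display = min_display, seed = seed
    ),
    input_md5 = as.list(tools::md5sum(inputs)),
    counts = list(
      n_frames = n_frames(cc$ensemble), n_atoms = n_atoms(cc$ensemble),
      n_nodes = nrow(tree$nodes), n_leaves = length(tree_leaves(tree)),
      n_levels = tree$n_levels, tree_complete = tree$complete
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(ensemble = sup, pca = pca, projected = projected,
                 tree = tree, annotation = annotation,
                 representatives = reps, validation = validation,
                 manifest = manifest))
}

#' Simulate a landscape fixture to disk
#'
#' Samples a Gaussian-well landscape and writes the coordinate matrix and
#' its label table in the formats the pipeline consumes. The shipped demo
#' spec (see [demo_well_spec()]) has two well-separated dense regions.
#'
#' @param spec A [well_spec()] or path to a JSON spec file.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param prefix File-name prefix (default `"fixture"`).
#' @return Invisibly, a list with paths `coords` and `labels`.
#' @export
simulate_fixture <- function(spec, n, seed, out_dir, prefix = "fixture") {
  if (is.character(spec)) spec <- read_well_spec(spec)
  stopifnot(inherits(spec, "well_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- sample_gaussian_wells(spec, n, seed)
  pts <- sample_points(s)
  coords_path <- file.path(out_dir, paste0(prefix, "_coords.tsv"))
  hdr <- paste0("c", seq_len(max(ncol(pts), 1L)))
  utils::write.table(
    stats::setNames(as.data.frame(pts), hdr[seq_len(ncol(pts))]),
    coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  labels_path <- file.path(out_dir, paste0(prefix, "_labels.tsv"))
  write_label_table(
    tibble::tibble(frame_index = s$frame_index,
                   simulation_id = prefix,
                   well_label = if (nrow(s)) s$well_label else character()),
    labels_path)
  invisible(list(coords = coords_path, labels = labels_path))
}

#' Demo two-well landscape
#'
#' Two well-separated isotropic Gaussian wells on the 9 coordinates of a
#' 3-atom toy structure (the wells differ by an 8 nm displacement of one
#' atom, far beyond the 0.25 nm well width): the minimal landscape whose
#' conformation tree shows two deep dense branches merging into a single
#' root, and whose samples can run through the full pipeline including
#' superposition and PCA.
#'
#' @return A [well_spec()] in 9 dimensions (3 atoms x 3 coordinates, nm).
#' @export
demo_well_spec <- function() {
  a <- c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0)
  b <- c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 8)
  well_spec(rbind(a, b), widths = c(0.25, 0.25),
            weights = c(0.5, 0.5), labels = c("well_A", "well_B"))
}
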