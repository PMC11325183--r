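#' Construct a conformational ensemble
#'
#' A `conf_ensemble` holds the coordinates of `n_frames` conformations of the
#' same molecule: a frames-by-3N matrix in nm, ordered x,y,z per atom, plus
#' per-frame time stamps and source-simulation identifiers.
#'
#' @param coords Numeric matrix, `n_frames` rows, `3 * n_atoms` columns (nm).
#' @param frame_time Per-frame ordinal or time stamp; defaults to
#'   `0:(n_frames-1)`. Must be non-decreasing within each `source_id`.
#' @param source_id Per-frame simulation identifier (recycled if length 1).
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(coords, frame_time = NULL, source_id = "sim") {
  coords <- rbind(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) %% 3L != 0L) {
    stop("coordinate matrix must have 3N columns (x,y,z per atom)",
         call. = FALSE)
  }
  n <- nrow(coords)
  if (is.null(frame_time)) frame_time <- seq_len(n) - 1
  if (length(source_id) == 1L) source_id <- rep(source_id, n)
  stopifnot(length(frame_time) == n, length(source_id) == n)
  for (id in unique(source_id)) {
    tt <- frame_time[source_id == id]
    if (is.unsorted(tt)) {
      stop("frame_time must be non-decreasing within each source_id",
           call. = FALSE)
    }
  }
  structure(
    list(coords = coords, frame_time = as.numeric(frame_time),
         source_id = as.character(source_id)),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %d frames x %d atoms (%d sources)\n",
              n_frames(x), n_atoms(x), length(unique(x$source_id))))
  invisible(x)
}

#' Ensemble dimensions
#' @param x A `conf_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(x) nrow(x$coords)

#' @rdname n_frames
#' @export
n_atoms <- function(x) ncol(x$coords) %/% 3L

# one frame as an n_atoms x 3 matrix
frame_xyz <- function(x, i) {
  matrix(x$coords[i, ], ncol = 3L, byrow = TRUE)
}

#' @exportS3Method tibble::as_tibble
as_tibble.conf_ensemble <- function(x, ...) {
  tibble::tibble(
    frame_index = seq_len(n_frames(x)) - 1L,
    frame_time = x$frame_time,
    source_id = x$source_id,
    coord = lapply(seq_len(n_frames(x)), function(i) x$coords[i, ])
  )
}

#' Load a conformational ensemble from disk
#'
#' Two plain-text formats are supported: multi-model PDB (`MODEL`/`ENDMDL`
#' records; coordinates are converted from Angstrom to nm on load) and a
#' coordinate matrix (TSV/CSV, one frame per row, 3N columns, already in nm,
#' header optional).
#'
#' @param path File path.
#' @param format `"pdb"` (multi-model PDB) or `"matrix"`; default guesses
#'   from the file extension.
#' @param atom_select For PDB input, an optional vector of atom names (e.g.
#'   `"CA"`) to retain; carbon-alpha-only analysis is the common choice for
#'   trajectory PCA.
#' @param source_id Simulation identifier attached to every frame.
#' @return A [conf_ensemble()].
#' @export
load_ensemble <- function(path, format = c("auto", "pdb", "matrix"),
                          atom_select = NULL, source_id = "sim") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "matrix"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    if (!is.null(atom_select)) {
      keep <- which(pdb$atom$elety %in% atom_select)
      if (!length(keep)) stop("atom_select matched no atoms", call. = FALSE)
      xyz <- xyz[, bio3d::atom2xyz(keep), drop = FALSE]
    }
    conf_ensemble(xyz / 10, source_id = source_id)  # Angstrom -> nm
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty coordinate file: ", path, call. = FALSE)
    sep <- if (grepl(",", lines[[1]])) "," else "\t"
    fields <- strsplit(lines, sep, fixed = TRUE)
    first <- suppressWarnings(as.numeric(fields[[1L]]))
    if (anyNA(first)) fields <- fields[-1L]  # header row
    widths <- lengths(fields)
    if (length(unique(widths)) != 1L) {
      stop("inconsistent column counts across frames", call. = FALSE)
    }
    vals <- suppressWarnings(vapply(fields, as.numeric, numeric(widths[[1L]])))
    if (anyNA(vals)) stop("non-numeric coordinate entry", call. = FALSE)
    conf_ensemble(t(rbind(vals)), source_id = source_id)
  }
}

#' Write an ensemble as a TSV coordinate matrix
#'
#' One frame per row, 3N columns, header `x1 y1 z1 x2 ...`, full double
#' precision so that a load/write/load round trip reproduces coordinates.
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Output file path.
#' @export
write_ensemble_matrix <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  hdr <- paste0(c("x", "y", "z"), rep(seq_len(n_atoms(ensemble)), each = 3L))
  utils::write.table(
    stats::setNames(as.data.frame(ensemble$coords), hdr), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#'
#' Coordinates are converted from nm back to Angstrom; atoms are written as
#' carbon-alpha records of consecutive glycine residues (a generic backbone
#' proxy when no topology is carried).
#'
#' @inheritParams write_ensemble_matrix
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  na <- n_atoms(ensemble)
  bio3d::write.pdb(file = path, xyz = ensemble$coords * 10,
                   resno = seq_len(na), resid = rep("GLY", na),
                   elety = rep("CA", na))
  invisible(path)
}

#' Concatenate ensembles from multiple simulations
#'
#' Joins per-simulation trajectories into one ensemble, preserving frame
#' order, and returns alongside it the label table that records which source
#' simulation each frame came from — the basis for demultiplexing projected
#' data by mutation or disease label downstream.
#'
#' @param ensembles List of [conf_ensemble()] objects sharing an atom count.
#' @param ids Unique simulation identifier per ensemble; defaults to existing
#'   source ids when unambiguous.
#' @return A list with elements `ensemble` (the concatenation) and `labels`
#'   (a tibble: `frame_index`, `simulation_id`, `frame_time`).
#' @export
concatenate_ensembles <- function(ensembles, ids = NULL) {
  stopifnot(length(ensembles) >= 1L,
            all(vapply(ensembles, inherits, logical(1), "conf_ensemble")))
  if (is.null(ids)) ids <- paste0("sim_", seq_along(ensembles))
  stopifnot(length(ids) == length(ensembles), !anyDuplicated(ids))
  natoms <- vapply(ensembles, n_atoms, integer(1))
  if (length(unique(natoms)) != 1L) {
    stop("atom-count mismatch across ensembles: ",
         paste(natoms, collapse = ", "), call. = FALSE)
  }
  coords <- do.call(rbind, lapply(ensembles, `[[`, "coords"))
  frame_time <- unlist(lapply(ensembles, `[[`, "frame_time"), use.names = FALSE)
  source_id <- rep(ids, vapply(ensembles, n_frames, integer(1)))
  out <- conf_ensemble(coords, frame_time = frame_time, source_id = source_id)
  labels <- tibble::tibble(
    frame_index = seq_len(n_frames(out)) - 1L,
    simulation_id = source_id,
    frame_time = frame_time
  )
  list(ensemble = out, labels = labels)
}

#' Superpose all frames onto a reference frame
#'
#' Rigid-body (rotation + translation) least-squares superposition of every
#' frame onto the chosen reference, removing overall tumbling and drift
#' before PCA. The optimal transform is the classical Kabsch solution; the
#' reference frame itself is unchanged up to numerical noise, and no frame's
#' RMSD to the reference can increase.
#'
#' @param ensemble A [conf_ensemble()].
#' @param reference 0-based index of the reference frame (default 0, the
#'   first frame).
#' @return The superposed [conf_ensemble()].
#' @export
superpose_frames <- function(ensemble, reference = 0L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  n <- n_frames(ensemble)
  if (reference < 0 || reference >= n) {
    stop("reference frame index out of range", call. = FALSE)
  }
  if (n_atoms(ensemble) < 3L) {
    stop("superposition needs at least 3 atoms", call. = FALSE)
  }
  ref <- ensemble$coords[reference + 1L, , drop = FALSE]
  if (degenerate_frame(ref)) {
    stop("degenerate superposition: reference atoms are collinear",
         call. = FALSE)
  }
  fitted <- suppressWarnings(bio3d::fit.xyz(ref, ensemble$coords))
  out <- ensemble
  out$coords <- unclass(rbind(fitted))
  dimnames(out$coords) <- NULL
  out
}

# collinearity check: rank of centered atom coordinates < 2
degenerate_frame <- function(row) {
  m <- matrix(row, ncol = 3L, byrow = TRUE)
  m <- sweep(m, 2L, colMeans(m))
  sv <- svd(m, nu = 0L, nv = 0L)$d
  sum(sv > max(sv) * 1e-10) < 2L
}

#' Read or write a per-frame label table
#'
#' The label table TSV carries one row per frame with mandatory columns
#' `frame_index` (0-based) and `simulation_id`, plus arbitrary categorical
#' label columns (mutation, disease progression type, ...) and numeric
#' covariates (e.g. a biomarker ratio). A `# frame_index: 0-based` comment
#' header documents the index convention.
#'
#' @param path File path.
#' @return `read_label_table()` returns a tibble.
#' @export
read_label_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' @rdname read_label_table
#' @param labels Data frame with at least `frame_index` and `simulation_id`.
#' @export
write_label_table <- function(labels, path) {
  stopifnot(all(c("frame_index", "simulation_id") %in% names(labels)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame_index: 0-based", con)
  utils::write.table(labels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
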