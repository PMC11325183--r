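#' Logarithmic colour intensity of a node count
#'
#' Tree nodes are coloured by how many conformations of a given type they
#' hold, on a logarithmic scale: white (0) below the display floor, rising
#' as `log10(count) / log10(total)` to full intensity (1) when a node
#' regroups every conformation of that type.
#'
#' @param count_in_node Conformations of the type inside the node.
#' @param total_of_type Total conformations of that type in the tree
#'   (>= 2, so the logarithm is non-degenerate).
#' @param min_display Display floor: nodes holding fewer conformations than
#'   this render white (intensity 0). Default 5.
#' @return Intensity in `[0, 1]` (vectorised over `count_in_node`).
#' @examples
#' node_intensity(10, 1000)    # 1/3
#' node_intensity(4, 1000)     # 0: below the display floor
#' node_intensity(1000, 1000)  # 1: full intensity
#' @export
node_intensity <- function(count_in_node, total_of_type, min_display = 5L) {
  if (any(total_of_type < 2)) {
    stop("total_of_type must be >= 2 for a logarithmic scale", call. = FALSE)
  }
  if (any(count_in_node < 0) || any(count_in_node > total_of_type)) {
    stop("count_in_node must lie in [0, total_of_type]", call. = FALSE)
  }
  i <- ifelse(count_in_node >= pmax(min_display, 1),
              log10(count_in_node) / log10(total_of_type), 0)
  pmin(pmax(i, 0), 1)
}

#' Default label palette
#'
#' Cyan / magenta / yellow (then a recycled extension) so that overlapping
#' branches holding conformations of several types mix into distinct
#' secondary colours.
#'
#' @param values Character vector of label values to colour.
#' @return Named character vector of hex colours.
#' @export
label_palette <- function(values) {
  base <- c("#00ffff", "#ff00ff", "#ffff00",
            "#ff8000", "#0080ff", "#00c000")
  stats::setNames(rep_len(base, length(values)), values)
}

#' Project a categorical per-frame label onto tree nodes
#'
#' For every node and every value of the chosen label, counts the member
#' frames carrying that value and converts counts into logarithmic colour
#' intensities (see [node_intensity()]); intensities are normalised per
#' label value (count in node over all conformations of that value). Nodes
#' holding several values mix their colours additively on white, so
#' overlapping branches show secondary hues.
#'
#' @param tree A `conf_tree` from [build_tree()].
#' @param labels A label table (tibble) with a `frame_index` column covering
#'   every tree member frame.
#' @param label_name Name of the categorical column to project.
#' @param palette Named hex-colour vector per label value; defaults to
#'   [label_palette()].
#' @param min_display Display floor passed to [node_intensity()].
#' @return A `node_annotation` tibble: `node_id`, `label`, `value`, `count`,
#'   `total`, `intensity`, `color`.
#' @export
annotate_tree <- function(tree, labels, label_name, palette = NULL,
                          min_display = 5L) {
  stopifnot(inherits(tree, "conf_tree"),
            "frame_index" %in% names(labels),
            label_name %in% names(labels))
  all_members <- unique(unlist(tree$nodes$members))
  missing <- setdiff(all_members, labels$frame_index)
  if (length(missing)) {
    stop("missing-label: frames absent from the label table: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  value_of <- stats::setNames(as.character(labels[[label_name]]),
                              labels$frame_index)
  values <- sort(unique(as.character(labels[[label_name]])))
  totals <- table(factor(as.character(labels[[label_name]]), levels = values))
  if (is.null(palette)) palette <- label_palette(values)
  out <- tidyr::crossing(node_id = tree$nodes$node_id, value = values)
  counts <- purrr::map2_int(out$node_id, out$value, function(id, v) {
    sum(value_of[as.character(node_members(tree, id))] == v)
  })
  out <- dplyr::mutate(
    out,
    label = label_name,
    count = counts,
    total = as.integer(totals[.data$value]),
    intensity = node_intensity(counts, .data$total, min_display),
    color = unname(palette[.data$value])
  )
  dplyr::select(out, "node_id", "label", "value", "count", "total",
                "intensity", "color")
}

#' Project a numeric covariate onto tree nodes via discretisation
#'
#' A numeric per-frame covariate (a biomarker level, say) is cut into bins —
#' by default the empirical terciles of the frames' values — and the binned
#' variable is projected like a categorical label. This is how trees are
#' coloured by, e.g., tercile of a fatty-acid concentration ratio to look
#' for branch/biomarker correspondence.
#'
#' @inheritParams annotate_tree
#' @param covariate Name of the numeric column to discretise.
#' @param breaks `"terciles"` (default) or a numeric vector of interior cut
#'   points.
#' @return A `node_annotation` tibble (see [annotate_tree()]); bin labels
#'   are `"T1" < "T2" < ...` in ascending covariate order. The cut points
#'   used are attached as attribute `breaks`.
#' @export
annotate_numeric <- function(tree, labels, covariate, breaks = "terciles",
                             palette = NULL, min_display = 5L) {
  stopifnot(covariate %in% names(labels))
  xv <- labels[[covariate]]
  if (!is.numeric(xv) || anyNA(xv)) {
    stop("covariate must be numeric and complete", call. = FALSE)
  }
  if (identical(breaks, "terciles")) {
    cuts <- unname(stats::quantile(xv, c(1 / 3, 2 / 3)))
    if (anyDuplicated(cuts) || length(unique(xv)) < 2L) {
      stop("degenerate-breaks: covariate has no spread at the tercile cuts",
           call. = FALSE)
    }
  } else {
    cuts <- sort(as.numeric(breaks))
    if (anyDuplicated(cuts)) {
      stop("degenerate-breaks: duplicate cut points", call. = FALSE)
    }
  }
  bin <- cut(xv, c(-Inf, cuts, Inf),
             labels = paste0("T", seq_len(length(cuts) + 1L)))
  labels2 <- dplyr::mutate(labels, .bin = as.character(bin))
  out <- annotate_tree(tree, labels2, ".bin", palette = palette,
                       min_display = min_display)
  out$label <- covariate
  attr(out, "breaks") <- cuts
  out
}

#' Additive colour mix per node
#'
#' Collapses a per-value annotation to one display colour per node: each
#' value contributes its hue scaled by intensity from white, and
#' contributions combine subtractively (cyan + magenta at full intensity
#' gives blue), matching how overlapping branches are rendered.
#'
#' @param annotation A `node_annotation` tibble from [annotate_tree()].
#' @return Tibble with `node_id` and mixed hex `color`.
#' @export
node_color_mix <- function(annotation) {
  stopifnot(all(c("node_id", "intensity", "color") %in% names(annotation)))
  mix_one <- function(int, col) {
    rgbm <- t(grDevices::col2rgb(col)) / 255
    absorb <- colSums(int * (1 - rgbm))
    out <- pmin(pmax(1 - absorb, 0), 1)
    grDevices::rgb(out[1L], out[2L], out[3L])
  }
  dplyr::summarise(
    dplyr::group_by(annotation, .data$node_id),
    color = mix_one(.data$intensity, .data$color),
    .groups = "drop"
  )
}

#' Select the representative conformation of a node
#'
#' The representative of a cluster node is its latest member in simulation
#' time; ties are broken toward the lowest frame index, so selection is
#' reproducible.
#'
#' @param tree A `conf_tree`.
#' @param node_id Node to summarise.
#' @param frame_time Per-frame times: either a numeric vector aligned with
#'   0-based frame indices, or a tibble with `frame_index` and `frame_time`
#'   columns (e.g. a `projected_ensemble` or label table).
#' @return One-row tibble: `node_id`, `frame_index`, `frame_time`, `rule`.
#' @export
select_representative <- function(tree, node_id, frame_time) {
  members <- node_members(tree, node_id)  # errors on unknown node
  if (!length(members)) stop("node has no members", call. = FALSE)
  if (is.data.frame(frame_time)) {
    tt <- frame_time$frame_time[match(members, frame_time$frame_index)]
  } else {
    tt <- frame_time[members + 1L]
  }
  if (anyNA(tt)) stop("frame_time missing for some node members",
                      call. = FALSE)
  latest <- members[tt == max(tt)]
  pick <- min(latest)
  tibble::tibble(node_id = node_id, frame_index = pick,
                 frame_time = max(tt), rule = "latest_time_lowest_index")
}

#' RMSD between two conformations
#'
#' Root mean square deviation between matched atoms of two structures,
#' optionally after optimal rigid-body (Kabsch) superposition. With
#' superposition on, rigid motions are removed and the value reflects
#' internal deformation only; both modes are provided because published
#' comparisons do not always state which was used.
#'
#' @param coords_a,coords_b Numeric `n_atoms x 3` matrices (nm), equal atom
#'   counts.
#' @param superpose Superpose before measuring (default `TRUE`).
#' @return RMSD in nm.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' rmsd_coords(a, a + 5)            # translation removed
#' rmsd_coords(a, a + 5, superpose = FALSE)
#' @export
rmsd_coords <- function(coords_a, coords_b, superpose = TRUE) {
  coords_a <- rbind(coords_a)
  coords_b <- rbind(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)) || ncol(coords_a) != 3L) {
    stop("coordinate sets must be equal-sized n_atoms x 3 matrices",
         call. = FALSE)
  }
  a <- as.vector(t(coords_a))
  b <- as.vector(t(coords_b))
  if (superpose && nrow(coords_a) >= 3L) {
    bio3d::rmsd(a, b, fit = TRUE)
  } else if (superpose) {
    # too few atoms for a unique rotation: remove translation only
    ac <- sweep(coords_a, 2L, colMeans(coords_a))
    bc <- sweep(coords_b, 2L, colMeans(coords_b))
    sqrt(mean(rowSums((ac - bc)^2)))
  } else {
    sqrt(mean(rowSums((coords_a - coords_b)^2)))
  }
}

#' RMSD between the representatives of two tree nodes
#'
#' Convenience wrapper: picks each node's representative (latest member in
#' simulation time) and measures the RMSD between the corresponding frames
#' of the ensemble.
#'
#' @param tree A `conf_tree`.
#' @param node_a,node_b Node ids.
#' @param ensemble The [conf_ensemble()] whose frames were clustered.
#' @param superpose Passed to [rmsd_coords()].
#' @return One-row tibble: `node_a`, `node_b`, `frame_a`, `frame_b`, `rmsd`.
#' @export
representative_rmsd <- function(tree, node_a, node_b, ensemble,
                                superpose = TRUE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  tt <- tibble::tibble(frame_index = seq_len(n_frames(ensemble)) - 1L,
                       frame_time = ensemble$frame_time)
  ra <- select_representative(tree, node_a, tt)
  rb <- select_representative(tree, node_b, tt)
  tibble::tibble(
    node_a = node_a, node_b = node_b,
    frame_a = ra$frame_index, frame_b = rb$frame_index,
    rmsd = rmsd_coords(frame_xyz(ensemble, ra$frame_index + 1L),
                       frame_xyz(ensemble, rb$frame_index + 1L),
                       superpose = superpose)
  )
}

#' Write annotations as a per-node TSV
#'
#' @param annotation A `node_annotation` tibble.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
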