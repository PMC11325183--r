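#' Volume of a d-dimensional hypersphere
#'
#' `V_d(R) = pi^(d/2) R^d / Gamma(d/2 + 1)`. This is the volume entering the
#' density threshold of DBSCAN in the clustered PC subspace.
#'
#' @param radius Sphere radius (> 0), in PC-space units.
#' @param dim Dimension (>= 1).
#' @return Volume (radius units to the power `dim`).
#' @examples
#' hypersphere_volume(1, 2)  # pi
#' hypersphere_volume(1, 3)  # 4 * pi / 3
#' @export
hypersphere_volume <- function(radius, dim) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("radius must be positive", call. = FALSE)
  }
  if (any(dim < 1) || any(dim != round(dim))) {
    stop("dim must be a positive integer", call. = FALSE)
  }
  pi^(dim / 2) * radius^dim / gamma(dim / 2 + 1)
}

#' Minimum density threshold of a DBSCAN sweep level
#'
#' The density a cluster must exceed at radius `radius`: `minpts` points per
#' hypersphere volume, `minpts / V_dim(radius)`. For `minpts = 4` in a
#' 10-dimensional subspace this equals `480 / (pi^5 R^10)`, since
#' `V_10(R) = pi^5 R^10 / 120`.
#'
#' @param minpts Minimum number of points (self included) within the radius.
#' @param radius Neighbourhood radius (> 0).
#' @param dim Dimension of the clustered space.
#' @return Density threshold (points per unit volume).
#' @export
min_density <- function(minpts, radius, dim) {
  if (any(minpts < 1)) stop("minpts must be >= 1", call. = FALSE)
  minpts / hypersphere_volume(radius, dim)
}

# Deterministic DBSCAN labelling from a squared-distance matrix.
# Returns an integer vector: 0 = noise, clusters 1..m numbered by ascending
# lowest member row index. Core points need >= minpts points (self included)
# within eps; clusters are connected components of the core-core
# eps-neighbourhood graph; a border point joins the cluster of its
# lowest-index core neighbour.
dbscan_assign <- function(d2, eps, minpts) {
  n <- nrow(d2)
  assignment <- integer(n)
  if (n == 0L) return(assignment)
  nb <- d2 <= eps * eps
  core <- rowSums(nb) >= minpts
  if (!any(core)) return(assignment)
  ci <- which(core)
  sub <- nb[ci, ci, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  first <- vapply(split(ci, memb), min, numeric(1))
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  assignment[ci] <- relabel[memb]
  border <- which(!core & rowSums(nb[, ci, drop = FALSE]) > 0L)
  if (length(border)) {
    reach <- nb[border, ci, drop = FALSE]
    firstcore <- ci[max.col(reach, ties.method = "first")]
    assignment[border] <- assignment[firstcore]
  }
  assignment
}

#' DBSCAN at a fixed radius
#'
#' Standard density-based clustering under the L2 norm: a point is *core*
#' when at least `minpts` points (itself included) lie within `eps`;
#' clusters are maximal density-connected sets of core points plus the
#' border points they reach; everything else is noise. The labelling is
#' deterministic: clusters are numbered by ascending lowest member frame
#' index, and a border point reachable from several clusters joins the
#' cluster of its lowest-index core neighbour.
#'
#' @param points A `projected_ensemble` tibble from [project_frames()], or a
#'   bare numeric matrix of coordinates (rows = frames).
#' @param eps Neighbourhood radius (> 0).
#' @param minpts Minimum neighbourhood size, self included (>= 1).
#' @return A tibble with one row per point: `frame_index`, `cluster`
#'   (integer, `NA` for noise) and `core` (logical), carrying attributes
#'   `eps`, `minpts` and `n_clusters`.
#' @examples
#' pts <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
#' dbscan_level(pts, eps = 0.15, minpts = 2)
#' @export
dbscan_level <- function(points, eps, minpts) {
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop("eps must be a single positive number", call. = FALSE)
  }
  if (length(minpts) != 1L || is.na(minpts) || minpts < 1) {
    stop("minpts must be >= 1", call. = FALSE)
  }
  x <- projection_matrix(points)
  fi <- point_frame_index(points, nrow(x))
  d2 <- as.matrix(stats::dist(x))^2
  asg <- dbscan_assign(d2, eps, minpts)
  nb_count <- if (nrow(x)) rowSums(d2 <= eps * eps) else integer()
  out <- tibble::tibble(
    frame_index = fi,
    cluster = ifelse(asg == 0L, NA_integer_, asg),
    core = nb_count >= minpts
  )
  attr(out, "eps") <- eps
  attr(out, "minpts") <- as.integer(minpts)
  attr(out, "n_clusters") <- if (length(asg)) max(asg) else 0L
  out
}

# frame_index column if present, else 0-based row order
point_frame_index <- function(points, n) {
  if (!is.matrix(points) && "frame_index" %in% names(points)) {
    as.integer(points$frame_index)
  } else {
    seq_len(n) - 1L
  }
}
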