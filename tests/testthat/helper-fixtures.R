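# wells on a line in `d` dimensions with prescribed inter-center gaps
line_well_spec <- function(gaps, width = 0.25, d = 2L) {
  centers <- matrix(0, length(gaps) + 1L, d)
  centers[, 1L] <- cumsum(c(0, gaps))
  well_spec(centers, widths = rep(width, nrow(centers)))
}

# the six 1-D points used across DBSCAN/tree toy cases: two triplets with
# 0.125 spacing (exactly representable in binary) separated by a 4.75 gap
six_points <- function() matrix(c(0, 0.125, 0.25, 5, 5.125, 5.25), ncol = 1)

# small random ensemble (n_atoms x 3 coordinates per frame)
random_ensemble <- function(n_frames, n_atoms, seed = 1, sd = 1) {
  set.seed(seed)
  conf_ensemble(matrix(rnorm(n_frames * 3 * n_atoms, sd = sd),
                       n_frames, 3 * n_atoms))
}

# proper rotation matrix in 3-D
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion (rotation + translation) to every frame
rigid_transform <- function(ensemble, rot, shift = c(0, 0, 0)) {
  coords <- t(apply(ensemble$coords, 1L, function(row) {
    m <- matrix(row, ncol = 3L, byrow = TRUE) %*% t(rot)
    as.vector(t(sweep(m, 2L, -shift)))
  }))
  conf_ensemble(coords, frame_time = ensemble$frame_time,
                source_id = ensemble$source_id)
}

rmsd_to_ref <- function(coords, ref_row) {
  apply(coords, 1L, function(r) sqrt(mean((r - ref_row)^2) * 3))
}
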