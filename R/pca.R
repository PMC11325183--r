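#' Fit a principal-component subspace to a superposed ensemble
#'
#' Eigendecomposition of the positional covariance over frames ("essential
#' dynamics"): the top components capture the dominant collective motions of
#' the molecule, and the ensemble is subsequently projected into the spanned
#' k-dimensional subspace for density clustering. The covariance is
#' normalised by `1/n_frames` (frames are treated as the full sample), so on
#' the fitting ensemble the per-component projected variance equals the
#' eigenvalue exactly under that convention. Component signs are fixed by
#' making each component's largest-magnitude entry positive, which makes the
#' decomposition deterministic across linear-algebra backends. No mass
#' weighting is applied.
#'
#' @param ensemble A superposed [conf_ensemble()].
#' @param k Number of components to retain, `1 <= k <= min(n_frames - 1, 3N)`.
#'   Defaults to 10, the usual choice for conformational tree building.
#' @return A `conf_pca` object with fields `mean` (3N, nm), `components`
#'   (k x 3N, row-orthonormal), `eigenvalues` (nm^2, descending),
#'   `total_variance` (sum of all 3N eigenvalues, nm^2) and `spectrum` (the
#'   full eigenvalue vector, for explained-ratio queries at any k).
#' @examples
#' ens <- conf_ensemble(matrix(rnorm(60), 10, 6))
#' fit <- fit_pca(superpose_frames(ens), k = 2)
#' glance(fit)
#' @export
fit_pca <- function(ensemble, k = 10L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  n <- n_frames(ensemble)
  p <- ncol(ensemble$coords)
  if (n < 2L) stop("need at least 2 frames to fit a PCA", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (length(k) != 1L || is.na(k) || k < 1L || k > kmax) {
    stop(sprintf("k must be in [1, %d]", kmax), call. = FALSE)
  }
  k <- as.integer(k)
  mu <- colMeans(ensemble$coords)
  xc <- sweep(ensemble$coords, 2L, mu)
  sv <- svd(xc, nu = 0L)
  eig <- sv$d^2 / n                      # 1/n covariance convention
  spectrum <- c(eig, rep(0, p - length(eig)))
  comp <- t(sv$v[, seq_len(k), drop = FALSE])
  # sign convention: largest-magnitude entry of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(
    list(mean = mu, components = comp, eigenvalues = spectrum[seq_len(k)],
         total_variance = sum(spectrum), spectrum = spectrum, k = k,
         n_frames = n),
    class = "conf_pca"
  )
}

#' @export
print.conf_pca <- function(x, ...) {
  cat(sprintf(
    "<conf_pca> %d components over %d coordinates; explained ratio %.3f\n",
    x$k, length(x$mean), explained_ratio(x, x$k)))
  invisible(x)
}

#' @rdname fit_pca
#' @param x A `conf_pca`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.conf_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    eigenvalue = x$eigenvalues,
    explained = x$eigenvalues / x$total_variance,
    cumulative = cumsum(x$eigenvalues) / x$total_variance
  )
}

#' @rdname fit_pca
#' @exportS3Method generics::glance
glance.conf_pca <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_frames = x$n_frames,
    total_variance = x$total_variance,
    explained_ratio = explained_ratio(x, x$k)
  )
}

#' Fraction of total positional variance captured by the top components
#'
#' @param model A `conf_pca` from [fit_pca()].
#' @param k Number of leading components to sum (defaults to all retained).
#' @return `sum(eigenvalues[1:k]) / total_variance`, in `[0, 1]`.
#' @export
explained_ratio <- function(model, k = model$k) {
  stopifnot(inherits(model, "conf_pca"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(model$spectrum)) {
    stop("k exceeds the recorded spectrum", call. = FALSE)
  }
  if (model$total_variance == 0) return(1)
  sum(model$spectrum[seq_len(k)]) / model$total_variance
}

#' Project an ensemble into a fitted PC subspace
#'
#' Computes `(coords - mean) %*% t(components)`. The projected ensemble need
#' not be the fitting ensemble: a wild-type-only trajectory can be projected
#' into a subspace fitted on the full mutant concatenation, which is how
#' per-simulation data are compared in a common coordinate system.
#'
#' @param model A `conf_pca` from [fit_pca()].
#' @param ensemble A [conf_ensemble()] with matching atom count.
#' @return A `projected_ensemble` tibble: `frame_index` (0-based),
#'   `frame_time`, `source_id`, then `pc1 ... pck` (nm).
#' @export
project_frames <- function(model, ensemble) {
  stopifnot(inherits(model, "conf_pca"), inherits(ensemble, "conf_ensemble"))
  if (ncol(ensemble$coords) != length(model$mean)) {
    stop("ensemble dimensionality does not match the PCA model",
         call. = FALSE)
  }
  pts <- sweep(ensemble$coords, 2L, model$mean) %*% t(model$components)
  colnames(pts) <- paste0("pc", seq_len(model$k))
  dplyr::bind_cols(
    tibble::tibble(
      frame_index = seq_len(n_frames(ensemble)) - 1L,
      frame_time = ensemble$frame_time,
      source_id = ensemble$source_id
    ),
    tibble::as_tibble(pts)
  )
}

#' Reconstruct coordinates from a projection
#'
#' Inverse map of [project_frames()]: `mean + points %*% components`. With a
#' full-rank model this reproduces the centered coordinates exactly.
#'
#' @param model A `conf_pca`.
#' @param projected A `projected_ensemble` tibble (or bare matrix of PC
#'   coordinates).
#' @return A coordinate matrix, frames x 3N (nm).
#' @export
reconstruct_frames <- function(model, projected) {
  stopifnot(inherits(model, "conf_pca"))
  pts <- projection_matrix(projected, model$k)
  sweep(pts %*% model$components, 2L, model$mean, `+`)
}

# pull the pc columns of a projected_ensemble as a dense matrix
projection_matrix <- function(projected, k = NULL) {
  if (is.matrix(projected)) return(projected)
  pc_cols <- grep("^pc[0-9]+$", names(projected), value = TRUE)
  pc_cols <- pc_cols[order(as.integer(sub("pc", "", pc_cols)))]
  if (!is.null(k)) {
    stopifnot(length(pc_cols) >= k)
    pc_cols <- pc_cols[seq_len(k)]
  }
  as.matrix(projected[pc_cols])
}

#' Serialise a PCA model to a JSON bundle
#'
#' @param model A `conf_pca`.
#' @param path Output path.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "conf_pca"))
  jsonlite::write_json(
    list(mean = model$mean, components = model$components,
         eigenvalues = model$eigenvalues, total_variance = model$total_variance,
         spectrum = model$spectrum, k = model$k, n_frames = model$n_frames),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mean = j$mean, components = rbind(j$components),
         eigenvalues = j$eigenvalues, total_variance = j$total_variance,
         spectrum = j$spectrum, k = as.integer(j$k),
         n_frames = as.integer(j$n_frames)),
    class = "conf_pca"
  )
}
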