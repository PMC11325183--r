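#' Specify a multi-well energy landscape
#'
#' A `well_spec` describes an explicit mixture of isotropic Gaussian wells on
#' a k-dimensional conformational coordinate. Molecular simulations dwell in
#' local minima of the force-field landscape, so prevalent conformations
#' cluster around mixture modes; sampling from a `well_spec` therefore
#' produces point clouds with a known well hierarchy, which is what the
#' tree-building tests need as ground truth.
#'
#' @param centers Numeric matrix, one row per well, one column per dimension
#'   (arbitrary length units, conventionally nm to match ensembles).
#' @param widths Numeric vector of per-well standard deviations (> 0).
#' @param weights Numeric vector of relative well populations; must be
#'   strictly positive and is normalised to sum to 1.
#' @param labels Character vector of per-well tags; defaults to
#'   `"well_1" ... "well_k"`.
#' @return An object of class `well_spec`.
#' @examples
#' spec <- well_spec(rbind(c(0, 0), c(6, 0)), widths = c(0.5, 0.5),
#'                   weights = c(0.5, 0.5))
#' spec
#' @export
well_spec <- function(centers, widths, weights = NULL, labels = NULL) {
  centers <- rbind(centers)
  storage.mode(centers) <- "double"
  k <- nrow(centers)
  if (k < 1L) stop("well_spec needs at least one well", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (is.null(labels)) labels <- paste0("well_", seq_len(k))
  stopifnot(length(widths) == k, length(weights) == k, length(labels) == k)
  if (any(!is.finite(widths)) || any(widths <= 0)) {
    stop("well widths must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("well weights must be strictly positive", call. = FALSE)
  }
  weights <- weights / sum(weights)
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  structure(
    list(centers = centers, widths = as.numeric(widths),
         weights = as.numeric(weights), labels = as.character(labels)),
    class = "well_spec"
  )
}

#' @export
print.well_spec <- function(x, ...) {
  cat(sprintf("<well_spec> %d wells in %d dimensions\n",
              nrow(x$centers), ncol(x$centers)))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname well_spec
#' @param x A `well_spec`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.well_spec <- function(x, ...) {
  tibble::tibble(
    well = seq_len(nrow(x$centers)),
    label = x$labels,
    width = x$widths,
    weight = x$weights,
    center = lapply(seq_len(nrow(x$centers)), function(i) x$centers[i, ])
  )
}

#' Read or write a well specification as JSON
#'
#' @param path File path.
#' @return `read_well_spec()` returns a `well_spec`; `write_well_spec()`
#'   returns `path` invisibly.
#' @export
read_well_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  well_spec(centers = rbind(j$centers), widths = j$widths,
            weights = j$weights, labels = j$labels)
}

#' @rdname read_well_spec
#' @param spec A `well_spec`.
#' @export
write_well_spec <- function(spec, path) {
  stopifnot(inherits(spec, "well_spec"))
  jsonlite::write_json(
    list(centers = spec$centers, widths = spec$widths,
         weights = spec$weights, labels = spec$labels),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor"
  )
  invisible(path)
}

new_sample_set <- function(points, well_assignment, spec, seed) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  tibble::new_tibble(
    tibble::tibble(
      frame_index = if (nrow(points)) seq_len(nrow(points)) - 1L else integer(),
      well = as.integer(well_assignment),
      well_label = spec$labels[well_assignment],
      coord = lapply(seq_len(nrow(points)), function(i) points[i, ])
    ),
    class = "sample_set", seed = seed, spec = spec, points = points
  )
}

#' Extract the raw coordinate matrix of a sample set
#'
#' @param x A `sample_set` as returned by [sample_gaussian_wells()] or
#'   [sample_boltzmann()].
#' @return Numeric n-by-k matrix of sampled coordinates.
#' @export
sample_points <- function(x) {
  stopifnot(inherits(x, "sample_set"))
  attr(x, "points")
}

#' Sample conformational point clouds from Gaussian wells
#'
#' Draws `n` points from the isotropic Gaussian mixture described by `spec`:
#' each point picks a well with probability proportional to the well weights,
#' then scatters around the well center with the well's standard deviation.
#'
#' @param spec A [well_spec()].
#' @param n Number of points (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical samples.
#' @return A `sample_set` tibble with columns `frame_index` (0-based), `well`,
#'   `well_label` and a `coord` list-column; the dense coordinate matrix is
#'   available via [sample_points()].
#' @examples
#' spec <- well_spec(rbind(c(0, 0), c(8, 0)), widths = c(0.5, 0.5))
#' s <- sample_gaussian_wells(spec, n = 100, seed = 1)
#' dplyr::count(s, well_label)
#' @export
sample_gaussian_wells <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "well_spec"))
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("n must be a single non-negative count", call. = FALSE)
  }
  n <- as.integer(n)
  d <- ncol(spec$centers)
  if (n == 0L) {
    return(new_sample_set(matrix(numeric(), 0L, d), integer(), spec, seed))
  }
  with_local_seed(seed, {
    wells <- sample.int(nrow(spec$centers), n, replace = TRUE,
                        prob = spec$weights)
    noise <- matrix(stats::rnorm(n * d), n, d)
    pts <- spec$centers[wells, , drop = FALSE] + noise * spec$widths[wells]
    new_sample_set(pts, wells, spec, seed)
  })
}

# mixture density and its -log (the energy surface) for Metropolis sampling
mixture_density <- function(spec, x) {
  d <- ncol(spec$centers)
  comp <- vapply(seq_len(nrow(spec$centers)), function(i) {
    s <- spec$widths[i]
    q <- sum((x - spec$centers[i, ])^2) / (2 * s^2)
    spec$weights[i] * exp(-q) / (2 * pi * s^2)^(d / 2)
  }, numeric(1))
  sum(comp)
}

#' Metropolis sampling of a well landscape
#'
#' Runs a Metropolis random walk on the energy surface `U(x) = -log f(x)`,
#' where `f` is the Gaussian-mixture density of `spec`. This emulates a
#' simulation exploring potential wells: at low temperature the walk dwells
#' inside wells and rarely crosses barriers. Proposals are isotropic Gaussian
#' steps of size `step_size` (default half the smallest well width, which
#' keeps acceptance moderate across specs).
#'
#' @inheritParams sample_gaussian_wells
#' @param temperature Dimensionless temperature (> 0) scaling the acceptance
#'   rule `exp(-dU / temperature)`.
#' @param steps Chain length (>= 1).
#' @param burn_in Fraction of initial steps discarded (default 0.1).
#' @param step_size Proposal standard deviation; default
#'   `0.5 * min(spec$widths)`.
#' @return A `sample_set` of the retained chain states; `well` holds the
#'   nearest-center assignment (distances scaled by well width).
#' @export
sample_boltzmann <- function(spec, temperature = 1, steps = 1000L, seed = 1L,
                             burn_in = 0.1, step_size = NULL) {
  stopifnot(inherits(spec, "well_spec"))
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number", call. = FALSE)
  }
  if (length(steps) != 1L || is.na(steps) || steps < 1) {
    stop("steps must be >= 1", call. = FALSE)
  }
  stopifnot(burn_in >= 0, burn_in < 1)
  steps <- as.integer(steps)
  d <- ncol(spec$centers)
  if (is.null(step_size)) step_size <- 0.5 * min(spec$widths)
  x <- spec$centers[which.max(spec$weights), ]
  chain <- matrix(NA_real_, steps, d)
  with_local_seed(seed, {
    u <- -log(mixture_density(spec, x))
    for (t in seq_len(steps)) {
      prop <- x + stats::rnorm(d, sd = step_size)
      up <- -log(mixture_density(spec, prop))
      if (stats::runif(1) < exp(-(up - u) / temperature)) {
        x <- prop
        u <- up
      }
      chain[t, ] <- x
    }
  })
  keep <- seq.int(floor(burn_in * steps) + 1L, steps)
  pts <- chain[keep, , drop = FALSE]
  # nearest center in width-scaled distance
  asg <- apply(pts, 1L, function(p) {
    which.min(sqrt(colSums((t(spec$centers) - p)^2)) / spec$widths)
  })
  new_sample_set(pts, as.integer(asg), spec, seed)
}

#' Expected branch merge order of a well landscape
#'
#' Ground-truth oracle for tree-topology tests: well pairs separated by lower
#' effective barriers merge into common density-connected clusters at smaller
#' radii. The proxy score for a pair is the inter-center distance minus the
#' sum of the two widths (closer and wider pairs merge first); merge events
#' are single-linkage agglomerations under that score.
#'
#' @param spec A [well_spec()] with at least two wells.
#' @return A tibble with one row per merge event, ordered by ascending merge
#'   score: columns `step`, `score`, and list-columns `group_a` / `group_b` of
#'   well labels joined at that event. A single-well spec gives zero rows.
#' @export
expected_merge_order <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  k <- nrow(spec$centers)
  empty <- tibble::tibble(step = integer(), score = numeric(),
                          group_a = list(), group_b = list())
  if (k < 2L) return(empty)
  d <- as.matrix(stats::dist(spec$centers))
  score <- d - outer(spec$widths, spec$widths, `+`)
  hc <- stats::hclust(stats::as.dist(score), method = "single")
  groups <- lapply(seq_len(k), function(i) spec$labels[i])
  out <- vector("list", k - 1L)
  for (s in seq_len(k - 1L)) {
    pick <- function(idx) {
      if (idx < 0) groups[[-idx]] else out[[idx]]$merged[[1L]]
    }
    a <- pick(hc$merge[s, 1L])
    b <- pick(hc$merge[s, 2L])
    out[[s]] <- tibble::tibble(step = s, score = hc$height[s],
                               group_a = list(a), group_b = list(b),
                               merged = list(sort(c(a, b))))
  }
  dplyr::select(dplyr::bind_rows(out), -"merged")
}
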