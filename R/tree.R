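#' Radius schedule for the adaptive DBSCAN sweep
#'
#' The tree builder runs DBSCAN at `eps_L = eps_init + L * delta_eps` for
#' `L = 0, 1, 2, ...`. Small radii isolate the densest conformational cores
#' (deep energy wells); as the radius grows the implied density threshold
#' `minpts / V(eps)` falls and clusters merge, until a single cluster — the
#' tree root — contains every frame.
#'
#' @param eps_init Initial radius (> 0), PC-space units.
#' @param delta_eps Per-level radius increment (> 0).
#' @param minpts Minimum neighbourhood size, self included (>= 1); default 4.
#' @param max_levels Safety cap on sweep iterations; default 10000.
#' @return An `epsilon_schedule` object.
#' @seealso [schedule_presets()] for documented parameter sets.
#' @export
epsilon_schedule <- function(eps_init, delta_eps, minpts = 4L,
                             max_levels = 10000L) {
  stopifnot(length(eps_init) == 1L, is.finite(eps_init), eps_init > 0,
            length(delta_eps) == 1L, is.finite(delta_eps), delta_eps > 0,
            minpts >= 1L, max_levels >= 1L)
  structure(
    list(eps_init = as.numeric(eps_init), delta_eps = as.numeric(delta_eps),
         minpts = as.integer(minpts), max_levels = as.integer(max_levels)),
    class = "epsilon_schedule"
  )
}

#' @export
print.epsilon_schedule <- function(x, ...) {
  cat(sprintf(
    "<epsilon_schedule> eps_init=%g, delta_eps=%g, minpts=%d, max_levels=%d\n",
    x$eps_init, x$delta_eps, x$minpts, x$max_levels))
  invisible(x)
}

#' Documented schedule presets
#'
#' Parameter sets used for full-transporter conformation trees in a
#' 10-dimensional PC subspace, one row per analysis. These are starting
#' points, not universal defaults: the radius scale depends on the spread of
#' the projected data, and in practice `eps_init` is refined by manual
#' bisection until the tree shows a useful number of branches (reducing
#' `delta_eps` when trees come out too coarse).
#'
#' @return A tibble with columns `preset`, `eps_init`, `delta_eps`, `minpts`.
#' @export
schedule_presets <- function() {
  tibble::tribble(
    ~preset,                        ~eps_init, ~delta_eps, ~minpts,
    "peroxisome_open_all_ca",       0.83,      0.01,       4L,
    "peroxisome_open_atp_pocket",   0.135,     0.001,      4L,
    "cytosol_open_all_ca",          3.7,       0.05,       4L,
    "cytosol_open_vlcfa_pocket",    0.3,       0.001,      4L
  )
}

#' Build a conformation tree by adaptive density clustering
#'
#' The core algorithm: DBSCAN is run repeatedly on the projected frames at
#' radii `eps_init, eps_init + delta_eps, ...`. Each density-connected
#' cluster found at a level becomes (or extends) a tree node; as the radius
#' grows, clusters disconnected at one level become embedded in the more
#' diffuse clusters of the next, so every node links to the parent cluster
#' that absorbs it. The sweep ends when one cluster holds every frame (the
#' root) or when `max_levels` is reached, in which case the result is
#' flagged incomplete rather than silently truncated.
#'
#' Bookkeeping rules, all deterministic: clusters are numbered by lowest
#' member frame index; a node's parent is the next-level cluster containing
#' the majority of its members (ties toward the candidate with the lower
#' minimum member frame index — moot when nesting is exact); consecutive
#' levels with identical member sets are collapsed into one node recording
#' its `[eps_first, eps_last]` interval; frames that were noise at earlier
#' levels enter the tree at the first level that clusters them.
#'
#' @param points A `projected_ensemble` tibble from [project_frames()] (or a
#'   bare coordinate matrix).
#' @param schedule An [epsilon_schedule()].
#' @return A `conf_tree`: list with `nodes` (tibble: `node_id`, `parent_id`,
#'   `eps_first`, `eps_last`, `level_first`, `level_last`, `n_members`,
#'   `members` list-column of 0-based frame indices), `root_id` (`NA` when
#'   incomplete), `complete`, `n_levels`, `n_points`, `dim`, `schedule`.
#' @examples
#' pts <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
#' tree <- build_tree(pts, epsilon_schedule(0.05, 0.05, minpts = 2))
#' tidy(tree)
#' @export
build_tree <- function(points, schedule) {
  stopifnot(inherits(schedule, "epsilon_schedule"))
  x <- projection_matrix(points)
  n <- nrow(x)
  if (n < schedule$minpts) {
    stop("fewer frames than minpts: no cluster can form", call. = FALSE)
  }
  fi <- point_frame_index(points, n)
  d2 <- as.matrix(stats::dist(x))^2

  nodes <- list()   # each: members, eps_first, eps_last, level_*, parent, children
  open <- integer() # node ids still extendable at the current frontier
  complete <- FALSE
  level <- 0L
  while (level < schedule$max_levels) {
    eps <- schedule$eps_init + level * schedule$delta_eps
    asg <- dbscan_assign(d2, eps, schedule$minpts)
    m <- max(asg)
    if (m > 0L) {
      clusters <- lapply(seq_len(m), function(cl) which(asg == cl))
      # map each open node to the cluster holding the majority of its members
      mapped <- rep(NA_integer_, length(open))
      for (oi in seq_along(open)) {
        labs <- asg[nodes[[open[oi]]]$members]
        labs <- labs[labs > 0L]
        if (!length(labs)) next
        tab <- tabulate(labs, nbins = m)
        cand <- which(tab == max(tab))
        if (length(cand) > 1L) {
          cand <- cand[which.min(vapply(clusters[cand], min, numeric(1)))]
        }
        mapped[oi] <- cand
      }
      next_open <- integer(m)
      for (cl in seq_len(m)) {
        members <- clusters[[cl]]
        kids <- open[which(mapped == cl)]
        if (length(kids) == 1L &&
            identical(nodes[[kids]]$members, members)) {
          # same member set as its single predecessor: extend, don't split
          nodes[[kids]]$eps_last <- eps
          nodes[[kids]]$level_last <- level
          next_open[cl] <- kids
        } else {
          id <- length(nodes) + 1L
          nodes[[id]] <- list(members = members, eps_first = eps,
                              eps_last = eps, level_first = level,
                              level_last = level, parent = NA_integer_,
                              children = kids)
          for (k in kids) nodes[[k]]$parent <- id
          next_open[cl] <- id
        }
      }
      # nodes whose members were all noise at this level stay on the frontier
      open <- c(next_open, open[is.na(mapped)])
      if (m == 1L && length(clusters[[1L]]) == n) {
        complete <- TRUE
        level <- level + 1L
        break
      }
    }
    level <- level + 1L
  }

  node_tbl <- tibble::tibble(
    node_id = seq_along(nodes),
    parent_id = vapply(nodes, `[[`, integer(1), "parent"),
    eps_first = vapply(nodes, `[[`, numeric(1), "eps_first"),
    eps_last = vapply(nodes, `[[`, numeric(1), "eps_last"),
    level_first = vapply(nodes, `[[`, integer(1), "level_first"),
    level_last = vapply(nodes, `[[`, integer(1), "level_last"),
    n_members = vapply(nodes, function(nd) length(nd$members), integer(1)),
    members = lapply(nodes, function(nd) fi[nd$members])
  )
  root_id <- if (complete) {
    node_tbl$node_id[is.na(node_tbl$parent_id)]
  } else {
    NA_integer_
  }
  structure(
    list(nodes = node_tbl, root_id = root_id, complete = complete,
         n_levels = level, n_points = n, dim = ncol(x),
         schedule = schedule),
    class = "conf_tree"
  )
}

#' @export
print.conf_tree <- function(x, ...) {
  cat(sprintf(
    "<conf_tree> %d nodes over %d levels (%d frames, %d-D)%s\n",
    nrow(x$nodes), x$n_levels, x$n_points, x$dim,
    if (x$complete) "" else " [INCOMPLETE: no all-frame root reached]"))
  invisible(x)
}

#' @rdname build_tree
#' @param x A `conf_tree`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.conf_tree <- function(x, ...) {
  dplyr::select(x$nodes, -"members")
}

#' @rdname build_tree
#' @exportS3Method generics::glance
glance.conf_tree <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_leaves = length(tree_leaves(x)),
    n_levels = x$n_levels,
    n_points = x$n_points,
    dim = x$dim,
    complete = x$complete,
    eps_root = if (x$complete) x$nodes$eps_first[x$nodes$node_id == x$root_id]
               else NA_real_
  )
}

#' Leaf nodes of a conformation tree
#'
#' Leaves are nodes with no children: the maximal-depth branches, i.e. the
#' densest distinct conformational cores (one per well when wells are
#' well separated).
#'
#' @param tree A `conf_tree`.
#' @return Integer vector of leaf node ids.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "conf_tree"))
  setdiff(tree$nodes$node_id, tree$nodes$parent_id[!is.na(tree$nodes$parent_id)])
}

#' Frame members of a tree node
#'
#' @param tree A `conf_tree`.
#' @param node_id Node identifier.
#' @return Integer vector of 0-based frame indices.
#' @export
node_members <- function(tree, node_id) {
  stopifnot(inherits(tree, "conf_tree"))
  i <- match(node_id, tree$nodes$node_id)
  if (is.na(i)) stop("unknown node id: ", node_id, call. = FALSE)
  tree$nodes$members[[i]]
}

#' Validate the structural invariants of a conformation tree
#'
#' Asserts that the tree has a single root (when complete), that every
#' non-root node's member set is a subset of its parent's, and that the
#' children of any node have pairwise-disjoint member sets. A violation
#' raises an error naming the offending node (or, with `strict = FALSE`, is
#' recorded in the report); the report includes the containment fraction
#' (share of child members found in the chosen parent, 1.0 when nesting is
#' exact).
#'
#' @param tree A `conf_tree`.
#' @param strict Raise an error on the first violated invariant (default);
#'   `FALSE` returns the report with `valid = FALSE` instead.
#' @return A one-row tibble: `n_nodes`, `n_roots`, `single_root`,
#'   `containment_fraction`, `sibling_overlap`, `valid`.
#' @export
validate_tree <- function(tree, strict = TRUE) {
  stopifnot(inherits(tree, "conf_tree"))
  nd <- tree$nodes
  fail <- function(...) {
    if (strict) stop("validation-error: ", ..., call. = FALSE)
    FALSE
  }
  valid <- TRUE
  roots <- nd$node_id[is.na(nd$parent_id)]
  if (tree$complete && length(roots) != 1L) {
    valid <- fail("expected a single root, found nodes [",
                  paste(roots, collapse = ", "), "]")
  }
  contain <- 1
  nonroot <- which(!is.na(nd$parent_id))
  if (length(nonroot)) {
    fr <- vapply(nonroot, function(i) {
      p <- match(nd$parent_id[i], nd$node_id)
      mean(nd$members[[i]] %in% nd$members[[p]])
    }, numeric(1))
    contain <- min(fr)
    if (contain < 1) {
      bad <- nonroot[which.min(fr)]
      valid <- fail("node ", nd$node_id[bad],
                    " is not a subset of its parent (containment ",
                    sprintf("%.3f", min(fr)), ")")
    }
  }
  overlap <- 0L
  for (p in nd$node_id) {
    kids <- which(!is.na(nd$parent_id) & nd$parent_id == p)
    if (length(kids) < 2L) next
    dup <- sum(duplicated(unlist(nd$members[kids])))
    if (dup > 0L) {
      overlap <- overlap + dup
      valid <- fail("children of node ", p, " share ", dup,
                    " member frame(s)")
    }
  }
  tibble::tibble(
    n_nodes = nrow(nd),
    n_roots = length(roots),
    single_root = length(roots) == 1L,
    containment_fraction = contain,
    sibling_overlap = overlap,
    valid = valid
  )
}

#' Export a conformation tree as a Newick string
#'
#' Internal and leaf labels are node ids (`n<id>`); each branch length is
#' the epsilon span of the child, i.e. the difference between the parent's
#' birth radius and the child's birth radius. Incomplete trees (forests)
#' cannot be serialised to a single Newick string.
#'
#' @param tree A `conf_tree`.
#' @param path Optional output file; when given the string is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "conf_tree"))
  if (!tree$complete) {
    stop("cannot serialise an incomplete tree (forest) to Newick",
         call. = FALSE)
  }
  nd <- tree$nodes
  kids_of <- split(nd$node_id[!is.na(nd$parent_id)],
                   nd$parent_id[!is.na(nd$parent_id)])
  rec <- function(id, parent_eps) {
    i <- match(id, nd$node_id)
    len <- if (is.na(parent_eps)) 0 else parent_eps - nd$eps_first[i]
    kids <- kids_of[[as.character(id)]]
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, rec, character(1),
                               parent_eps = nd$eps_first[i]),
                        collapse = ","), ")")
    } else ""
    sprintf("%sn%d:%.10g", inner, id, len)
  }
  nwk <- paste0(rec(tree$root_id, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Write the node table of a tree as TSV
#'
#' Columns: `node_id`, `parent_id`, `eps_first`, `eps_last`, `n_members`,
#' `members` (comma-separated 0-based frame indices).
#'
#' @param tree A `conf_tree`.
#' @param path Output path.
#' @export
write_tree_nodes <- function(tree, path) {
  stopifnot(inherits(tree, "conf_tree"))
  tbl <- dplyr::mutate(
    tidy(tree),
    members = vapply(tree$nodes$members, paste, character(1), collapse = ",")
  )
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a conformation tree as a DOT graph
#'
#' One graph node per tree node (label: id, member count, epsilon interval);
#' optional fill colours from an annotation table carrying `node_id` and
#' `color` columns.
#'
#' @param tree A `conf_tree`.
#' @param path Output path.
#' @param annotation Optional annotation tibble (see [annotate_tree()]),
#'   summarised to one colour per node by additive mixing.
#' @export
write_tree_dot <- function(tree, path, annotation = NULL) {
  stopifnot(inherits(tree, "conf_tree"))
  nd <- tree$nodes
  fill <- rep("#ffffff", nrow(nd))
  if (!is.null(annotation)) {
    mixed <- node_color_mix(annotation)
    i <- match(nd$node_id, mixed$node_id)
    fill[!is.na(i)] <- mixed$color[i[!is.na(i)]]
  }
  lines <- c("digraph conformation_tree {",
             "  node [shape=box, style=filled];")
  lines <- c(lines, sprintf(
    "  n%d [label=\"n%d\\n%d frames\\neps %.4g-%.4g\", fillcolor=\"%s\"];",
    nd$node_id, nd$node_id, nd$n_members, nd$eps_first, nd$eps_last, fill))
  e <- !is.na(nd$parent_id)
  lines <- c(lines,
             sprintf("  n%d -> n%d;", nd$parent_id[e], nd$node_id[e]),
             "}")
  writeLines(lines, path)
  invisible(path)
}
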