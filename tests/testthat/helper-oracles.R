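# Independent brute-force DBSCAN: pairwise distances, explicit neighbourhood
# graph, breadth-first connected components over core points, then border
# attachment to the lowest-index core neighbour. Pure R, no igraph — a
# separate route from the package implementation.
oracle_dbscan <- function(x, eps, minpts) {
  x <- rbind(x)
  n <- nrow(x)
  if (n == 0L) return(integer())
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= minpts
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      reach <- which(nb[j, ] & core & lab == 0L)
      lab[reach] <- cl
      queue <- c(queue, reach)
    }
  }
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    if (length(cn)) lab[i] <- lab[min(cn)]
  }
  lab
}

# canonical relabelling by first occurrence, noise (0/NA) kept as 0
canonical_partition <- function(lab) {
  lab[is.na(lab)] <- 0L
  out <- integer(length(lab))
  nxt <- 0L
  seen <- integer()
  for (i in seq_along(lab)) {
    if (lab[i] == 0L) next
    k <- match(lab[i], seen)
    if (is.na(k)) {
      seen <- c(seen, lab[i])
      nxt <- nxt + 1L
      k <- nxt
    }
    out[i] <- k
  }
  out
}

expect_same_partition <- function(a, b) {
  expect_identical(canonical_partition(a), canonical_partition(b))
}

# epsilon at which the branches of two wells join: birth radius of the
# smallest node holding a majority of both wells' frames
well_merge_eps <- function(tree, frames_by_well) {
  k <- length(frames_by_well)
  out <- matrix(NA_real_, k, k)
  nd <- tree$nodes
  ord <- order(nd$eps_first)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      for (r in ord) {
        m <- nd$members[[r]]
        if (mean(frames_by_well[[i]] %in% m) > 0.5 &&
            mean(frames_by_well[[j]] %in% m) > 0.5) {
          out[i, j] <- out[j, i] <- nd$eps_first[r]
          break
        }
      }
    }
  }
  out
}
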