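# Independent oracles used across the suite. These re-derive expected
# values from first principles (recursive definitions, exhaustive
# enumeration) and never call the implementation paths they check.

# path contribution computed by the literal front-peeling recursion
oracleF <- function(w, path) {
  vols <- unname(rowSums(w))
  if (length(path) == 1L) return(vols[path])
  if (vols[path[1]] == 0) return(0)
  unname((w[path[1], path[2]] / vols[path[1]])) * oracleF(w, path[-1])
}

# WL signature by exhaustive path enumeration: a plain list-based FIFO
# queue, extensions over every node, ranked by a freshly recomputed f.
# Assumes strict rankings (continuous weights), so no tie-breaking.
oracleSignature <- function(w, u, k, ell) {
  n <- nrow(w)
  H <- numeric(0)
  queue <- list(u)
  while (length(queue) > 0L) {
    pth <- queue[[1L]]
    queue <- queue[-1L]
    H <- c(H, oracleF(w, pth))
    if (length(pth) - 1L < ell) {
      fs <- vapply(seq_len(n), function(z) oracleF(w, c(pth, z)), numeric(1))
      ord <- order(fs, decreasing = TRUE)
      for (z in ord[seq_len(min(k, n))]) {
        queue <- c(queue, list(c(pth, z)))
      }
    }
  }
  H
}

# exhaustive assignment minimum over all permutations (independent of
# the package's enumeration code: builds permutations via recursion on
# utils::combn-free base R)
oracleAssignmentCost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) {
      best <<- acc
      return()
    }
    for (j in seq_len(ncol(cost))) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(row + 1L, used, acc + cost[row, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(ncol(cost)), 0)
  best
}

# random nonnegative symmetric zero-diagonal matrix
randomSymMatrix <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w + t(w)
}

# unique-edge weights of a connectome (strict upper triangle)
.upperWeightsOf <- function(g) {
  w <- adjacency(g)
  w[upper.tri(w)]
}

# rescale every edge weight of a connectome by a positive constant
.scaleConnectome <- function(g, c) {
  Connectome(adjacency(g) * c, labels = nodeLabels(g))
}

# a uniformly random bijective alignment between two label sets
randomAlignment <- function(src, tgt) {
  Alignment(stats::setNames(sample(tgt), src), targetLabels = tgt)
}
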