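#' WL-align parameters
#'
#' The signature expansion is controlled by a width \eqn{k} (children
#' kept per expansion) and a depth \eqn{\ell} (hops). The defaults,
#' \eqn{k = \lfloor \log_2 n \rfloor} (clamped to \eqn{[1, n - 1]}) and
#' \eqn{\ell = 2}, balance signature expressiveness against cost: the
#' signature has \eqn{d = \sum_{i=0}^{\ell} k^i} entries, and deeper
#' hops contribute geometrically less because every hop multiplies the
#' path contribution by a weight/volume ratio \eqn{\le 1}.
#'
#' @param n number of nodes of the network being aligned (one
#'   hemisphere, when aligning per hemisphere).
#' @param width \eqn{k \ge 1}; \code{NULL} selects the default.
#' @param depth \eqn{\ell \ge 0}.
#' @param seed integer seed for the uniform-at-random tie-breaking in
#'   the expansion ranking. Irrelevant when all contribution values are
#'   distinct (almost surely the case for continuous weights).
#' @return a list with elements \code{width}, \code{depth}, \code{seed}.
#' @export
wlParams <- function(n, width = NULL, depth = 2, seed = 1L) {
  if (is.null(width)) {
    width <- max(1L, min(floor(log2(n)), n - 1L))
  }
  width <- as.integer(width)
  depth <- as.integer(depth)
  if (width < 1L) stop("'width' must be >= 1")
  if (depth < 0L) stop("'depth' must be >= 0")
  list(width = width, depth = depth, seed = as.integer(seed))
}

#' Volume of a node
#'
#' The sum of the weights of the edges incident to a node (its weighted
#' degree), \eqn{\mathrm{vol}(v) = \sum_{u} w_{uv}}.
#'
#' @param g a \linkS4class{Connectome}.
#' @param v a node label, or \code{NULL} for all nodes.
#' @return non-negative numeric; named vector over all nodes when
#'   \code{v} is \code{NULL}.
#' @export
nodeVolume <- function(g, v = NULL) {
  vols <- rowSums(adjacency(g))
  names(vols) <- nodeLabels(g)
  if (is.null(v)) return(vols)
  if (!all(v %in% nodeLabels(g))) stop("unknown node label")
  vols[v]
}

#' Contribution of a path to a node signature
#'
#' The recursive score
#' \deqn{f(v_0, \ldots, v_h) = \mathrm{vol}(v_0) \text{ if } h = 0,
#'   \quad \frac{w(v_0, v_1)}{\mathrm{vol}(v_0)} f(v_1, \ldots, v_h)
#'   \text{ otherwise},}
#' i.e. the terminal node's volume damped by the product of
#' weight/volume ratios along the path. A step through a non-edge
#' (weight 0) makes the whole contribution 0, as does a zero-volume
#' intermediate node (such a node has no positive incident edge).
#'
#' @param g a \linkS4class{Connectome}.
#' @param path character vector of node labels \eqn{(v_0, \ldots, v_h)}.
#' @return non-negative numeric.
#' @export
pathContribution <- function(g, path) {
  lab <- nodeLabels(g)
  if (!all(path %in% lab)) stop("path contains unknown node labels")
  w <- adjacency(g)
  vols <- rowSums(w)
  idx <- match(path, lab)
  h <- length(idx) - 1L
  f <- vols[idx[length(idx)]]
  if (h == 0L) return(unname(f))
  for (s in seq_len(h)) {
    v0 <- idx[s]
    if (vols[v0] == 0) return(0)
    f <- f * w[v0, idx[s + 1L]] / vols[v0]
  }
  unname(f)
}

# signature of one node, given adjacency A and volumes vols.
# Expansion follows the FIFO-queue schedule: pop a path, emit f(path),
# and if it is shorter than `depth` hops extend it by every node of the
# graph, keep the `width` extensions of largest contribution (ties
# uniformly at random via `tie`), and enqueue them in descending order.
# A path's contribution is tracked incrementally as
# f(path) = prefix * vol(last), prefix being the product of w/vol ratios.
.signatureOne <- function(A, vols, u, width, depth) {
  n <- nrow(A)
  d <- sum(width^(0:depth))
  H <- numeric(d)
  qLast <- integer(d)   # 0 encodes a padded (null) path
  qPre <- numeric(d)
  qHop <- integer(d)
  qLast[1] <- u
  qPre[1] <- 1
  tail <- 1L
  for (head in seq_len(d)) {
    last <- qLast[head]
    pre <- qPre[head]
    hop <- qHop[head]
    H[head] <- if (last > 0L) pre * vols[last] else 0
    if (hop < depth) {
      if (last > 0L && vols[last] > 0 && pre > 0) {
        ratio <- pre * A[, last] / vols[last]
        f <- ratio * vols
        ord <- order(f, stats::runif(n), decreasing = TRUE)
        take <- ord[seq_len(min(width, n))]
        nk <- length(take)
        sel <- tail + seq_len(nk)
        qLast[sel] <- take
        qPre[sel] <- ratio[take]
        qHop[sel] <- hop + 1L
        tail <- tail + nk
      } else {
        nk <- 0L
      }
      # pad with null children when fewer than `width` candidates exist
      if (nk < width) {
        pad <- tail + seq_len(width - nk)
        qHop[pad] <- hop + 1L
        tail <- tail + (width - nk)
      }
    }
  }
  H
}

#' WL signature of a node
#'
#' Builds the fixed-length signature vector \eqn{H_u} describing the
#' local weighted connectivity of node \eqn{u}: a FIFO breadth-first
#' expansion of paths starting at \eqn{u}, in which each popped path
#' appends its contribution (\code{\link{pathContribution}}) to the
#' signature and, while shorter than \code{depth} hops, is extended by
#' every node of the graph, keeping the \code{width} extensions with the
#' largest contribution (ties broken uniformly at random). The signature
#' has exactly \eqn{d = \sum_{i=0}^{\ell} k^i} entries and its first
#' entry is \eqn{\mathrm{vol}(u)}.
#'
#' @param g a \linkS4class{Connectome} (connected, or repaired with
#'   \code{\link{repairIsolatedNodes}}).
#' @param u a node label.
#' @param params parameters from \code{\link{wlParams}}; defaults to
#'   \code{wlParams(nNodes(g))}.
#' @return numeric vector of length \eqn{\sum_{i=0}^{\ell} k^i}.
#' @export
wlSignature <- function(g, u, params = wlParams(nNodes(g))) {
  lab <- nodeLabels(g)
  if (!u %in% lab) stop("node not found: ", u)
  A <- adjacency(g)
  vols <- rowSums(A)
  withr::with_seed(params$seed, {
    .signatureOne(A, vols, match(u, lab), params$width, params$depth)
  })
}

#' Signature table of a connectome
#'
#' One WL signature per node, as a matrix with one row per node (row
#' names are node labels) and \eqn{\sum_{i=0}^{\ell} k^i} columns.
#' Deterministic given \code{params$seed}.
#'
#' @inheritParams wlSignature
#' @return numeric matrix, rows named by node labels.
#' @export
signatureTable <- function(g, params = wlParams(nNodes(g))) {
  A <- adjacency(g)
  vols <- rowSums(A)
  n <- nrow(A)
  d <- sum(params$width^(0:params$depth))
  S <- matrix(0, n, d, dimnames = list(nodeLabels(g), NULL))
  # each node gets the same fresh tie-breaking stream, so a single-node
  # wlSignature() call reproduces the corresponding table row exactly
  for (i in seq_len(n)) {
    S[i, ] <- withr::with_seed(params$seed, {
      .signatureOne(A, vols, i, params$width, params$depth)
    })
  }
  S
}

#' Signature-distance cost matrix
#'
#' The weights of the complete bipartite graph between the two node
#' sets: entry \eqn{(u, v)} is the Euclidean distance
#' \eqn{\|H_u - H_v\|_2} between the signatures of \eqn{u} in the first
#' graph and \eqn{v} in the second.
#'
#' @param sigs1,sigs2 signature tables from \code{\link{signatureTable}}
#'   with equal signature length.
#' @return non-negative numeric matrix; rows named by the first graph's
#'   labels, columns by the second's.
#' @export
bipartiteCost <- function(sigs1, sigs2) {
  if (ncol(sigs1) != ncol(sigs2)) {
    stop("signature lengths differ between the two graphs")
  }
  n1 <- nrow(sigs1)
  d <- matrix(0, n1, nrow(sigs2),
              dimnames = list(rownames(sigs1), rownames(sigs2)))
  t2 <- t(sigs2)
  for (i in seq_len(n1)) {
    d[i, ] <- sqrt(colSums((t2 - sigs1[i, ])^2))
  }
  d
}

#' Solve the minimum-cost assignment problem
#'
#' Finds the injective map from rows to columns minimising the total
#' cost \eqn{\sum_u b(u, m(u))} — the minimum-weight matching of the
#' complete bipartite graph whose edge weights are the cost entries
#' (square case: a bijection). Solved exactly via maximum-weight
#' bipartite matching on the complemented costs.
#'
#' @param cost numeric matrix with row/column dimnames naming the two
#'   node sets; all entries finite; \code{nrow <= ncol}.
#' @return an \linkS4class{Alignment} from row labels to column labels,
#'   with the achieved total cost in attribute \code{"totalCost"}.
#' @export
solveAssignment <- function(cost) {
  if (!is.matrix(cost) || length(cost) == 0L) {
    stop("'cost' must be a non-empty matrix")
  }
  if (any(!is.finite(cost))) stop("costs must be finite")
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  if (n1 > n2) stop("assignment needs nrow(cost) <= ncol(cost)")
  rows <- rownames(cost)
  cols <- colnames(cost)
  if (is.null(rows)) rows <- paste0("r", seq_len(n1))
  if (is.null(cols)) cols <- paste0("c", seq_len(n2))
  big <- max(cost) + 1
  ig <- igraph::make_full_bipartite_graph(n1, n2)
  el <- igraph::as_edgelist(ig, names = FALSE)
  wts <- big - cost[cbind(el[, 1], el[, 2] - n1)]
  mt <- igraph::max_bipartite_match(
    ig, types = c(rep(FALSE, n1), rep(TRUE, n2)), weights = wts)
  assign <- mt$matching[seq_len(n1)] - n1
  a <- Alignment(stats::setNames(cols[assign], rows), targetLabels = cols)
  attr(a, "totalCost") <- sum(cost[cbind(seq_len(n1), assign)])
  a
}

#' Align two connectomes with WL-align
#'
#' The three-step procedure: (1) compute a WL signature for every node
#' of both graphs, (2) build the complete bipartite graph whose edge
#' weights are Euclidean distances between signatures, (3) solve the
#' minimum-cost assignment problem on it. Both graphs must have the
#' same number of nodes and should be connected (apply
#' \code{\link{repairIsolatedNodes}} first if not).
#'
#' @param g1,g2 \linkS4class{Connectome}s of equal size.
#' @param params parameters from \code{\link{wlParams}}; the default
#'   uses \eqn{k = \lfloor \log_2 n \rfloor} and \eqn{\ell = 2}.
#' @return an \linkS4class{Alignment} from \code{g1}'s labels to
#'   \code{g2}'s labels, with attribute \code{"totalCost"}.
#' @examples
#' g <- randomConnectome(12, density = 0.5, seed = 7)
#' pg <- permuteConnectome(g, seed = 8)
#' m <- wlAlign(g, pg$connectome)
#' nodeMatchingRatio(m, pg$truth)  # 1: the permutation is recovered
#' @export
wlAlign <- function(g1, g2, params = NULL) {
  if (nNodes(g1) != nNodes(g2)) {
    stop("WL-align requires two graphs with the same number of nodes")
  }
  if (is.null(params)) params <- wlParams(nNodes(g1))
  s1 <- signatureTable(g1, params)
  s2 <- signatureTable(g2, params)
  solveAssignment(bipartiteCost(s1, s2))
}

#' Hemisphere-wise WL-align
#'
#' Runs WL-align separately on the left- and right-hemisphere induced
#' subgraphs (the width default \eqn{k = \lfloor \log_2 n \rfloor} uses
#' each hemisphere's own node count) and merges the two partial
#' alignments. No output pair ever crosses hemispheres.
#'
#' @param g1,g2 \linkS4class{Connectome}s with hemisphere tags on all
#'   nodes and matching per-hemisphere node counts.
#' @param width,depth,seed passed to \code{\link{wlParams}} per
#'   hemisphere (\code{width = NULL} selects the per-hemisphere default).
#' @return an \linkS4class{Alignment} over the full label sets.
#' @export
wlAlignHemispheres <- function(g1, g2, width = NULL, depth = 2, seed = 1L) {
  h1 <- splitHemispheres(g1)
  h2 <- splitHemispheres(g2)
  maps <- lapply(c("L", "R"), function(side) {
    a <- h1[[side]]
    b <- h2[[side]]
    if (nNodes(a) != nNodes(b)) {
      stop("hemisphere ", side, " has different sizes in the two graphs")
    }
    alignmentMap(wlAlign(a, b, wlParams(nNodes(a), width, depth, seed)))
  })
  m <- c(maps[[1]], maps[[2]])
  Alignment(m[nodeLabels(g1)], targetLabels = nodeLabels(g2))
}
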