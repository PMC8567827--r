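#' Jaccard similarity index between two finite sets
#'
#' The ratio between the size of the intersection and the size of the
#' union, \eqn{|A \cap B| / |A \cup B|}, in \eqn{[0, 1]}. At least one
#' set must be non-empty.
#'
#' @param a,b vectors interpreted as finite sets (duplicates ignored).
#' @return numeric in \eqn{[0, 1]}.
#' @examples
#' setJaccard(1:18, 16:33)  # 3 shared out of 33 -> 3/33
#' @export
setJaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("Jaccard index is undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Weighted (Ruzicka) Jaccard similarity between non-negative vectors
#'
#' \eqn{\sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)}. Reduces to the
#' set Jaccard index when both vectors are binary indicators over the
#' union of two sets.
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return numeric in \eqn{[0, 1]}.
#' @export
weightedJaccard <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have the same dimension")
  if (min(x, y) < 0) stop("entries must be non-negative")
  den <- sum(pmax(x, y))
  if (den == 0) stop("weighted Jaccard is undefined for two zero vectors")
  sum(pmin(x, y)) / den
}

#' Weighted graph Jaccard similarity index (GJI)
#'
#' For two connectomes on the same node set with adjacencies \eqn{A} and
#' \eqn{B}, the GJI is
#' \deqn{J(G_1, G_2) = \frac{\sum_{(i,j)} \min(A_{ij}, B_{ij})}
#'                          {\sum_{(i,j)} \max(A_{ij}, B_{ij})},}
#' the sums running over all unordered node pairs. It equals the
#' weighted Jaccard similarity of the vectorised adjacency matrices,
#' is 1 iff the adjacencies coincide, 0 iff the graphs share no edge,
#' and \eqn{1 - J} is a metric (see \code{\link{jaccardDistance}}).
#' Nodes are matched by label, so the two graphs may list their nodes
#' in different orders; use \code{\link{applyAlignment}} first when the
#' graphs live on different label sets.
#'
#' @param g1,g2 \linkS4class{Connectome}s with identical label sets,
#'   not both edgeless.
#' @return numeric in \eqn{[0, 1]}.
#' @export
graphJaccard <- function(g1, g2) {
  A <- adjacency(g1)
  B <- .matchedAdjacency(g1, g2)
  ut <- upper.tri(A, diag = TRUE)
  weightedJaccard(A[ut], B[ut])
}

#' Graph Jaccard distance
#'
#' \eqn{d_J = 1 - J(G_1, G_2)}: satisfies identity, symmetry and the
#' triangle inequality, making the space of connectomes a metric space.
#'
#' @inheritParams graphJaccard
#' @return numeric in \eqn{[0, 1]}.
#' @export
jaccardDistance <- function(g1, g2) 1 - graphJaccard(g1, g2)

#' Norm-based distance between connectomes
#'
#' The matrix norm of the adjacency difference,
#' \eqn{d_t(G_1, G_2) = \|\mathrm{Adj}(G_1) - \mathrm{Adj}(G_2)\|_t},
#' with \eqn{t} either the Frobenius norm or an entrywise \eqn{\ell^p}
#' norm (\eqn{p \ge 1}) on the vectorised difference. For two
#' weight-normalised connectomes the Frobenius distance lies in
#' \eqn{[0, 2]}.
#'
#' @inheritParams graphJaccard
#' @param type \code{"frobenius"} (default) or \code{"lp"}.
#' @param p norm order for \code{type = "lp"}; \code{p >= 1}.
#' @return non-negative numeric.
#' @export
normDistance <- function(g1, g2, type = c("frobenius", "lp"), p = 2) {
  type <- match.arg(type)
  D <- adjacency(g1) - .matchedAdjacency(g1, g2)
  if (type == "frobenius") {
    sqrt(sum(D^2))
  } else {
    if (p < 1) stop("'p' must be >= 1")
    sum(abs(D)^p)^(1 / p)
  }
}

#' Cosine similarity between connectomes
#'
#' The scalar product of the vectorised adjacency matrices divided by
#' the product of their Euclidean norms — the cosine of the angle
#' between the two vectorised graphs. Uncentred (no mean subtraction),
#' so it is not a Pearson correlation; for non-negative graphs the
#' value lies in \eqn{[0, 1]} and is invariant to rescaling either
#' graph.
#'
#' @inheritParams graphJaccard
#' @return numeric in \eqn{[0, 1]} for non-negative graphs.
#' @export
cosineSimilarity <- function(g1, g2) {
  a <- as.vector(adjacency(g1))
  b <- as.vector(.matchedAdjacency(g1, g2))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for an empty graph")
  sum(a * b) / (na * nb)
}
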