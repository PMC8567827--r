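#' Replace negative entries of a raw connectivity matrix by zero
#'
#' Connectivity estimates that can go negative (e.g. regressed or
#' covariance-based matrices) are thresholded at zero before being
#' treated as weighted graphs; non-negative entries are untouched.
#'
#' @param gRaw square symmetric numeric matrix of any sign, or a
#'   \linkS4class{Connectome}.
#' @param labels optional node labels when \code{gRaw} is a bare matrix.
#' @return a \linkS4class{Connectome} with all entries \eqn{\ge 0}.
#' @export
thresholdNegative <- function(gRaw, labels = NULL) {
  if (is(gRaw, "Connectome")) return(gRaw)
  w <- gRaw
  w[w < 0] <- 0
  Connectome(w, labels = labels)
}

#' Normalise edge weights to unit total
#'
#' Divides every edge weight by the sum of all the weights in the graph,
#' taken over the unique undirected edges (the upper triangle), so that
#' the total unique-edge weight becomes exactly 1. Relative weight
#' ratios are preserved and the operation is idempotent.
#'
#' @param g a \linkS4class{Connectome} with at least one positive weight.
#' @return the normalised \linkS4class{Connectome}.
#' @export
normalizeWeights <- function(g) {
  tot <- sum(.upperWeights(g))
  if (tot <= 0) stop("cannot normalise an all-zero graph")
  .withWeights(g, adjacency(g) / tot)
}

#' Reconnect isolated nodes
#'
#' Nodes with zero volume (no incident streamlines) are artificially
#' connected to every other node in the graph with a small edge weight —
#' by default 1, the equivalent of a single streamline — so that the
#' graph is connected enough for signature-based alignment. Must be
#' applied to raw (pre-normalisation) weights, before
#' \code{\link{normalizeWeights}}. When several nodes are isolated, each
#' is connected to all other nodes, including the other formerly
#' isolated ones.
#'
#' @param g a \linkS4class{Connectome}.
#' @param repairWeight positive weight given to each repair edge
#'   (default 1, on the raw streamline-count scale).
#' @return a \linkS4class{Connectome} in which every node has positive
#'   volume.
#' @export
repairIsolatedNodes <- function(g, repairWeight = 1) {
  if (nNodes(g) < 2) stop("cannot repair a graph with fewer than 2 nodes")
  if (repairWeight <= 0) stop("'repairWeight' must be positive")
  w <- adjacency(g)
  vols <- rowSums(w)
  iso <- which(vols == 0)
  if (length(iso) == 0L) return(g)
  for (i in iso) {
    w[i, ] <- pmax(w[i, ], repairWeight)
    w[, i] <- pmax(w[, i], repairWeight)
  }
  diag(w) <- 0
  .withWeights(g, w)
}

#' Split a connectome into its two hemispheres
#'
#' Returns the two induced subgraphs: left-hemisphere nodes with their
#' within-hemisphere edges, and likewise for the right. Interhemispheric
#' edges are dropped from both, so node volumes in the outputs count
#' within-hemisphere connectivity only.
#'
#' @param g a \linkS4class{Connectome} whose every node carries a
#'   hemisphere tag.
#' @return named list with elements \code{L} and \code{R}, both
#'   \linkS4class{Connectome}s.
#' @export
splitHemispheres <- function(g) {
  h <- hemisphereTags(g)
  if (length(h) != nNodes(g) || anyNA(h)) {
    stop("every node needs a hemisphere tag to split")
  }
  out <- lapply(c(L = "L", R = "R"), function(side) {
    keep <- which(h == side)
    if (length(keep) == 0L) stop("hemisphere ", side, " is empty")
    Connectome(adjacency(g)[keep, keep, drop = FALSE],
               labels = nodeLabels(g)[keep],
               hemisphere = h[keep])
  })
  out
}

#' Standard preprocessing pipeline for raw streamline-count connectomes
#'
#' Applies, in order: isolated-node repair (raw scale) and weight
#' normalisation. Thresholding of negative entries, when needed, happens
#' at construction time via \code{\link{thresholdNegative}}.
#'
#' @param g a \linkS4class{Connectome} with raw weights.
#' @param repairWeight weight of the repair edges (default 1).
#' @return a normalised, repair-completed \linkS4class{Connectome}.
#' @export
preprocessConnectome <- function(g, repairWeight = 1) {
  normalizeWeights(repairIsolatedNodes(g, repairWeight))
}
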