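#' Construct a Connectome
#'
#' Builds a \linkS4class{Connectome} from a square weight matrix. The
#' matrix is symmetrised by averaging when row/column discrepancies are
#' within the absolute tolerance \code{1e-12}; larger asymmetries and
#' negative entries are errors.
#'
#' @param weights square numeric matrix of non-negative edge weights.
#'   Dimnames, if present, are used as node labels when \code{labels} is
#'   missing.
#' @param labels character vector of unique node labels; defaults to the
#'   matrix rownames, or \code{"n1".."nN"} when absent.
#' @param hemisphere optional named character vector of \code{"L"}/\code{"R"}
#'   tags (names are node labels), or an unnamed vector in label order.
#'
#' @return A \linkS4class{Connectome}.
#' @examples
#' w <- matrix(c(0, 1.5, 1.5, 0), 2, 2)
#' g <- Connectome(w, labels = c("A", "B"))
#' adjacency(g)["A", "B"]
#' @export
Connectome <- function(weights, labels = NULL, hemisphere = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("'weights' must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop("'weights' must be square")
  }
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("n", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("number of labels must match matrix dimension")
  }
  if (anyDuplicated(labels)) stop("duplicate node labels")
  if (anyNA(weights)) stop("weights must not contain NA")
  asym <- if (n > 0) max(abs(weights - t(weights))) else 0
  if (asym > .SYM_TOL) {
    stop(sprintf("matrix asymmetric beyond tolerance (max |w - t(w)| = %g)",
                 asym))
  }
  w <- (weights + t(weights)) / 2
  if (n > 0 && min(w) < 0) {
    stop("negative weights found; run thresholdNegative() first")
  }
  dimnames(w) <- list(labels, labels)
  h <- character(0)
  if (!is.null(hemisphere)) {
    h <- as.character(hemisphere)
    if (is.null(names(hemisphere))) {
      if (length(h) != n) stop("unnamed hemisphere vector must have length n")
      names(h) <- labels
    } else {
      names(h) <- names(hemisphere)
    }
  }
  new("Connectome", labels = labels, weights = w, hemisphere = h)
}

#' Node labels of a Connectome or Alignment-related object
#'
#' @param x a \linkS4class{Connectome}.
#' @return character vector of node labels in matrix order.
#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "Connectome", function(x) x@labels)

#' Adjacency matrix of a Connectome
#'
#' @param x a \linkS4class{Connectome}.
#' @return the symmetric weight matrix with labels as dimnames.
#' @rdname adjacency
#' @export
setMethod("adjacency", "Connectome", function(x) x@weights)

#' Hemisphere tags of a Connectome
#'
#' @param x a \linkS4class{Connectome}.
#' @return named character vector of \code{"L"}/\code{"R"} tags in node
#'   order, or a zero-length vector when the connectome carries none.
#' @rdname hemisphereTags
#' @export
setMethod("hemisphereTags", "Connectome", function(x) {
  h <- x@hemisphere
  if (length(h) == 0L) return(h)
  h[x@labels]
})

#' Number of nodes
#'
#' @param x a \linkS4class{Connectome}.
#' @rdname nNodes
#' @export
setMethod("nNodes", "Connectome", function(x) length(x@labels))

setMethod("show", "Connectome", function(object) {
  n <- nNodes(object)
  w <- object@weights
  m <- if (n > 0) sum(w[upper.tri(w)] > 0) else 0L
  cat(sprintf("Connectome with %d nodes and %d weighted edges\n", n, m))
  if (n > 0) {
    cat(sprintf("  total unique-edge weight: %g\n", sum(w[upper.tri(w)])))
  }
  if (length(object@hemisphere) > 0L) {
    h <- hemisphereTags(object)
    cat(sprintf("  hemispheres: %d L / %d R\n",
                sum(h == "L"), sum(h == "R")))
  }
  invisible(object)
})

# weights of the unique undirected edges (strict upper triangle)
.upperWeights <- function(g) {
  w <- adjacency(g)
  w[upper.tri(w)]
}

# internal: replace the weight matrix, keeping labels/hemisphere
.withWeights <- function(g, w) {
  dimnames(w) <- list(g@labels, g@labels)
  new("Connectome", labels = g@labels, weights = w,
      hemisphere = g@hemisphere)
}

# reorder g2's adjacency into g1's label order; error on label mismatch
.matchedAdjacency <- function(g1, g2, what = "graphs") {
  if (!setequal(nodeLabels(g1), nodeLabels(g2)) ||
      nNodes(g1) != nNodes(g2)) {
    stop("label sets of the two ", what, " differ")
  }
  idx <- match(nodeLabels(g1), nodeLabels(g2))
  adjacency(g2)[idx, idx, drop = FALSE]
}
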