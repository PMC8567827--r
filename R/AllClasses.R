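#' @import methods
NULL

# symmetry tolerance for adjacency matrices (absolute)
.SYM_TOL <- 1e-12

#' Connectome: a weighted undirected brain network
#'
#' An S4 container for a structural connectome: an ordered set of node
#' labels (brain parcels), a square symmetric non-negative weight matrix
#' whose entries encode connection strength (typically normalised
#' streamline counts), and optional per-node hemisphere tags.
#'
#' @slot labels character vector of unique node identifiers; its order is
#'   the row/column order of \code{weights}.
#' @slot weights square numeric matrix, symmetric within \code{1e-12},
#'   all entries non-negative.
#' @slot hemisphere named character vector mapping node labels to
#'   \code{"L"} or \code{"R"}; length zero when no tags are attached.
#'
#' @details Symmetry is enforced at construction: matrices within the
#' tolerance are symmetrised by averaging, larger asymmetries are
#' rejected. Negative entries are rejected; raw matrices with negative
#' entries (e.g. regressed functional connectivity) must go through
#' \code{\link{thresholdNegative}} first. The zero diagonal required by
#' the preprocessing pipeline is established by the I/O and generator
#' functions, not by the class validity, so that raw matrices can be
#' represented during preprocessing.
#'
#' @seealso \code{\link{Connectome}}, \code{\link{adjacency}},
#'   \code{\link{nodeLabels}}, \code{\link{hemisphereTags}}
#' @name Connectome-class
#' @rdname Connectome-class
#' @exportClass Connectome
setClass("Connectome",
  representation(
    labels = "character",
    weights = "matrix",
    hemisphere = "character"
  ),
  prototype(
    labels = character(0),
    weights = matrix(numeric(0), 0, 0),
    hemisphere = character(0)
  )
)

setValidity("Connectome", function(object) {
  w <- object@weights
  lab <- object@labels
  msgs <- character(0)
  if (!is.numeric(w)) {
    msgs <- c(msgs, "weights must be a numeric matrix")
  }
  if (nrow(w) != ncol(w)) {
    msgs <- c(msgs, "weight matrix must be square")
  }
  if (nrow(w) != length(lab)) {
    msgs <- c(msgs, "dimension of weights must equal the number of labels")
  }
  if (anyDuplicated(lab)) {
    msgs <- c(msgs, "node labels must be unique")
  }
  if (length(msgs) == 0L && nrow(w) > 0L) {
    if (anyNA(w)) {
      msgs <- c(msgs, "weights must not contain NA")
    } else {
      if (max(abs(w - t(w))) > .SYM_TOL) {
        msgs <- c(msgs, sprintf(
          "weight matrix is asymmetric beyond tolerance %g", .SYM_TOL
        ))
      }
      if (min(w) < 0) {
        msgs <- c(msgs, paste0(
          "negative weights found; apply thresholdNegative() ",
          "before constructing a Connectome"
        ))
      }
    }
  }
  h <- object@hemisphere
  if (length(h) > 0L) {
    if (is.null(names(h)) || !all(names(h) %in% lab)) {
      msgs <- c(msgs, "hemisphere tags must be named by node labels")
    }
    if (!all(h %in% c("L", "R"))) {
      msgs <- c(msgs, "hemisphere tags must be 'L' or 'R'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Alignment: an injective node-label map between two connectomes
#'
#' Represents a graph matching \eqn{m : V_1 \to V_2}: every source node
#' label is mapped to a distinct target node label. In the usual
#' equal-size case the map is a bijection and its matrix form
#' (\code{\link{matchingMatrix}}) is a permutation matrix. Alignments are
#' stored by label, never by index, so that maps survive node reordering
#' and per-hemisphere merging.
#'
#' @slot sourceLabels ordered character vector, the domain \eqn{V_1}.
#' @slot targetLabels ordered character vector, the codomain \eqn{V_2}.
#' @slot map named character vector; \code{map[u]} is the target label
#'   assigned to source label \code{u}. Injective.
#'
#' @seealso \code{\link{Alignment}}, \code{\link{matchingMatrix}},
#'   \code{\link{applyAlignment}}
#' @name Alignment-class
#' @rdname Alignment-class
#' @exportClass Alignment
setClass("Alignment",
  representation(
    sourceLabels = "character",
    targetLabels = "character",
    map = "character"
  )
)

setValidity("Alignment", function(object) {
  msgs <- character(0)
  src <- object@sourceLabels
  tgt <- object@targetLabels
  m <- object@map
  if (anyDuplicated(src)) msgs <- c(msgs, "source labels must be unique")
  if (anyDuplicated(tgt)) msgs <- c(msgs, "target labels must be unique")
  if (length(src) > length(tgt)) {
    msgs <- c(msgs, "alignment needs |source| <= |target|")
  }
  if (is.null(names(m)) || !setequal(names(m), src) ||
      length(m) != length(src)) {
    msgs <- c(msgs, "map must be named by exactly the source labels")
  }
  if (!all(m %in% tgt)) {
    msgs <- c(msgs, "every mapped target label must exist in targetLabels")
  }
  if (anyDuplicated(m)) {
    msgs <- c(msgs, "map must be injective")
  }
  if (length(msgs)) msgs else TRUE
})
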