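#' Construct an Alignment
#'
#' An alignment is an injective map \eqn{m : V_1 \to V_2} from the node
#' labels of one connectome to those of another; in the usual equal-size
#' setting it is a bijection.
#'
#' @param map named character vector: \code{map[u]} is the target label
#'   assigned to source label \code{u}.
#' @param targetLabels ordered character vector of the target label
#'   universe; defaults to the mapped labels (bijection case).
#' @param sourceLabels ordered character vector of the source labels;
#'   defaults to \code{names(map)}.
#'
#' @return An \linkS4class{Alignment}.
#' @examples
#' a <- Alignment(c(A = "y", B = "x"), targetLabels = c("x", "y"))
#' matchingMatrix(a)
#' @export
Alignment <- function(map, targetLabels = NULL, sourceLabels = NULL) {
  map <- vapply(map, as.character, character(1))
  if (is.null(names(map))) stop("'map' must be a named vector")
  if (is.null(sourceLabels)) sourceLabels <- names(map)
  if (is.null(targetLabels)) targetLabels <- unname(map)
  new("Alignment",
      sourceLabels = as.character(sourceLabels),
      targetLabels = as.character(targetLabels),
      map = map[sourceLabels])
}

#' @param x an \linkS4class{Alignment}.
#' @return \code{sourceLabels}: the ordered source label vector.
#' @rdname sourceLabels
#' @export
setMethod("sourceLabels", "Alignment", function(x) x@sourceLabels)

#' @param x an \linkS4class{Alignment}.
#' @return \code{targetLabels}: the ordered target label vector.
#' @rdname targetLabels
#' @export
setMethod("targetLabels", "Alignment", function(x) x@targetLabels)

#' Label map of an alignment
#'
#' @param x an \linkS4class{Alignment}.
#' @return named character vector mapping source labels to target labels.
#' @rdname alignmentMap
#' @export
setMethod("alignmentMap", "Alignment", function(x) x@map)

setMethod("show", "Alignment", function(object) {
  n1 <- length(object@sourceLabels)
  n2 <- length(object@targetLabels)
  cat(sprintf("Alignment of %d source nodes into %d target nodes\n", n1, n2))
  k <- min(n1, 4L)
  if (k > 0) {
    u <- object@sourceLabels[seq_len(k)]
    cat("  ", paste(u, "->", object@map[u], collapse = ", "),
        if (n1 > k) ", ..." else "", "\n", sep = "")
  }
  invisible(object)
})

#' Identity alignment on a label set
#'
#' @param labels character vector of node labels.
#' @return the \linkS4class{Alignment} mapping every label to itself.
#' @export
identityAlignment <- function(labels) {
  labels <- as.character(labels)
  Alignment(stats::setNames(labels, labels), targetLabels = labels)
}

#' Invert a bijective alignment
#'
#' @param a a bijective \linkS4class{Alignment}.
#' @return the inverse \linkS4class{Alignment}.
#' @export
invertAlignment <- function(a) {
  if (length(sourceLabels(a)) != length(targetLabels(a))) {
    stop("only bijective alignments can be inverted")
  }
  m <- alignmentMap(a)
  Alignment(stats::setNames(names(m), unname(m))[targetLabels(a)],
            targetLabels = sourceLabels(a))
}

#' Compose two alignments
#'
#' Returns the alignment \eqn{u \mapsto b(a(u))}.
#'
#' @param a an \linkS4class{Alignment} from \eqn{V_1} to \eqn{V_2}.
#' @param b an \linkS4class{Alignment} from \eqn{V_2} to \eqn{V_3}.
#' @return the composed \linkS4class{Alignment} from \eqn{V_1} to \eqn{V_3}.
#' @export
composeAlignments <- function(a, b) {
  ma <- alignmentMap(a)
  mb <- alignmentMap(b)
  if (!all(ma %in% names(mb))) {
    stop("codomain of 'a' is not contained in the domain of 'b'")
  }
  Alignment(stats::setNames(unname(mb[ma]), names(ma)),
            targetLabels = targetLabels(b),
            sourceLabels = sourceLabels(a))
}

#' Matching matrix of an alignment
#'
#' The binary matrix form \eqn{P_m} of an alignment \eqn{m}: an
#' \eqn{n_2 \times n_1} matrix with \eqn{P_{ij} = 1} iff \eqn{m} sends
#' the \eqn{j}-th source label to the \eqn{i}-th target label. Each
#' column sums to 1 and each row to at most 1; for a bijection the
#' result is a permutation matrix.
#'
#' @param a an \linkS4class{Alignment}.
#' @return binary matrix with target labels as rownames and source
#'   labels as colnames.
#' @export
matchingMatrix <- function(a) {
  src <- sourceLabels(a)
  tgt <- targetLabels(a)
  P <- matrix(0, nrow = length(tgt), ncol = length(src),
              dimnames = list(tgt, src))
  P[cbind(match(alignmentMap(a)[src], tgt), seq_along(src))] <- 1
  P
}

#' Pull a connectome back through an alignment
#'
#' Given a connectome \eqn{G_2} on the target labels and an alignment
#' \eqn{m : V_1 \to V_2}, returns the connectome on the source labels
#' whose adjacency is \eqn{P_m^\top \mathrm{Adj}(G_2) P_m} — i.e. the
#' relabelling of \eqn{G_2}'s nodes under \eqn{m^{-1}}. The multiset of
#' edge weights is preserved for bijections.
#'
#' @param g a \linkS4class{Connectome} whose label set equals the
#'   alignment's target labels.
#' @param a an \linkS4class{Alignment}.
#' @return a \linkS4class{Connectome} on the alignment's source labels.
#' @examples
#' g <- Connectome(matrix(c(0, 2, 2, 0), 2), labels = c("x", "y"))
#' a <- Alignment(c(A = "y", B = "x"), targetLabels = c("x", "y"))
#' adjacency(applyAlignment(g, a))
#' @export
applyAlignment <- function(g, a) {
  if (!setequal(nodeLabels(g), targetLabels(a))) {
    stop("connectome labels do not match the alignment's target labels")
  }
  tgt <- targetLabels(a)
  idx <- match(tgt, nodeLabels(g))
  A2 <- adjacency(g)[idx, idx, drop = FALSE]
  P <- matchingMatrix(a)
  w <- t(P) %*% A2 %*% P
  h <- character(0)
  if (length(g@hemisphere) > 0L) {
    ht <- hemisphereTags(g)
    h <- stats::setNames(unname(ht[alignmentMap(a)[sourceLabels(a)]]),
                         sourceLabels(a))
  }
  Connectome(w, labels = sourceLabels(a), hemisphere = if (length(h)) h)
}

#' Relabel a connectome through an alignment
#'
#' Pushes a connectome living on the alignment's source labels forward
#' onto the target labels: node \eqn{u} becomes node \eqn{m(u)}, weights
#' unchanged. This is the \eqn{m(G_1)} notation used when scoring an
#' alignment against a reference graph.
#'
#' @param g a \linkS4class{Connectome} on the alignment's source labels.
#' @param a a bijective \linkS4class{Alignment}.
#' @return a \linkS4class{Connectome} on the target labels.
#' @export
relabelConnectome <- function(g, a) {
  if (!setequal(nodeLabels(g), sourceLabels(a))) {
    stop("connectome labels do not match the alignment's source labels")
  }
  if (length(sourceLabels(a)) != length(targetLabels(a))) {
    stop("relabelling requires a bijective alignment")
  }
  applyAlignment(g, invertAlignment(a))
}

#' Read / write alignments
#'
#' Alignments are stored as two-column TSV files (\code{source_label},
#' \code{target_label}, with header) or as JSON objects mapping source
#' labels to target labels.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"json"}; inferred from the file
#'   extension when missing.
#' @param targetLabels optional full target label universe (for
#'   non-surjective alignments).
#' @return \code{readAlignment}: an \linkS4class{Alignment}.
#' @export
readAlignment <- function(path, format = c("auto", "tsv", "json"),
                          targetLabels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    m <- unlist(jsonlite::read_json(path))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    m <- stats::setNames(df[[2]], df[[1]])
  }
  Alignment(m, targetLabels = targetLabels)
}

#' @param a an \linkS4class{Alignment} to write.
#' @rdname readAlignment
#' @return \code{writeAlignment}: the path, invisibly.
#' @export
writeAlignment <- function(a, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  m <- alignmentMap(a)
  if (format == "json") {
    jsonlite::write_json(as.list(m), path, auto_unbox = TRUE)
  } else {
    utils::write.table(
      data.frame(source_label = names(m), target_label = unname(m)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
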