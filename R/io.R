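#' Read a connectome from disk
#'
#' Supports three plain-text dialects: a labelled adjacency-matrix CSV
#' (first row and first column carry node labels), a weighted edge-list
#' TSV (\code{source}, \code{target}, \code{weight}; undirected, missing
#' pairs get weight 0), and GraphML (read through \pkg{igraph}).
#'
#' @param path file path.
#' @param format one of \code{"matrix-csv"}, \code{"edgelist-tsv"},
#'   \code{"graphml"}; \code{"auto"} infers from the extension.
#' @param hemisphereMap optional path to a two-column TSV sidecar
#'   (\code{label}, \code{hemisphere}) attaching L/R tags; for GraphML a
#'   node attribute named \code{hemisphere} is honoured automatically.
#' @param hemiRegex optional regular expression; labels matching it are
#'   tagged \code{"L"}, all others \code{"R"} (convenience for atlases
#'   that encode the hemisphere in the label).
#'
#' @return A \linkS4class{Connectome}. Negative entries are an error:
#'   run such matrices through \code{\link{thresholdNegative}} instead.
#' @export
readConnectome <- function(path,
                           format = c("auto", "matrix-csv", "edgelist-tsv",
                                      "graphml"),
                           hemisphereMap = NULL, hemiRegex = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "matrix-csv",
      tsv = "edgelist-tsv",
      graphml = "graphml",
      stop("cannot infer format from extension of ", path))
  }
  g <- switch(format,
    "matrix-csv" = .readMatrixCSV(path),
    "edgelist-tsv" = .readEdgeListTSV(path),
    "graphml" = .readGraphML(path))
  if (!is.null(hemisphereMap)) {
    df <- utils::read.table(hemisphereMap, header = TRUE, sep = "\t",
                            colClasses = "character")
    g <- Connectome(adjacency(g), labels = nodeLabels(g),
                    hemisphere = stats::setNames(df[[2]], df[[1]]))
  } else if (!is.null(hemiRegex)) {
    lab <- nodeLabels(g)
    h <- ifelse(grepl(hemiRegex, lab), "L", "R")
    g <- Connectome(adjacency(g), labels = lab,
                    hemisphere = stats::setNames(h, lab))
  }
  g
}

.readMatrixCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  w <- as.matrix(df)
  if (nrow(w) != ncol(w)) {
    stop("matrix in ", path, " is not square (", nrow(w), "x", ncol(w), ")")
  }
  if (!identical(rownames(w), colnames(w))) {
    stop("row and column labels of ", path, " differ")
  }
  Connectome(w)
}

.readEdgeListTSV <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("source", "target", "weight"),
                          colClasses = c("character", "character", "numeric"))
  labels <- unique(c(df$source, df$target))
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(df$source, labels)
  j <- match(df$target, labels)
  # each undirected edge may be stated once or (consistently) twice
  for (r in seq_len(nrow(df))) {
    prev <- w[i[r], j[r]]
    if (prev != 0 && abs(prev - df$weight[r]) > .SYM_TOL) {
      stop("inconsistent duplicate edge ", df$source[r], "--", df$target[r],
           " in ", path)
    }
    w[i[r], j[r]] <- df$weight[r]
    w[j[r], i[r]] <- df$weight[r]
  }
  diag(w) <- 0
  Connectome(w)
}

.readGraphML <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  labels <- igraph::vertex_attr(ig, "name")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(ig)))
  w <- igraph::as_adjacency_matrix(ig, attr = "weight", sparse = FALSE)
  dimnames(w) <- list(labels, labels)
  hemi <- igraph::vertex_attr(ig, "hemisphere")
  Connectome(w, labels = labels,
             hemisphere = if (!is.null(hemi)) {
               stats::setNames(hemi, labels)
             })
}

#' Write a connectome to disk
#'
#' Matrix CSV round-trips bit-compatibly (full double precision via
#' \code{format(..., digits = 17)}); edge lists state each undirected
#' edge once; GraphML stores weights as an edge attribute and hemisphere
#' tags, when present, as a node attribute.
#'
#' @param g a \linkS4class{Connectome}.
#' @param path output file path.
#' @param format as in \code{\link{readConnectome}}.
#' @return the path, invisibly.
#' @export
writeConnectome <- function(g, path,
                            format = c("auto", "matrix-csv", "edgelist-tsv",
                                       "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "matrix-csv",
      tsv = "edgelist-tsv",
      graphml = "graphml",
      stop("cannot infer format from extension of ", path))
  }
  switch(format,
    "matrix-csv" = .writeMatrixCSV(g, path),
    "edgelist-tsv" = .writeEdgeListTSV(g, path),
    "graphml" = .writeGraphML(g, path))
  invisible(path)
}

.writeMatrixCSV <- function(g, path) {
  w <- adjacency(g)
  lab <- nodeLabels(g)
  lines <- c(
    paste(c("", lab), collapse = ","),
    vapply(seq_along(lab), function(i) {
      paste(c(lab[i], format(w[i, ], digits = 17, trim = TRUE,
                             scientific = FALSE)),
            collapse = ",")
    }, character(1)))
  writeLines(lines, path)
}

.writeEdgeListTSV <- function(g, path) {
  w <- adjacency(g)
  lab <- nodeLabels(g)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(source = lab[ut[, 1]], target = lab[ut[, 2]],
                   weight = format(w[ut], digits = 17, trim = TRUE,
                                   scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.writeGraphML <- function(g, path) {
  ig <- .asIgraph(g)
  igraph::write_graph(ig, path, format = "graphml")
}

# Connectome -> igraph (weighted, undirected, named)
.asIgraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(adjacency(g), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::V(ig)$name <- nodeLabels(g)
  h <- hemisphereTags(g)
  if (length(h) > 0L) igraph::V(ig)$hemisphere <- unname(h)
  ig
}
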