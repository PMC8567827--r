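#' @rdname nodeLabels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname adjacency
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname hemisphereTags
#' @export
setGeneric("hemisphereTags", function(x) standardGeneric("hemisphereTags"))

#' @rdname nNodes
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname sourceLabels
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))

#' @rdname targetLabels
#' @export
setGeneric("targetLabels", function(x) standardGeneric("targetLabels"))

#' @rdname alignmentMap
#' @export
setGeneric("alignmentMap", function(x) standardGeneric("alignmentMap"))
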