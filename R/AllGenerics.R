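#' Network accessors
#'
#' @param x a [FoodNetwork-class] or [TargetNetwork-class].
#' @return `networkNodes`/`networkEdges` return the node/edge data.frame;
#'   `asIgraph` an undirected weighted [igraph::graph] carrying all
#'   attributes.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkNodes
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname topKEdges
#' @export
setGeneric("topKEdges", function(x, k, ...) standardGeneric("topKEdges"))

for (cls in c("FoodNetwork", "TargetNetwork")) {
  setMethod("networkNodes", cls, function(x) x@nodes)
  setMethod("networkEdges", cls, function(x) x@edges)
  setMethod("asIgraph", cls, function(x) {
    igraph::graph_from_data_frame(
      d = x@edges, directed = FALSE,
      vertices = x@nodes)
  })
}

#' Registry accessors
#'
#' Read-only access to the validated tables of a [DfiRegistry-class].
#'
#' @param x a [DfiRegistry-class].
#' @return The corresponding data.frame (or matrix / list).
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))
#' @rdname compounds
#' @export
setGeneric("foods", function(x) standardGeneric("foods"))
#' @rdname compounds
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname compounds
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))
#' @rdname compounds
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname compounds
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname compounds
#' @export
setGeneric("orthologs", function(x) standardGeneric("orthologs"))
#' @rdname compounds
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
#' @rdname compounds
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname compounds
#' @export
setGeneric("referenceRanks", function(x) standardGeneric("referenceRanks"))
#' @rdname compounds
#' @export
setGeneric("referenceInstances",
           function(x) standardGeneric("referenceInstances"))
#' @rdname compounds
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

setMethod("compounds", "DfiRegistry", function(x) x@compounds)
setMethod("foods", "DfiRegistry", function(x) x@foods)
setMethod("proteins", "DfiRegistry", function(x) x@proteins)
setMethod("drugs", "DfiRegistry", function(x) x@drugs)
setMethod("measurements", "DfiRegistry", function(x) x@measurements)
setMethod("ppiEdges", "DfiRegistry", function(x) x@ppi)
setMethod("orthologs", "DfiRegistry", function(x) x@orthologs)
setMethod("expressionMatrix", "DfiRegistry", function(x) x@expression)
setMethod("sampleGroups", "DfiRegistry", function(x) x@groups)
setMethod("referenceRanks", "DfiRegistry", function(x) x@referenceRanks)
setMethod("referenceInstances", "DfiRegistry", function(x) x@instances)
setMethod("loadReport", "DfiRegistry", function(x) x@loadReport)
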