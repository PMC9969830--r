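#' Accessors for netkin objects
#'
#' Small generic accessors so code never reaches into slots directly.
#'
#' @param object a netkin S4 object.
#' @return `nodeIds`: character vector of gene symbols; `edgeTable` /
#'   `droppedEdges` / `elementTable` / `reactionTable` / `datasetTable` /
#'   `fitTrace`: data.frames; the counting accessors: a single integer;
#'   `estimatedParameters`: numeric vector; `trajectoryStates`: numeric
#'   matrix; `trajectoryTimes`: numeric vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("droppedEdges", function(object) standardGeneric("droppedEdges"))
#' @rdname accessors
#' @export
setGeneric("elementTable", function(object) standardGeneric("elementTable"))
#' @rdname accessors
#' @export
setGeneric("reactionTable", function(object) standardGeneric("reactionTable"))
#' @rdname accessors
#' @export
setGeneric("nElements", function(object) standardGeneric("nElements"))
#' @rdname accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))
#' @rdname accessors
#' @export
setGeneric("datasetTable", function(object) standardGeneric("datasetTable"))
#' @rdname accessors
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))
#' @rdname accessors
#' @export
setGeneric("estimatedParameters", function(object) standardGeneric("estimatedParameters"))
#' @rdname accessors
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))
#' @rdname accessors
#' @export
setGeneric("trajectoryStates", function(object) standardGeneric("trajectoryStates"))
#' @rdname accessors
#' @export
setGeneric("objectiveTotal", function(object) standardGeneric("objectiveTotal"))
#' @rdname accessors
#' @export
setGeneric("objectivePsi", function(object) standardGeneric("objectivePsi"))

#' @rdname accessors
setMethod("nodeIds", "InteractionNetwork", function(object) object@nodes$gene_id)
#' @rdname accessors
setMethod("edgeTable", "InteractionNetwork", function(object) object@edges)
#' @rdname accessors
setMethod("droppedEdges", "InteractionNetwork", function(object) object@dropped)

#' @rdname accessors
setMethod("elementTable", "ReactionSystem", function(object) object@elements)
#' @rdname accessors
setMethod("reactionTable", "ReactionSystem", function(object) object@reactions)
#' @rdname accessors
setMethod("nElements", "ReactionSystem", function(object) nrow(object@elements))
#' @rdname accessors
setMethod("nReactions", "ReactionSystem", function(object) nrow(object@reactions))
#' @rdname accessors
setMethod("nParameters", "ReactionSystem", function(object) object@n_parameters)

#' @rdname accessors
setMethod("nElements", "OdeModel", function(object) object@n)
#' @rdname accessors
setMethod("nReactions", "OdeModel", function(object) object@m)
#' @rdname accessors
setMethod("nParameters", "OdeModel", function(object) object@n_parameters)

#' @rdname accessors
setMethod("datasetTable", "ExperimentalDataset", function(object) object@data)

#' @rdname accessors
setMethod("fitTrace", "FitResult", function(object) object@trace)
#' @rdname accessors
setMethod("estimatedParameters", "FitResult", function(object) object@k_hat)

#' @rdname accessors
setMethod("trajectoryTimes", "Trajectory", function(object) object@times)
#' @rdname accessors
setMethod("trajectoryStates", "Trajectory", function(object) object@states)

#' @rdname accessors
setMethod("objectiveTotal", "ObjectiveReport", function(object) object@stotal)
#' @rdname accessors
setMethod("objectivePsi", "ObjectiveReport", function(object) object@psi)

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf(
    "InteractionNetwork: %d nodes, %d edges (%d input rows dropped)\n",
    nrow(object@nodes), nrow(object@edges), nrow(object@dropped)
  ))
  if (nrow(object@edges)) {
    tab <- table(object@edges$mechanism)
    cat("  mechanisms:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf(
    "ReactionSystem (%s dialect): %d elements, %d reactions, %d parameters\n",
    object@dialect, nElements(object), nReactions(object), nParameters(object)
  ))
  if (nElements(object)) {
    tab <- table(object@elements$form)
    cat("  elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "OdeModel", function(object) {
  cat(sprintf(
    "OdeModel: %d states, %d reactions, %d parameters (H %dx%d, arity %d/%d)\n",
    object@n, object@m, object@n_parameters, object@n, object@m,
    ncol(object@XR), ncol(object@XP)
  ))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d time points (%.3g..%.3g h), %d states\n",
    length(object@times), min(object@times), max(object@times),
    ncol(object@states)
  ))
})

setMethod("show", "ExperimentalDataset", function(object) {
  d <- object@data
  cat(sprintf(
    "ExperimentalDataset: %d measurements, %d genes, layers {%s}, conditions {%s}\n",
    nrow(d), length(unique(d$gene)),
    paste(sort(unique(d$layer)), collapse = ", "),
    paste(sort(unique(d$condition)), collapse = ", ")
  ))
})

setMethod("show", "ObjectiveReport", function(object) {
  cat(sprintf(
    "ObjectiveReport: Sp=%.4g Sph=%.4g Srna=%.4g Stotal=%.4g Psi=%.4g (%d cells, %d obs)\n",
    object@sp, object@sph, object@srna, object@stotal, object@psi,
    object@n_cells, object@n_obs
  ))
})

setMethod("show", "FitResult", function(object) {
  last <- if (nrow(object@trace)) utils::tail(object@trace, 1) else NULL
  cat(sprintf(
    "FitResult: %d parameters, %d trace rows, converged=%s, seed=%d\n",
    length(object@k_hat), nrow(object@trace), object@converged, object@seed
  ))
  if (!is.null(last)) {
    cat(sprintf("  final Stotal=%.6g Psi=%.6g\n", last$stotal, last$psi))
  }
})

setMethod("show", "AggregationMatrices", function(object) {
  cat(sprintf(
    "AggregationMatrices: protein %dx%d, phospho %dx%d, rna %dx%d\n",
    nrow(object@protein), ncol(object@protein),
    nrow(object@phospho), ncol(object@phospho),
    nrow(object@rna), ncol(object@rna)
  ))
})
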