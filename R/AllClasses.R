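#' Interaction network of typed, signed edges between biomolecules
#'
#' Directed graph produced by [readSignorSnapshot()] /
#' [harvestSubnetwork()].  Nodes are gene symbols (isoforms collapsed);
#' edges carry a mechanism (one of phosphorylation, dephosphorylation,
#' ubiquitination, binding, transcriptional_regulation), a signed effect
#' (activation / inhibition) and free-text evidence.  Edges are stored in a
#' canonical sort order so that downstream compilation is independent of
#' the row order of the input file.
#'
#' @slot nodes data.frame with column `gene_id` (unique, normalized gene
#'   symbols).
#' @slot edges data.frame with columns `source`, `target`, `mechanism`,
#'   `effect`, `evidence`.
#' @slot dropped data.frame log of input rows not retained, with a
#'   `reason` column (conservation of edge count is checked against it).
#'
#' @seealso [interactionNetwork()], [nodeIds()], [edgeTable()]
#' @export
setClass("InteractionNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    dropped = "data.frame"
  )
)

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  if (!identical(colnames(object@nodes), "gene_id")) {
    msg <- c(msg, "nodes must have a single 'gene_id' column")
  }
  need <- c("source", "target", "mechanism", "effect", "evidence")
  if (!all(need %in% colnames(object@edges))) {
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  } else {
    e <- object@edges
    if (anyDuplicated(object@nodes$gene_id)) {
      msg <- c(msg, "duplicate gene_id in nodes")
    }
    if (nrow(e)) {
      if (!all(e$mechanism %in% SUPPORTED_MECHANISMS)) {
        msg <- c(msg, "unsupported mechanism in edges")
      }
      if (!all(e$effect %in% SUPPORTED_EFFECTS)) {
        msg <- c(msg, "unsupported effect in edges")
      }
      if (!all(c(e$source, e$target) %in% object@nodes$gene_id)) {
        msg <- c(msg, "edge endpoint not present in nodes")
      }
      key <- paste(e$source, e$target, e$mechanism, e$effect, sep = "\r")
      if (anyDuplicated(key)) msg <- c(msg, "duplicated identical edges")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Registry of molecular elements plus elementary reactions
#'
#' The compiled reaction network.  Every distinct molecular form (an
#' unmodified protein, its phospho- or ubiquitinated form, a complex, free
#' or TF-bound DNA, an mRNA) is an *element* with a unique integer id; the
#' ordered reaction list is the tabular equivalent of a 3-D reactions
#' array, one page per reaction with reactant and product columns.
#'
#' @slot elements data.frame with columns `id`, `name` (display, e.g.
#'   `"A_p"`, `"A:B"`, `"DNA_B:TF_A"`), `form` (one of the element form
#'   classes), `gene` (primary gene for single-gene forms, `NA` for
#'   complexes), and list-columns `genes` (all protein-level member genes)
#'   and `phospho_genes` (members present in phosphorylated form).
#' @slot reactions data.frame with columns `id`, `name`, list-columns
#'   `reactants` / `products` (element ids, multiplicity by repetition, a
#'   catalyst appears on both sides), `reversible`, `rate_law`
#'   (`"mass_action"`, `"michaelis_menten"`, `"hill"`), `hill_n`,
#'   parameter slots `kf` / `kb` (`kb` is `NA` for irreversible reactions),
#'   and provenance columns `rule`, `src`, `tgt`.
#' @slot n_parameters integer, total number of parameter slots; every slot
#'   in `[1, n_parameters]` is used exactly once.
#' @slot dialect character, the edge-expansion dictionary used
#'   (`"lumped"` or `"detailed"`).
#'
#' @seealso [compileReactions()], [expandEdge()], [addHousekeeping()]
#' @export
setClass("ReactionSystem",
  representation(
    elements = "data.frame",
    reactions = "data.frame",
    n_parameters = "integer",
    dialect = "character"
  )
)

setValidity("ReactionSystem", function(object) {
  msg <- character()
  el <- object@elements
  rx <- object@reactions
  if (nrow(el) && !identical(el$id, seq_len(nrow(el)))) {
    msg <- c(msg, "element ids must be 1..n in order")
  }
  if (nrow(el) && !all(el$form %in% ELEMENT_FORMS)) {
    msg <- c(msg, "unknown element form")
  }
  if (nrow(rx)) {
    refs <- unlist(c(rx$reactants, rx$products))
    if (length(refs) && (any(refs < 1) || any(refs > nrow(el)))) {
      msg <- c(msg, "reaction references unknown element")
    }
    slots <- c(rx$kf, rx$kb[!is.na(rx$kb)])
    if (anyDuplicated(slots)) msg <- c(msg, "parameter slot used twice")
    if (length(slots) && !setequal(slots, seq_len(object@n_parameters))) {
      msg <- c(msg, "parameter slots must cover 1..n_parameters exactly")
    }
    bad <- !rx$reversible & !is.na(rx$kb)
    if (any(bad)) msg <- c(msg, "irreversible reaction with backward slot")
    empty_both <- vapply(rx$reactants, length, 1L) == 0L &
      vapply(rx$products, length, 1L) == 0L
    if (any(empty_both)) msg <- c(msg, "reaction with neither reactants nor products")
  }
  if (length(msg)) msg else TRUE
})

#' Vectorized mass-action ODE model
#'
#' The executable form of a [ReactionSystem-class]: a signed net
#' stoichiometry matrix `H` (n elements x m reactions) and fixed-width
#' reactant/product index tables.  The rate vector is evaluated as
#' `V = K_F * X[R1] * X[R2] * ... - K_B * X[P1] * X[P2] * ...` where
#' unused table slots point at a reserved constant-one pseudo-state, and
#' derivatives are `H %*% V`.  For a catalyst (same species on both
#' sides) `H` holds the net coefficient 0 while the species still enters
#' the rate product.
#'
#' @slot n,m integer: number of state variables / reactions.
#' @slot H sparse `dgCMatrix`, n x m net stoichiometry.
#' @slot XR,XP integer matrices m x p / m x q of state indices (pad = n+1).
#' @slot kf_idx,kb_idx integer maps from reaction to parameter slot
#'   (`kb_idx` 0 when irreversible).
#' @slot rate_law character per reaction; @slot hill_n numeric per reaction.
#' @slot element_names character display names of the states.
#' @slot n_parameters integer length of the parameter vector K.
#'
#' @seealso [buildOdeModel()], [reactionRates()], [stateDerivatives()],
#'   [simulateModel()]
#' @export
setClass("OdeModel",
  representation(
    n = "integer", m = "integer",
    H = "dgCMatrix",
    XR = "matrix", XP = "matrix",
    kf_idx = "integer", kb_idx = "integer",
    rate_law = "character", hill_n = "numeric",
    element_names = "character",
    n_parameters = "integer"
  )
)

setValidity("OdeModel", function(object) {
  msg <- character()
  if (!identical(dim(object@H), c(object@n, object@m))) {
    msg <- c(msg, "H must be n x m")
  }
  if (nrow(object@XR) != object@m || nrow(object@XP) != object@m) {
    msg <- c(msg, "index tables must have one row per reaction")
  }
  if (object@m > 0) {
    idx <- c(object@XR, object@XP)
    if (any(idx < 1L) || any(idx > object@n + 1L)) {
      msg <- c(msg, "index table entry out of range (pad = n+1)")
    }
  }
  if (length(object@element_names) != object@n) {
    msg <- c(msg, "element_names length must equal n")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory
#'
#' @slot times numeric, strictly increasing sampling times (hours); the
#'   first row of `states` equals the supplied initial state.
#' @slot states numeric matrix, time x n, column names are element names.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix")
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@states)) {
    msg <- c(msg, "one state row per time point required")
  }
  if (length(object@times) > 1 && any(diff(object@times) <= 0)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Layer aggregation matrices
#'
#' Binary matrices summing element concentrations into measured
#' biomolecule totals: row i of the protein matrix selects every element
#' carrying protein i in any form (free, modified, in complexes, bound to
#' DNA); the phospho matrix selects phospho-containing forms; the RNA
#' matrix selects mRNA elements.  Stored sparse with gene row names.
#'
#' @slot protein,phospho,rna sparse `dgCMatrix`, one row per measured
#'   biomolecule in the layer, one column per element.
#' @export
setClass("AggregationMatrices",
  representation(protein = "dgCMatrix", phospho = "dgCMatrix", rna = "dgCMatrix")
)

#' Replicate multi-layer time-course dataset
#'
#' Tidy container for per-biomolecule, per-layer, per-time, per-replicate
#' measurements.  The protein and RNA layers hold absolute concentrations
#' (copies per microliter); the phospho layer holds relative intensities
#' and is mean-normalized before scoring.
#'
#' @slot data data.frame with columns `gene`, `layer` (one of `protein`,
#'   `phospho`, `rna`), `condition`, `time_h`, `replicate`, `value`.
#' @slot absolute named logical per layer: TRUE when the layer is on an
#'   absolute concentration scale.
#' @seealso [experimentalDataset()], [replicateArray()], [layerObjective()]
#' @export
setClass("ExperimentalDataset",
  representation(data = "data.frame", absolute = "logical")
)

setValidity("ExperimentalDataset", function(object) {
  msg <- character()
  need <- c("gene", "layer", "condition", "time_h", "replicate", "value")
  if (!all(need %in% colnames(object@data))) {
    msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
  } else {
    if (!all(object@data$layer %in% DATA_LAYERS)) {
      msg <- c(msg, "layer must be one of protein/phospho/rna")
    }
    if (!all(DATA_LAYERS %in% names(object@absolute))) {
      msg <- c(msg, "absolute flags must name all three layers")
    }
    # series may miss individual cells (skipped in scoring), so no shared
    # time grid is enforced here; replicateArray aligns on the union grid
  }
  if (length(msg)) msg else TRUE
})

#' Objective report for one scored condition
#'
#' @slot sp,sph,srna Band-gated layer sums of squares (protein, phospho,
#'   RNA); absent layers contribute 0.
#' @slot stotal Their sum.
#' @slot psi Square root of `stotal` divided by the total number of
#'   replicate measurements scored (biomolecules x time points x
#'   replicates when balanced).
#' @slot n_cells,n_obs Effective counts: scored (biomolecule, time) cells
#'   and total replicate measurements behind them.
#' @slot residuals Per-(biomolecule, time) table with the simulated value,
#'   band indicator alpha and residual contribution.
#' @export
setClass("ObjectiveReport",
  representation(
    sp = "numeric", sph = "numeric", srna = "numeric",
    stotal = "numeric", psi = "numeric",
    n_cells = "integer", n_obs = "integer",
    residuals = "data.frame"
  )
)

#' Result of a block-coordinate parameter fit
#'
#' @slot k_hat Estimated parameter vector (length `n_parameters`).
#' @slot trace data.frame with one row per optimized group: `cycle`,
#'   `group` (rank in the schedule), `element`, `evaluations`, `stotal`,
#'   `psi`.  `stotal` is non-increasing down the trace.
#' @slot schedule data.frame of the group schedule (element, repetition
#'   count, group size).
#' @slot converged logical, TRUE when the relative improvement of a full
#'   cycle fell below the cycle tolerance.
#' @slot seed integer seed that produced the run.
#' @export
setClass("FitResult",
  representation(
    k_hat = "numeric", trace = "data.frame", schedule = "data.frame",
    converged = "logical", seed = "integer"
  )
)
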