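#' Normalize gene identifiers
#'
#' Uppercases symbols and strips trailing numeric isoform/transcript
#' suffixes (`"-2"`, `"-003"`), so that isoforms and transcript variants
#' of one gene collapse onto one biomolecule.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of canonical gene symbols.
#' @export
#' @examples
#' normalizeGeneIds(c("akt1", "AKT1-2", "TP53-003"))
normalizeGeneIds <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub("-[0-9]+$", "", x)
}

.canonicalEdgeOrder <- function(edges) {
  edges[order(edges$source, edges$target, edges$mechanism, edges$effect), ,
        drop = FALSE]
}

#' Construct an interaction network
#'
#' Low-level constructor: normalizes identifiers, deduplicates identical
#' edges, sorts edges canonically and validates.  Most users go through
#' [readSignorSnapshot()].
#'
#' @param nodes character vector of gene symbols (normalized internally).
#' @param edges data.frame with columns `source`, `target`, `mechanism`,
#'   `effect` and optionally `evidence`.
#' @param dropped optional data.frame log of discarded input rows.
#' @return an [InteractionNetwork-class].
#' @export
interactionNetwork <- function(nodes, edges = NULL, dropped = NULL) {
  nodes <- unique(normalizeGeneIds(nodes))
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(
      source = character(), target = character(), mechanism = character(),
      effect = character(), evidence = character(), stringsAsFactors = FALSE
    )
  } else {
    edges$source <- normalizeGeneIds(edges$source)
    edges$target <- normalizeGeneIds(edges$target)
    if (is.null(edges$evidence)) edges$evidence <- ""
    edges <- edges[, c("source", "target", "mechanism", "effect", "evidence")]
    key <- paste(edges$source, edges$target, edges$mechanism, edges$effect,
                 sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- .canonicalEdgeOrder(edges)
  }
  rownames(edges) <- NULL
  if (is.null(dropped)) {
    dropped <- data.frame(
      source = character(), target = character(), mechanism = character(),
      reason = character(), stringsAsFactors = FALSE
    )
  }
  new("InteractionNetwork",
      nodes = data.frame(gene_id = sort(nodes), stringsAsFactors = FALSE),
      edges = edges, dropped = dropped)
}

# Map a raw MECHANISM string onto the supported vocabulary (NA when
# unsupported).  "dephosphorylation" is matched before "phosphorylation".
.mapMechanism <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ -]+", "_", x)
  out <- rep(NA_character_, length(x))
  out[grepl("dephosphorylation", x)] <- "dephosphorylation"
  out[is.na(out) & grepl("phosphorylation", x)] <- "phosphorylation"
  out[grepl("deubiquitination", x)] <- NA_character_
  out[is.na(out) & grepl("ubiquitination", x)] <- "ubiquitination"
  out[x %in% c("binding", "complex_formation") | grepl("^binding", x)] <- "binding"
  out[grepl("transcriptional", x)] <- "transcriptional_regulation"
  out
}

.mapEffect <- function(effect, mechanism) {
  effect <- tolower(trimws(effect))
  out <- rep(NA_character_, length(effect))
  out[grepl("down-regulates", effect, fixed = TRUE)] <- "inhibition"
  out[is.na(out) & grepl("up-regulates", effect, fixed = TRUE)] <- "activation"
  out[effect %in% c("activation", "inhibition")] <-
    effect[effect %in% c("activation", "inhibition")]
  # binding rows often carry "form complex"-style annotations: the sign is
  # recorded but does not alter compilation, so default them to activation
  out[is.na(out) & mechanism == "binding"] <- "activation"
  out
}

#' Read a SIGNOR-dialect interaction snapshot
#'
#' Parses a local tab-separated snapshot in the SIGNOR dialect (columns
#' `ENTITYA`, `ENTITYB`, `EFFECT`, `MECHANISM`, `DIRECT`, `PMID`; the
#' mapping is overridable through `columns`), restricts edges to the five
#' supported mechanisms, normalizes identifiers, and (when `nodes` is
#' given) drops edges whose endpoints are absent from the biomolecule
#' list.  Every discarded row is logged in the returned network's drop
#' table with its reason, so the input edge count is conserved.
#'
#' @param path path to the snapshot TSV.
#' @param nodes optional character vector of gene symbols (or path to a
#'   one-symbol-per-line text file); when supplied, edges with an endpoint
#'   outside the list are dropped and logged.
#' @param columns named character vector mapping the roles `entity_a`,
#'   `entity_b`, `effect`, `mechanism`, `evidence` to column names in the
#'   file.
#' @return an [InteractionNetwork-class]; node set is `nodes` when given
#'   (including isolated nodes), otherwise the union of edge endpoints.
#' @export
readSignorSnapshot <- function(path, nodes = NULL,
                               columns = c(entity_a = "ENTITYA",
                                           entity_b = "ENTITYB",
                                           effect = "EFFECT",
                                           mechanism = "MECHANISM",
                                           evidence = "PMID")) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- columns[c("entity_a", "entity_b", "effect", "mechanism")]
  missing <- setdiff(unname(mandatory), colnames(raw))
  if (length(missing)) {
    stop("snapshot is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  evid <- if (columns[["evidence"]] %in% colnames(raw)) {
    as.character(raw[[columns[["evidence"]]]])
  } else ""
  edges <- data.frame(
    source = normalizeGeneIds(raw[[columns[["entity_a"]]]]),
    target = normalizeGeneIds(raw[[columns[["entity_b"]]]]),
    mechanism_raw = as.character(raw[[columns[["mechanism"]]]]),
    effect_raw = as.character(raw[[columns[["effect"]]]]),
    evidence = evid, stringsAsFactors = FALSE
  )
  edges$mechanism <- .mapMechanism(edges$mechanism_raw)
  edges$effect <- .mapEffect(edges$effect_raw, edges$mechanism)

  reason <- rep(NA_character_, nrow(edges))
  reason[is.na(edges$mechanism)] <- "unsupported_mechanism"
  reason[is.na(reason) & is.na(edges$effect)] <- "unsupported_effect"

  if (!is.null(nodes)) {
    if (length(nodes) == 1 && file.exists(nodes)) {
      nodes <- readLines(nodes)
      nodes <- nodes[nzchar(trimws(nodes))]
    }
    nodes <- unique(normalizeGeneIds(nodes))
    outside <- !(edges$source %in% nodes) | !(edges$target %in% nodes)
    reason[is.na(reason) & outside] <- "endpoint_not_in_list"
  }
  keep <- is.na(reason)
  kept <- edges[keep, c("source", "target", "mechanism", "effect", "evidence")]
  dup <- duplicated(paste(kept$source, kept$target, kept$mechanism,
                          kept$effect, sep = "\r"))
  dropped <- rbind(
    data.frame(source = edges$source[!keep], target = edges$target[!keep],
               mechanism = edges$mechanism_raw[!keep],
               reason = reason[!keep], stringsAsFactors = FALSE),
    data.frame(source = kept$source[dup], target = kept$target[dup],
               mechanism = kept$mechanism[dup],
               reason = rep("duplicate", sum(dup)), stringsAsFactors = FALSE)
  )
  if (nrow(dropped)) {
    tab <- table(dropped$reason)
    message("readSignorSnapshot: dropped ", nrow(dropped), " row(s) [",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "]")
  }
  if (is.null(nodes)) nodes <- unique(c(kept$source, kept$target))
  if (!nrow(kept)) warning("no supported edges remain after filtering")
  interactionNetwork(nodes = nodes, edges = kept, dropped = dropped)
}

#' Restrict a network to a gene list
#'
#' Keeps exactly the edges whose BOTH endpoints are in `genes`; the node
#' set of the result is `genes` itself (isolated nodes included).
#' Idempotent for a fixed gene list.
#'
#' @param net an [InteractionNetwork-class].
#' @param genes nonempty character vector of gene symbols.
#' @return an [InteractionNetwork-class].
#' @export
harvestSubnetwork <- function(net, genes) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!length(genes)) stop("'genes' must be nonempty")
  genes <- unique(normalizeGeneIds(genes))
  e <- edgeTable(net)
  keep <- e$source %in% genes & e$target %in% genes
  interactionNetwork(nodes = genes, edges = e[keep, , drop = FALSE],
                     dropped = droppedEdges(net))
}

#' Infer each protein's active modification form
#'
#' Scans modification edges to decide which form of each target is the
#' functionally active one: a phosphorylation edge that *activates* its
#' target implies the phosphorylated form is active; a phosphorylation
#' that *inhibits* implies the unmodified form is active; symmetrically
#' for dephosphorylation (so a dephosphorylation--inhibition edge onto C
#' marks phosphorylated C as active).  Ubiquitination routes degradation
#' and casts no vote; untouched nodes default to unmodified-active.
#' Conflicting evidence is resolved by majority vote over the implicated
#' edges; an exact tie resolves to phosphorylated-active with a warning.
#'
#' @param net an [InteractionNetwork-class].
#' @return data.frame (the active-mode table) with columns `gene_id`,
#'   `active_form` (`"unmodified"` or `"phosphorylated"`),
#'   `votes_phosphorylated`, `votes_unmodified`, `conflict` (logical: both
#'   vote counts positive), `tie` (logical: resolved by the tie-break).
#' @export
inferActiveModes <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  genes <- nodeIds(net)
  e <- edgeTable(net)
  e <- e[e$mechanism %in% MODIFICATION_MECHANISMS, , drop = FALSE]
  # vote: phosphorylated-active iff (phos & activation) | (dephos & inhibition)
  phos_vote <- (e$mechanism == "phosphorylation" & e$effect == "activation") |
    (e$mechanism == "dephosphorylation" & e$effect == "inhibition")
  vp <- vapply(genes, function(g) sum(e$target == g & phos_vote), 1L)
  vu <- vapply(genes, function(g) sum(e$target == g & !phos_vote), 1L)
  form <- ifelse(vp > vu, "phosphorylated",
          ifelse(vu > vp, "unmodified",
          ifelse(vp > 0, "phosphorylated", "unmodified")))
  tie <- vp == vu & vp > 0
  if (any(tie)) {
    warning("active-mode tie for ", paste(genes[tie], collapse = ", "),
            "; resolved to phosphorylated-active")
  }
  data.frame(
    gene_id = genes, active_form = unname(form),
    votes_phosphorylated = unname(vp), votes_unmodified = unname(vu),
    conflict = unname(vp > 0 & vu > 0), tie = unname(tie),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
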