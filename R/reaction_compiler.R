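# ---- element registry -------------------------------------------------
# Elements are registered once per distinct (genes, form, partner set);
# the registry hands out sequential integer ids in registration order,
# which is deterministic because compile walks edges in canonical order.

.newRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$items <- list()
  reg
}

.regAdd <- function(reg, key, name, form, gene, genes, phospho_genes) {
  it <- reg$items[[key]]
  if (!is.null(it)) return(it$id)
  id <- length(reg$items) + 1L
  reg$items[[key]] <- list(
    id = id, name = name, form = form, gene = gene,
    genes = genes, phospho_genes = phospho_genes
  )
  id
}

.regProtein <- function(reg, g) {
  .regAdd(reg, paste0("protein|", g), g, "protein", g, g, character(0))
}
.regPhospho <- function(reg, g) {
  .regAdd(reg, paste0("phospho_protein|", g), paste0(g, "_p"),
          "phospho_protein", g, g, g)
}
.regUbiq <- function(reg, g) {
  .regAdd(reg, paste0("ubiq_protein|", g), paste0(g, "_ub"),
          "ubiq_protein", g, g, character(0))
}
.regRna <- function(reg, g) {
  .regAdd(reg, paste0("rna|", g), paste0("RNA_", g), "rna", g,
          character(0), character(0))
}
.regDnaFree <- function(reg, g) {
  .regAdd(reg, paste0("dna_free|", g), paste0("DNA_", g), "dna_free", g,
          character(0), character(0))
}
.regDnaBound <- function(reg, g, tf, tf_phos) {
  tfname <- paste0("TF_", tf, if (tf_phos) "_p" else "")
  .regAdd(reg, paste0("dna_bound|", g, "|", tf, "|", tf_phos),
          paste0("DNA_", g, ":", tfname), "dna_bound", g,
          tf, if (tf_phos) tf else character(0))
}
# members: data.frame(gene, phos) — token order defines the display name
.regComplex <- function(reg, members) {
  tok <- paste0(members$gene, ifelse(members$phos, "_p", ""))
  .regAdd(reg, paste0("complex|", paste(sort(tok), collapse = "|")),
          paste(tok, collapse = ":"), "complex", NA_character_,
          members$gene, members$gene[members$phos])
}

.registryTable <- function(reg) {
  items <- reg$items
  if (!length(items)) {
    return(data.frame(
      id = integer(), name = character(), form = character(),
      gene = character(),
      genes = I(list()), phospho_genes = I(list()),
      stringsAsFactors = FALSE
    ))
  }
  items <- items[order(vapply(items, function(x) x$id, 1L))]
  data.frame(
    id = vapply(items, function(x) x$id, 1L),
    name = vapply(items, function(x) x$name, ""),
    form = vapply(items, function(x) x$form, ""),
    gene = vapply(items, function(x) x$gene, ""),
    genes = I(unname(lapply(items, function(x) x$genes))),
    phospho_genes = I(unname(lapply(items, function(x) x$phospho_genes))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.registryFromTable <- function(el) {
  reg <- .newRegistry()
  for (i in seq_len(nrow(el))) {
    key <- switch(el$form[i],
      protein = paste0("protein|", el$gene[i]),
      phospho_protein = paste0("phospho_protein|", el$gene[i]),
      ubiq_protein = paste0("ubiq_protein|", el$gene[i]),
      rna = paste0("rna|", el$gene[i]),
      dna_free = paste0("dna_free|", el$gene[i]),
      dna_bound = paste0("dna_bound|", el$gene[i], "|", el$genes[[i]],
                         "|", length(el$phospho_genes[[i]]) > 0),
      complex = {
        phos <- el$genes[[i]] %in% el$phospho_genes[[i]]
        # reconstruct token multiset from display name for exactness
        paste0("complex|",
               paste(sort(strsplit(el$name[i], ":", fixed = TRUE)[[1]]),
                     collapse = "|"))
      }
    )
    reg$items[[key]] <- list(
      id = el$id[i], name = el$name[i], form = el$form[i],
      gene = el$gene[i], genes = el$genes[[i]],
      phospho_genes = el$phospho_genes[[i]]
    )
  }
  reg
}

# ---- active-mode helpers ----------------------------------------------

.activeFormOf <- function(modes, g) {
  i <- match(g, modes$gene_id)
  if (is.na(i)) return("unmodified")
  f <- modes$active_form[i]
  if (identical(f, "unresolved")) {
    stop("active mode of gene '", g, "' is unresolved; resolve it before compiling")
  }
  f
}

.regActive <- function(reg, g, modes) {
  switch(.activeFormOf(modes, g),
    phosphorylated = .regPhospho(reg, g),
    ubiquitinated = .regUbiq(reg, g),
    .regProtein(reg, g)
  )
}

.activeToken <- function(g, modes) {
  data.frame(gene = g, phos = .activeFormOf(modes, g) == "phosphorylated",
             stringsAsFactors = FALSE)
}

# ---- edge expansion dictionary ----------------------------------------

.proto <- function(reactants, products, reversible, rule, src, tgt,
                   rate_law = "mass_action", hill_n = NA_real_) {
  list(reactants = as.integer(reactants), products = as.integer(products),
       reversible = reversible, rate_law = rate_law, hill_n = hill_n,
       rule = rule, src = src, tgt = tgt)
}

# Expansion of one edge into reaction prototypes, registering any new
# elements in `reg`.  Dictionary ("lumped" dialect):
#   phosphorylation  B->A : B_act + A      -> B_act + A_p     (1 slot)
#   dephosphorylation B->A: B_act + A_p    -> B_act + A       (1 slot)
#   ubiquitination   B->A : B_act + A      -> B_act + A_ub    (1 slot)
#   binding          A--B : A_act + B_act <-> A:B              (2 slots)
#   transcription act A->B: TF_A + DNA_B <-> DNA_B:TF_A        (2 slots)
#                           DNA_B:TF_A -> DNA_B:TF_A + RNA_B   (1 slot)
#                           RNA_B      -> RNA_B + B            (1 slot)
#   transcription inh A->B: TF binding as above (sequesters DNA),
#                           transcription from FREE DNA only, translation.
# "detailed" dialect splits each catalytic edge into reversible
# enzyme-substrate binding plus irreversible catalysis (3 slots).
.expandEdgeInto <- function(reg, edge, modes, dialect = "lumped") {
  src <- edge$source; tgt <- edge$target
  mech <- edge$mechanism; eff <- edge$effect
  if (!mech %in% SUPPORTED_MECHANISMS) {
    stop("unsupported mechanism '", mech, "' on edge ", src, " -> ", tgt)
  }
  .activeFormOf(modes, src)  # errors on an unresolved endpoint
  .activeFormOf(modes, tgt)
  protos <- list()
  if (mech %in% CATALYTIC_MECHANISMS) {
    enz <- .regActive(reg, src, modes)
    sub_ids <- switch(mech,
      phosphorylation = c(.regProtein(reg, tgt), .regPhospho(reg, tgt)),
      dephosphorylation = c(.regPhospho(reg, tgt), .regProtein(reg, tgt)),
      ubiquitination = c(.regProtein(reg, tgt), .regUbiq(reg, tgt))
    )
    substrate <- sub_ids[1]; product <- sub_ids[2]
    if (identical(dialect, "lumped")) {
      protos <- list(.proto(c(enz, substrate), c(enz, product),
                            FALSE, mech, src, tgt))
    } else {
      es_members <- rbind(.activeToken(src, modes),
                          data.frame(gene = tgt,
                                     phos = mech == "dephosphorylation",
                                     stringsAsFactors = FALSE))
      es <- .regComplex(reg, es_members)
      protos <- list(
        .proto(c(enz, substrate), es, TRUE, paste0(mech, "_binding"), src, tgt),
        .proto(es, c(enz, product), FALSE, mech, src, tgt)
      )
    }
  } else if (mech == "binding") {
    a <- .regActive(reg, src, modes)
    b <- .regActive(reg, tgt, modes)
    ab <- .regComplex(reg, rbind(.activeToken(src, modes),
                                 .activeToken(tgt, modes)))
    protos <- list(.proto(c(a, b), ab, TRUE, "binding", src, tgt))
  } else { # transcriptional_regulation
    tf <- .regActive(reg, src, modes)
    tf_phos <- .activeFormOf(modes, src) == "phosphorylated"
    dna <- .regDnaFree(reg, tgt)
    bound <- .regDnaBound(reg, tgt, src, tf_phos)
    rna <- .regRna(reg, tgt)
    prot <- .regProtein(reg, tgt)
    tx_src <- if (eff == "activation") bound else dna
    protos <- list(
      .proto(c(tf, dna), bound, TRUE, "tf_binding", src, tgt),
      .proto(tx_src, c(tx_src, rna), FALSE, "transcription", src, tgt),
      .proto(rna, c(rna, prot), FALSE, "translation", NA_character_, tgt)
    )
  }
  protos
}

.protoName <- function(p, reg_tab) {
  nm <- function(ids) {
    if (!length(ids)) return("0")
    paste(reg_tab$name[ids], collapse = " + ")
  }
  paste(nm(p$reactants), if (p$reversible) "<->" else "->", nm(p$products))
}

.systemFromProtos <- function(reg, protos, dialect) {
  el <- .registryTable(reg)
  # drop structurally identical duplicates (same reactants, products, rule):
  # arises when several transcriptional edges target one gene and each
  # re-emits the same translation / free-DNA transcription reaction
  if (length(protos)) {
    keys <- vapply(protos, function(p) {
      paste(paste(p$reactants, collapse = ","),
            paste(p$products, collapse = ","), p$rule, sep = "|")
    }, "")
    protos <- protos[!duplicated(keys)]
  }
  slot <- 0L
  rows <- lapply(seq_along(protos), function(i) {
    p <- protos[[i]]
    kf <- slot + 1L
    kb <- if (p$reversible) slot + 2L else NA_integer_
    slot <<- slot + 1L + as.integer(p$reversible)
    data.frame(
      id = i, name = .protoName(p, el),
      reactants = I(list(p$reactants)), products = I(list(p$products)),
      reversible = p$reversible, rate_law = p$rate_law, hill_n = p$hill_n,
      kf = kf, kb = kb, rule = p$rule, src = p$src, tgt = p$tgt,
      stringsAsFactors = FALSE
    )
  })
  rx <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = integer(), name = character(),
    reactants = I(list()), products = I(list()),
    reversible = logical(), rate_law = character(), hill_n = numeric(),
    kf = integer(), kb = integer(), rule = character(),
    src = character(), tgt = character(), stringsAsFactors = FALSE
  )
  rownames(rx) <- NULL
  new("ReactionSystem", elements = el, reactions = rx,
      n_parameters = slot, dialect = dialect)
}

.protosFromSystem <- function(sys) {
  rx <- reactionTable(sys)
  lapply(seq_len(nrow(rx)), function(i) {
    .proto(rx$reactants[[i]], rx$products[[i]], rx$reversible[i],
           rx$rule[i], rx$src[i], rx$tgt[i], rx$rate_law[i], rx$hill_n[i])
  })
}

# ---- exported operations ----------------------------------------------

#' Expand one interaction edge into elementary reactions
#'
#' Applies the edge-expansion dictionary to a single edge.  Enzymes and
#' transcription factors participate in their active form as given by the
#' active-mode table, so phosphorylating a target whose active form is
#' phosphorylated produces its active species.
#'
#' @param edge single-row data.frame (or list) with `source`, `target`,
#'   `mechanism`, `effect`.
#' @param modes active-mode table from [inferActiveModes()].
#' @param dialect `"lumped"` (default: one reaction per catalytic edge) or
#'   `"detailed"` (explicit enzyme--substrate complex).
#' @return list with `elements` (registry data.frame) and `reactions`
#'   (reaction data.frame with provisional parameter slots).
#' @export
expandEdge <- function(edge, modes, dialect = c("lumped", "detailed")) {
  dialect <- match.arg(dialect)
  reg <- .newRegistry()
  protos <- .expandEdgeInto(reg, as.list(edge), modes, dialect)
  sys <- .systemFromProtos(reg, protos, dialect)
  list(elements = elementTable(sys), reactions = reactionTable(sys))
}

#' Compile an interaction network into a reaction system
#'
#' Walks the network's edges in canonical order, expands each through the
#' dictionary, merges shared elements, and (by default) applies the
#' housekeeping rules: basal protein synthesis for genes without incoming
#' transcriptional regulation, basal transcription for measured-but-
#' unregulated RNAs, and universal degradation for every element except
#' DNA forms (total DNA stays constant).  Identical input yields a
#' byte-identical serialized system; element and reaction counts are
#' invariant under permutation of the input edge order.
#'
#' @param net an [InteractionNetwork-class].
#' @param modes active-mode table; defaults to [inferActiveModes()] on
#'   `net`.
#' @param dialect edge-expansion dialect, see [expandEdge()].
#' @param measured_rna genes whose RNA is measured; unregulated ones get a
#'   basal transcription reaction so their trajectory is fittable.
#' @param housekeeping logical; set `FALSE` to get the bare edge
#'   expansions.
#' @return a [ReactionSystem-class].
#' @export
compileReactions <- function(net, modes = inferActiveModes(net),
                             dialect = c("lumped", "detailed"),
                             measured_rna = character(),
                             housekeeping = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(is(net, "InteractionNetwork"))
  reg <- .newRegistry()
  for (g in nodeIds(net)) .regProtein(reg, g)  # every node exists as a protein
  e <- edgeTable(net)
  protos <- list()
  for (i in seq_len(nrow(e))) {
    p <- tryCatch(
      .expandEdgeInto(reg, as.list(e[i, ]), modes, dialect),
      error = function(err) {
        stop("while expanding edge ", e$source[i], " -> ", e$target[i],
             " (", e$mechanism[i], "/", e$effect[i], "): ",
             conditionMessage(err), call. = FALSE)
      }
    )
    protos <- c(protos, p)
  }
  sys <- .systemFromProtos(reg, protos, dialect)
  if (housekeeping) sys <- addHousekeeping(sys, net, measured_rna = measured_rna)
  sys
}

#' Add basal synthesis and universal degradation
#'
#' For every gene without an incoming transcriptional-regulation edge, a
#' basal protein synthesis reaction (0 -> protein) is added; for every
#' gene in `measured_rna` without an mRNA element, a basal transcription
#' reaction (0 -> RNA) is added; every element except DNA forms receives
#' one degradation reaction (X -> 0).  Parameter slots are renumbered so
#' each slot is used exactly once.
#'
#' @param sys a compiled [ReactionSystem-class] (no housekeeping yet).
#' @param net the [InteractionNetwork-class] it came from.
#' @param measured_rna genes whose RNA layer is measured.
#' @return a [ReactionSystem-class] including housekeeping reactions.
#' @export
addHousekeeping <- function(sys, net, measured_rna = character()) {
  stopifnot(is(sys, "ReactionSystem"), is(net, "InteractionNetwork"))
  reg <- .registryFromTable(elementTable(sys))
  protos <- .protosFromSystem(sys)
  e <- edgeTable(net)
  regulated <- unique(e$target[e$mechanism == "transcriptional_regulation"])
  for (g in nodeIds(net)) {
    if (!g %in% regulated) {
      protos <- c(protos, list(.proto(
        integer(0), .regProtein(reg, g), FALSE, "basal_synthesis",
        NA_character_, g
      )))
    }
  }
  for (g in normalizeGeneIds(measured_rna)) {
    if (!g %in% regulated) {
      protos <- c(protos, list(.proto(
        integer(0), .regRna(reg, g), FALSE, "basal_transcription",
        NA_character_, g
      )))
    }
  }
  el <- .registryTable(reg)
  for (i in el$id[!el$form %in% DNA_FORMS]) {
    protos <- c(protos, list(.proto(
      i, integer(0), FALSE, "degradation", NA_character_, NA_character_
    )))
  }
  .systemFromProtos(reg, protos, sys@dialect)
}

#' Build the per-layer aggregation matrices
#'
#' A measured biomolecule maps to several elements: its protein row sums
#' the free protein, modified forms, every complex containing it and its
#' DNA-bound transcription-factor form; its phospho row sums
#' phospho-containing forms; its RNA row selects the mRNA element.
#'
#' @param sys a [ReactionSystem-class].
#' @param measured named list with character vectors `protein`, `phospho`,
#'   `rna` of measured biomolecules per layer (missing entries = layer not
#'   measured).
#' @return an [AggregationMatrices-class] with sparse 0/1 matrices whose
#'   row names are the measured gene symbols.
#' @export
buildAggregation <- function(sys, measured) {
  stopifnot(is(sys, "ReactionSystem"))
  el <- elementTable(sys)
  n <- nrow(el)
  rowFor <- function(g, layer) {
    cols <- switch(layer,
      protein = which(vapply(el$genes, function(gs) g %in% gs, TRUE)),
      phospho = which(vapply(el$phospho_genes, function(gs) g %in% gs, TRUE)),
      rna = which(el$form == "rna" & el$gene == g)
    )
    if (!length(cols)) {
      stop("measured ", layer, " biomolecule '", g,
           "' matches no element in the system")
    }
    cols
  }
  mk <- function(layer) {
    genes <- normalizeGeneIds(measured[[layer]] %||% character())
    hits <- lapply(genes, rowFor, layer = layer)
    m <- Matrix::sparseMatrix(
      i = rep(seq_along(genes), lengths(hits)),
      j = unlist(hits, use.names = FALSE) %||% integer(0),
      x = 1, dims = c(length(genes), n)
    )
    rownames(m) <- genes
    methods::as(m, "CsparseMatrix")
  }
  new("AggregationMatrices",
      protein = mk("protein"), phospho = mk("phospho"), rna = mk("rna"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline statistics
#'
#' Node/edge/element/reaction/parameter counts for a compiled system, the
#' step-by-step statistics a modeling report prints.
#'
#' @param net an [InteractionNetwork-class].
#' @param sys the [ReactionSystem-class] compiled from it.
#' @return named list of integer counts.
#' @export
pipelineStats <- function(net, sys) {
  list(
    n_nodes = length(nodeIds(net)),
    n_edges = nrow(edgeTable(net)),
    n_elements = nElements(sys),
    n_reactions = nReactions(sys),
    n_parameters = nParameters(sys)
  )
}
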