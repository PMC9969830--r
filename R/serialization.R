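#' Serialize / deserialize a reaction system as JSON
#'
#' Canonical, deterministic JSON: elements, reactions (with parameter
#' slots and provenance), parameter count and dialect.  Writing the same
#' system twice yields byte-identical files; `readReactionSystem`
#' round-trips losslessly.
#'
#' @param sys a [ReactionSystem-class].
#' @param path output / input file path.
#' @return `readReactionSystem`: a [ReactionSystem-class];
#'   `writeReactionSystem`: invisibly, `path`.
#' @export
writeReactionSystem <- function(sys, path) {
  stopifnot(is(sys, "ReactionSystem"))
  el <- elementTable(sys)
  rx <- reactionTable(sys)
  obj <- list(
    format = "netkin-reaction-system",
    version = 1L,
    dialect = sys@dialect,
    n_parameters = nParameters(sys),
    elements = lapply(seq_len(nrow(el)), function(i) list(
      id = el$id[i], name = el$name[i], form = el$form[i],
      gene = el$gene[i], genes = as.list(el$genes[[i]]),
      phospho_genes = as.list(el$phospho_genes[[i]])
    )),
    reactions = lapply(seq_len(nrow(rx)), function(i) list(
      id = rx$id[i], name = rx$name[i],
      reactants = as.list(rx$reactants[[i]]),
      products = as.list(rx$products[[i]]),
      reversible = rx$reversible[i], rate_law = rx$rate_law[i],
      hill_n = rx$hill_n[i], kf = rx$kf[i], kb = rx$kb[i],
      rule = rx$rule[i], src = rx$src[i], tgt = rx$tgt[i]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeReactionSystem
#' @export
readReactionSystem <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "netkin-reaction-system")) {
    stop("not a serialized reaction system: ", path)
  }
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  el <- do.call(rbind, lapply(obj$elements, function(x) data.frame(
    id = as.integer(x$id), name = x$name, form = x$form,
    gene = chr1(x$gene),
    genes = I(list(as.character(unlist(x$genes)))),
    phospho_genes = I(list(as.character(unlist(x$phospho_genes)))),
    stringsAsFactors = FALSE
  )))
  if (is.null(el)) el <- .registryTable(.newRegistry())
  rxl <- lapply(obj$reactions, function(x) data.frame(
    id = as.integer(x$id), name = x$name,
    reactants = I(list(as.integer(unlist(x$reactants)))),
    products = I(list(as.integer(unlist(x$products)))),
    reversible = isTRUE(x$reversible),
    rate_law = x$rate_law,
    hill_n = if (is.null(x$hill_n)) NA_real_ else as.numeric(x$hill_n),
    kf = as.integer(x$kf),
    kb = if (is.null(x$kb)) NA_integer_ else as.integer(x$kb),
    rule = x$rule, src = chr1(x$src), tgt = chr1(x$tgt),
    stringsAsFactors = FALSE
  ))
  rx <- if (length(rxl)) do.call(rbind, rxl) else
    reactionTable(.systemFromProtos(.newRegistry(), list(), obj$dialect))
  rownames(el) <- NULL
  rownames(rx) <- NULL
  new("ReactionSystem", elements = el, reactions = rx,
      n_parameters = as.integer(obj$n_parameters), dialect = obj$dialect)
}

#' Write / read a parameter vector
#'
#' Plain CSV (`slot`, `value`) so fitted parameters round-trip between
#' pipeline commands.
#'
#' @param K numeric parameter vector.
#' @param path file path.
#' @return `readParameters`: numeric vector.
#' @export
writeParameters <- function(K, path) {
  utils::write.csv(data.frame(slot = seq_along(K), value = K), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeParameters
#' @export
readParameters <- function(path) {
  d <- utils::read.csv(path)
  K <- numeric(max(d$slot))
  K[d$slot] <- d$value
  K
}

#' Serialize aggregation matrices
#'
#' JSON listing, per layer, each measured biomolecule with the element
#' ids its row sums.
#'
#' @param agg an [AggregationMatrices-class].
#' @param path output path.
#' @export
writeAggregation <- function(agg, path) {
  lay <- function(C) {
    lapply(rownames(C), function(g) {
      list(gene = g, elements = as.list(unname(which(C[g, ] != 0))))
    })
  }
  jsonlite::write_json(
    list(format = "netkin-aggregation",
         protein = lay(agg@protein), phospho = lay(agg@phospho),
         rna = lay(agg@rna)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
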