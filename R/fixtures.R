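#' Specification of a synthetic study design
#'
#' Defines a toy interaction network and the experimental design its
#' synthetic data emulate: triplicate measurements of the protein,
#' phospho and RNA layers at 0/2/6/24/48 h, with multiplicative
#' (lognormal) noise so concentrations stay positive, and drug-like
#' perturbation conditions implemented as knock-downs of the catalytic
#' rates of target kinases.
#'
#' @param n_genes number of genes available to the network generator.
#' @param mechanisms named integer vector of edge counts per mechanism.
#' @param k_bounds log-uniform bounds for the true rate constants
#'   (per hour; concentrations in copies per microliter).
#' @param cv named per-layer coefficient of variation of the replicate
#'   noise.
#' @param times sampling time grid in hours.
#' @param replicates biological replicates per measurement.
#' @param protein_abundance,rna_abundance median time-zero abundances
#'   (copies per microliter).
#' @param seed integer seed; everything downstream is reproducible from
#'   it.
#' @return a list of class `"FixtureSpec"`.
#' @export
fixtureSpec <- function(n_genes = 4,
                        mechanisms = c(phosphorylation = 1,
                                       dephosphorylation = 1,
                                       ubiquitination = 0,
                                       binding = 1,
                                       transcriptional_regulation = 1),
                        k_bounds = c(1e-3, 1),
                        cv = c(protein = 0.1, phospho = 0.1, rna = 0.1),
                        times = c(0, 2, 6, 24, 48),
                        replicates = 3,
                        protein_abundance = 50,
                        rna_abundance = 2,
                        seed = 1L) {
  mech <- setNames(rep(0L, length(SUPPORTED_MECHANISMS)), SUPPORTED_MECHANISMS)
  mech[names(mechanisms)] <- as.integer(mechanisms)
  if (any(mech < 0) || sum(mech) < 1) stop("mechanism counts must be >= 0 with at least one edge")
  if (n_genes < 2) stop("need at least two genes")
  if (length(times) < 2 || any(diff(times) <= 0)) stop("times must be increasing")
  if (replicates < 1) stop("need at least one replicate")
  directed_pairs <- n_genes * (n_genes - 1)
  if (any(mech[names(mech) != "binding"] > directed_pairs) ||
      mech[["binding"]] > directed_pairs / 2) {
    stop("infeasible mechanism mix: more edges requested than node pairs")
  }
  structure(list(
    n_genes = as.integer(n_genes), mechanisms = mech,
    k_bounds = k_bounds, cv = cv, times = times,
    replicates = as.integer(replicates),
    protein_abundance = protein_abundance, rna_abundance = rna_abundance,
    seed = as.integer(seed)
  ), class = "FixtureSpec")
}

#' Preset fixture sizes
#'
#' `smallFixtureSpec`: 4 genes, one edge of most mechanisms, used for
#' unit tests.  `mediumFixtureSpec`: 10 genes, 15 edges, roughly 60
#' parameters, used for parameter-recovery studies.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [fixtureSpec()].
#' @return a `"FixtureSpec"`.
#' @export
smallFixtureSpec <- function(seed = 1L, ...) {
  fixtureSpec(seed = seed, ...)
}

#' @rdname smallFixtureSpec
#' @export
mediumFixtureSpec <- function(seed = 1L, ...) {
  fixtureSpec(
    n_genes = 10,
    mechanisms = c(phosphorylation = 6, dephosphorylation = 2,
                   ubiquitination = 1, binding = 4,
                   transcriptional_regulation = 2),
    seed = seed, ...
  )
}

#' Generate a toy interaction network
#'
#' Seeded generator emitting exactly the requested number of edges per
#' mechanism.  The first two modification edges share a substrate (the
#' shared-element motif every compiler test needs), new edges attach to
#' already-used genes so the emitted network is connected, and the node
#' set is the set of genes touched by edges.
#'
#' @param spec a [fixtureSpec()].
#' @return an [InteractionNetwork-class].
#' @export
makeToyNetwork <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  genes <- sprintf("G%02d", seq_len(spec$n_genes))
  mech_order <- c("phosphorylation", "dephosphorylation", "ubiquitination",
                  "binding", "transcriptional_regulation")
  wanted <- rep(mech_order, spec$mechanisms[mech_order])
  used <- character(0)
  taken <- character(0)  # src|tgt|mech keys (binding symmetrized)
  edges <- list()
  keyOf <- function(s, t, m) {
    if (m == "binding" && s > t) paste(t, s, m, sep = "|") else paste(s, t, m, sep = "|")
  }
  pickPair <- function(m) {
    for (try in 1:500) {
      s <- if (length(used)) sample(used, 1) else sample(genes, 1)
      fresh <- setdiff(genes, used)
      t <- if (length(fresh)) sample(fresh, 1) else sample(setdiff(genes, s), 1)
      if (s == t) next
      if (!keyOf(s, t, m) %in% taken) return(c(s, t))
    }
    # fall back to exhaustive scan over all ordered pairs
    for (s in genes) for (t in genes) {
      if (s != t && !keyOf(s, t, m) %in% taken) return(c(s, t))
    }
    stop("could not place a '", m, "' edge: pair space exhausted")
  }
  shared_target <- NULL
  n_mod_placed <- 0L
  for (m in wanted) {
    if (m %in% MODIFICATION_MECHANISMS && n_mod_placed < 2L &&
        sum(spec$mechanisms[MODIFICATION_MECHANISMS]) >= 2L) {
      # first two modification edges share their substrate
      if (is.null(shared_target)) {
        pr <- pickPair(m)
        shared_target <- pr[2]
      } else {
        cand <- sample(setdiff(genes, shared_target))
        free <- cand[!vapply(cand, function(s)
          keyOf(s, shared_target, m) %in% taken, TRUE)]
        pr <- if (length(free)) c(free[1], shared_target) else pickPair(m)
      }
      n_mod_placed <- n_mod_placed + 1L
    } else {
      pr <- pickPair(m)
    }
    eff <- sample(c("activation", "inhibition"), 1, prob = c(0.7, 0.3))
    taken <- c(taken, keyOf(pr[1], pr[2], m))
    used <- unique(c(used, pr))
    edges[[length(edges) + 1L]] <- data.frame(
      source = pr[1], target = pr[2], mechanism = m, effect = eff,
      evidence = sprintf("SYN%04d", length(edges) + 1L),
      stringsAsFactors = FALSE
    )
  }
  interactionNetwork(nodes = used, edges = do.call(rbind, edges))
}

.lnormNoise <- function(y, cv, n) {
  if (cv <= 0 || y <= 0) return(rep(y, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(y) - s^2 / 2, sdlog = s)
}

#' Generate ground-truth parameters and noisy multi-layer data
#'
#' Compiles the network, samples a true parameter vector (log-uniform in
#' the spec's bounds), builds the true initial state (proteins at
#' lognormal abundances split 30/70 between phospho and unmodified
#' forms, RNAs of regulated genes at lognormal abundances, DNA at two
#' copies per 8 ul), simulates every condition, and samples replicates
#' as lognormal noise around the simulated values.  The phospho layer is
#' emitted as relative intensities (a random per-biomolecule scale) so
#' the mean-normalized scoring branch is exercised.  If a sampled
#' parameter set fails to simulate, a fresh set is drawn (bounded
#' retries).
#'
#' Conditions: a control plus one knock-down per major kinase (the two
#' phosphorylation sources with the highest out-degree), with a held-out
#' double knock-down when two kinases exist.
#'
#' @param net an [InteractionNetwork-class] (from [makeToyNetwork()]).
#' @param spec the [fixtureSpec()] used to generate it.
#' @param max_retries resampling attempts for the true parameters.
#' @return list with the network, active `modes`, compiled `system`,
#'   `model`, `agg`, `measured` lists, `conditions` (incl. a `holdout`
#'   flag), `k_true`, `x0_true`, and the noisy `dataset`
#'   (an [ExperimentalDataset-class]).
#' @export
makeTruthAndData <- function(net, spec, max_retries = 5L) {
  stopifnot(is(net, "InteractionNetwork"), inherits(spec, "FixtureSpec"))
  set.seed(spec$seed + 1L)
  modes <- suppressWarnings(inferActiveModes(net))
  e <- edgeTable(net)
  regulated <- sort(unique(e$target[e$mechanism == "transcriptional_regulation"]))
  sys <- compileReactions(net, modes, measured_rna = regulated)
  el <- elementTable(sys)
  measured <- list(
    protein = sort(nodeIds(net)),
    phospho = sort(unique(el$gene[el$form == "phospho_protein"])),
    rna = regulated
  )
  agg <- buildAggregation(sys, measured)
  model <- buildOdeModel(sys)

  ktab <- table(e$source[e$mechanism == "phosphorylation"])
  kin <- names(ktab)[order(-as.integer(ktab), names(ktab))]
  conditions <- list(list(name = "control", targets = character(0),
                          factor = 1, holdout = FALSE))
  if (length(kin) >= 1) {
    conditions <- c(conditions, list(list(
      name = paste0(kin[1], "_i"), targets = kin[1], factor = 0,
      holdout = FALSE)))
  }
  if (length(kin) >= 2) {
    conditions <- c(conditions, list(
      list(name = paste0(kin[2], "_i"), targets = kin[2], factor = 0,
           holdout = FALSE),
      list(name = "combo_i", targets = kin[1:2], factor = 0, holdout = TRUE)
    ))
  }

  # true initial state
  x0 <- numeric(nrow(el))
  for (g in measured$protein) {
    total <- stats::rlnorm(1, log(spec$protein_abundance), 0.4)
    iu <- which(el$form == "protein" & el$gene == g)
    ip <- which(el$form == "phospho_protein" & el$gene == g)
    if (length(ip)) {
      x0[ip] <- 0.30 * total
      x0[iu] <- 0.70 * total
    } else {
      x0[iu] <- total
    }
  }
  for (g in measured$rna) {
    x0[which(el$form == "rna" & el$gene == g)] <-
      stats::rlnorm(1, log(spec$rna_abundance), 0.4)
  }
  x0[el$form == "dna_free"] <- 2 / 8
  names(x0) <- el$name

  trajs <- NULL
  k_true <- NULL
  for (attempt in seq_len(max_retries)) {
    K <- 10^stats::runif(nParameters(sys), log10(spec$k_bounds[1]),
                         log10(spec$k_bounds[2]))
    trajs <- tryCatch({
      lapply(conditions, function(cond) {
        simulateModel(model, x0, spec$times,
                      applyCondition(K, sys, cond))
      })
    }, error = function(err) NULL)
    if (!is.null(trajs)) {
      k_true <- K
      break
    }
  }
  if (is.null(trajs)) {
    stop("could not simulate a valid truth in ", max_retries, " attempts")
  }
  names(trajs) <- vapply(conditions, function(c) c$name, "")

  rows <- list()
  phospho_scale <- setNames(stats::runif(length(measured$phospho), 0.5, 2),
                            measured$phospho)
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    Y <- aggregateOutputs(trajs[[ci]], agg)
    for (layer in DATA_LAYERS) {
      if (is.null(Y[[layer]])) next
      ylayer <- Y[[layer]]
      for (g in rownames(ylayer)) {
        scale <- if (layer == "phospho") phospho_scale[[g]] else 1
        for (j in seq_along(spec$times)) {
          vals <- .lnormNoise(scale * ylayer[g, j], spec$cv[[layer]],
                              spec$replicates)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, layer = layer, condition = cond$name,
            time_h = spec$times[j], replicate = seq_len(spec$replicates),
            value = vals, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  dataset <- experimentalDataset(do.call(rbind, rows))
  list(network = net, modes = modes, system = sys, model = model,
       agg = agg, measured = measured, conditions = conditions,
       k_true = k_true, x0_true = x0, trajectories = trajs,
       dataset = dataset, spec = spec)
}

#' One-call fixture
#'
#' @param spec a [fixtureSpec()].
#' @param ... passed to [makeTruthAndData()].
#' @return see [makeTruthAndData()].
#' @export
makeFixture <- function(spec, ...) {
  makeTruthAndData(makeToyNetwork(spec), spec, ...)
}

#' Write fixture files to disk
#'
#' Emits the SIGNOR-dialect snapshot TSV, the gene list, the tidy
#' expression CSV and a manifest JSON recording seed and spec, i.e. the
#' exact files the readers of the other modules consume.
#'
#' @param fix a fixture from [makeTruthAndData()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeFixtureFiles <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    snapshot = file.path(dir, "snapshot.tsv"),
    genes = file.path(dir, "genes.txt"),
    expression = file.path(dir, "expression.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  e <- edgeTable(fix$network)
  snap <- data.frame(
    ENTITYA = e$source, ENTITYB = e$target,
    EFFECT = ifelse(e$effect == "activation", "up-regulates",
                    "down-regulates"),
    MECHANISM = gsub("_", " ", e$mechanism),
    DIRECT = "YES", PMID = e$evidence,
    stringsAsFactors = FALSE
  )
  utils::write.table(snap, paths[["snapshot"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(nodeIds(fix$network), paths[["genes"]])
  writeExpressionTable(fix$dataset, paths[["expression"]])
  manifest <- list(
    seed = fix$spec$seed,
    spec = fix$spec[setdiff(names(fix$spec), "seed")],
    conditions = fix$conditions,
    n_parameters = nParameters(fix$system)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
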