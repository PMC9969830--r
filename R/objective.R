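#' Construct a replicate time-course dataset
#'
#' @param data data.frame with columns `gene`, `layer` (`protein`,
#'   `phospho`, `rna`), `condition`, `time_h`, `replicate`, `value`.
#' @param absolute named logical: which layers are absolute
#'   concentrations.  The default matches the usual situation: protein and
#'   RNA absolute, phospho relative intensities.
#' @return an [ExperimentalDataset-class].
#' @export
experimentalDataset <- function(data,
                                absolute = c(protein = TRUE, phospho = FALSE,
                                             rna = TRUE)) {
  data$gene <- normalizeGeneIds(data$gene)
  data <- data[order(data$condition, data$layer, data$gene, data$time_h,
                     data$replicate), , drop = FALSE]
  rownames(data) <- NULL
  new("ExperimentalDataset", data = data, absolute = absolute)
}

#' Read / write the tidy expression table
#'
#' CSV with columns `gene`, `layer`, `condition`, `time_h`, `replicate`,
#' `value`.
#'
#' @param path file path.
#' @param absolute passed to [experimentalDataset()].
#' @return `readExpressionTable`: an [ExperimentalDataset-class].
#' @export
readExpressionTable <- function(path, absolute = c(protein = TRUE,
                                                   phospho = FALSE,
                                                   rna = TRUE)) {
  experimentalDataset(utils::read.csv(path, stringsAsFactors = FALSE),
                      absolute = absolute)
}

#' @rdname readExpressionTable
#' @param dataset an [ExperimentalDataset-class].
#' @export
writeExpressionTable <- function(dataset, path) {
  utils::write.csv(datasetTable(dataset), path, row.names = FALSE)
}

#' Replicate array for one condition and layer
#'
#' @param dataset an [ExperimentalDataset-class].
#' @param condition condition name.
#' @param layer one of `"protein"`, `"phospho"`, `"rna"`.
#' @return 3-d array gene x time x replicate (NA for missing cells), with
#'   dimnames.
#' @export
replicateArray <- function(dataset, condition, layer) {
  d <- datasetTable(dataset)
  d <- d[d$condition == condition & d$layer == layer, , drop = FALSE]
  genes <- sort(unique(d$gene))
  times <- sort(unique(d$time_h))
  reps <- sort(unique(d$replicate))
  arr <- array(NA_real_, dim = c(length(genes), length(times), length(reps)),
               dimnames = list(genes, as.character(times), as.character(reps)))
  if (nrow(d)) {
    arr[cbind(match(d$gene, genes), match(d$time_h, times),
              match(d$replicate, reps))] <- d$value
  }
  arr
}

#' Initial model state from time-zero measurements
#'
#' Builds the initial concentration vector: each measured protein's
#' time-zero total T is split `split` / `1 - split` between its
#' phosphorylated and unmodified forms (all of T goes to the unmodified
#' form when the gene has no phospho element); complexes and bound forms
#' start at zero; measured RNAs take their time-zero value (divided by
#' the cell volume when given as counts); free DNA of every regulated
#' gene starts at two copies per cell volume with the bound form at zero;
#' unmeasured elements start at zero.
#'
#' @param dataset an [ExperimentalDataset-class] with time-0 measurements.
#' @param sys the [ReactionSystem-class].
#' @param condition condition whose time-0 data to use.
#' @param split fraction of total protein in the phosphorylated form at
#'   time zero (default 0.30).
#' @param cell_volume_ul cell volume in microliters (default 8).
#' @param rna_as_counts when TRUE, RNA values are copy counts and are
#'   divided by `cell_volume_ul`.
#' @return named numeric state vector (element display names).
#' @export
initialState <- function(dataset, sys, condition,
                         split = 0.30, cell_volume_ul = 8,
                         rna_as_counts = FALSE) {
  stopifnot(is(dataset, "ExperimentalDataset"), is(sys, "ReactionSystem"))
  el <- elementTable(sys)
  x0 <- numeric(nrow(el))
  d <- datasetTable(dataset)
  d <- d[d$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("no data for condition '", condition, "'")
  t0 <- min(d$time_h)

  prot <- d[d$layer == "protein", , drop = FALSE]
  for (g in unique(prot$gene)) {
    v <- prot$value[prot$gene == g & prot$time_h == t0]
    if (!length(v)) {
      stop("missing time-0 protein measurement for gene '", g, "'")
    }
    total <- mean(v)
    iu <- which(el$form == "protein" & el$gene == g)
    ip <- which(el$form == "phospho_protein" & el$gene == g)
    if (!length(iu)) {
      stop("measured protein '", g, "' has no element in the system")
    }
    if (length(ip)) {
      x0[ip] <- split * total
      x0[iu] <- (1 - split) * total
    } else {
      x0[iu] <- total
    }
  }

  rna <- d[d$layer == "rna", , drop = FALSE]
  for (g in unique(rna$gene)) {
    v <- rna$value[rna$gene == g & rna$time_h == t0]
    if (!length(v)) next
    ir <- which(el$form == "rna" & el$gene == g)
    if (!length(ir)) {
      warning("measured RNA '", g, "' has no element in the system; skipped")
      next
    }
    x0[ir] <- mean(v) / (if (rna_as_counts) cell_volume_ul else 1)
  }

  x0[el$form == "dna_free"] <- 2 / cell_volume_ul
  names(x0) <- el$name
  x0
}

#' Aggregate simulated states into measured-biomolecule series
#'
#' `Y_layer(t) = C_layer %*% X(t)` for each sampled time point.
#'
#' @param traj a [Trajectory-class].
#' @param agg an [AggregationMatrices-class].
#' @return named list of matrices (gene x time) for each nonempty layer.
#' @export
aggregateOutputs <- function(traj, agg) {
  st <- t(trajectoryStates(traj))
  out <- list()
  for (layer in DATA_LAYERS) {
    C <- slot(agg, layer)
    if (nrow(C)) {
      y <- as.matrix(C %*% st)
      colnames(y) <- as.character(trajectoryTimes(traj))
      out[[layer]] <- y
    }
  }
  out
}

#' Mean-normalize a series over its time points
#'
#' Divides each value by the series mean so the normalized series has
#' mean one.  Idempotent; errors on a non-positive mean (a flat-zero
#' series cannot be normalized).
#'
#' @param x numeric series.
#' @return normalized series.
#' @export
meanNormalize <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("cannot mean-normalize: series mean <= 0")
  x / m
}

#' Replicate-band indicator
#'
#' `alpha = sgn((y - max(reps)) * (y - min(reps))) / 2 + 1/2`: 0 when the
#' simulated value lies strictly inside the replicate min-max band (the
#' residual is then ignored), 1 strictly outside, and 0.5 exactly on a
#' band boundary (literal sgn(0) = 0).
#'
#' @param y simulated value (scalar or vector).
#' @param reps replicate measurements (at one time point).
#' @return value(s) in {0, 0.5, 1}.
#' @export
alphaIndicator <- function(y, reps) {
  reps <- reps[!is.na(reps)]
  if (!length(reps)) stop("alphaIndicator needs at least one replicate")
  0.5 * sign((y - max(reps)) * (y - min(reps))) + 0.5
}

# Precompute everything about the data side of a layer score so repeated
# evaluations during fitting only touch the simulation side.
.prepLayer <- function(E, mode) {
  genes <- dimnames(E)[[1]]
  nt <- dim(E)[2]
  if (mode == "mean_normalized") {
    for (i in seq_along(genes)) {
      for (r in seq_len(dim(E)[3])) {
        s <- E[i, , r]
        if (all(is.na(s))) next
        m <- mean(s, na.rm = TRUE)
        E[i, , r] <- if (m > 0) s / m else NA_real_
      }
    }
  }
  repmean <- apply(E, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  lo <- apply(E, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  hi <- apply(E, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  nobs <- apply(E, c(1, 2), function(v) sum(!is.na(v)))
  etilde <- rowMeans(repmean, na.rm = TRUE)
  skip <- rep(FALSE, length(genes))
  if (mode == "absolute") {
    skip <- !is.finite(etilde) | etilde == 0
  }
  list(genes = genes, times = dimnames(E)[[2]], mode = mode,
       repmean = repmean, lo = lo, hi = hi, nobs = nobs,
       etilde = etilde, skip = skip)
}

.scoreLayer <- function(Y, prep) {
  genes <- prep$genes
  missing <- setdiff(genes, rownames(Y))
  if (length(missing)) {
    stop("simulated output missing for: ", paste(missing, collapse = ", "))
  }
  tm <- match(prep$times, colnames(Y))
  if (anyNA(tm)) stop("simulated output missing data time points")
  S <- 0
  n_cells <- 0L
  n_obs <- 0L
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    if (prep$skip[i]) next
    y <- Y[genes[i], tm]
    if (prep$mode == "mean_normalized") {
      my <- mean(y)
      y <- if (my > .Machine$double.eps) y / my else rep(0, length(y))
    }
    ok <- !is.na(prep$repmean[i, ])
    if (!any(ok)) next
    a <- 0.5 * sign((y - prep$hi[i, ]) * (y - prep$lo[i, ])) + 0.5
    d <- y - prep$repmean[i, ]
    contrib <- if (prep$mode == "absolute") {
      a * (d / prep$etilde[i])^2
    } else {
      a * d^2
    }
    contrib[!ok] <- NA_real_
    S <- S + sum(contrib[ok])
    n_cells <- n_cells + sum(ok)
    n_obs <- n_obs + sum(prep$nobs[i, ok])
    res[[i]] <- data.frame(
      gene = genes[i], time_h = as.numeric(prep$times),
      y = unname(y), alpha = unname(a), residual = unname(d),
      contribution = unname(contrib), stringsAsFactors = FALSE
    )
  }
  residuals <- if (any(!vapply(res, is.null, TRUE))) {
    do.call(rbind, res[!vapply(res, is.null, TRUE)])
  } else {
    data.frame(gene = character(), time_h = numeric(), y = numeric(),
               alpha = numeric(), residual = numeric(),
               contribution = numeric(), stringsAsFactors = FALSE)
  }
  skipped <- genes[prep$skip]
  if (length(skipped)) {
    warning("skipped biomolecule(s) with zero mean concentration: ",
            paste(skipped, collapse = ", "))
  }
  list(S = S, n_cells = n_cells, n_obs = n_obs, residuals = residuals)
}

#' Band-gated layer objective
#'
#' Sum over biomolecules and time points of `alpha * residual^2`.  In
#' `absolute` mode (protein, RNA) the residual is the difference between
#' the simulated value and the replicate mean, scaled by the biomolecule's
#' time-averaged mean concentration (so the score is invariant under
#' joint rescaling of simulation and data); biomolecules with zero mean
#' are skipped with a warning.  In `mean_normalized` mode (phospho) each
#' replicate series and the simulated series are first normalized to mean
#' one and the residual is used unscaled.  Cells with no measurement are
#' excluded from the sums and the effective counts.
#'
#' @param Y simulated layer matrix (gene x time, dimnames required).
#' @param E replicate array gene x time x replicate
#'   (see [replicateArray()]).
#' @param mode `"absolute"` or `"mean_normalized"`.
#' @return list with `S`, effective `n_cells`, `n_obs`, and a
#'   per-(biomolecule, time) `residuals` table.
#' @export
layerObjective <- function(Y, E, mode = c("absolute", "mean_normalized")) {
  mode <- match.arg(mode)
  .scoreLayer(Y, .prepLayer(E, mode))
}

#' Combine layer objectives
#'
#' `Stotal = Sp + Sph + SRNA` (absent layers contribute 0), plus the
#' summary `Psi = sqrt(Stotal) / N` where N is the total number of
#' replicate measurements behind the score (biomolecules x time points x
#' replicates when the design is balanced).
#'
#' @param protein,phospho,rna layer results from [layerObjective()], or
#'   NULL for an absent layer.
#' @return an [ObjectiveReport-class].
#' @export
totalObjective <- function(protein = NULL, phospho = NULL, rna = NULL) {
  pick <- function(r, f) if (is.null(r)) 0 else r[[f]]
  sp <- pick(protein, "S"); sph <- pick(phospho, "S"); srna <- pick(rna, "S")
  stotal <- sp + sph + srna
  n_cells <- as.integer(pick(protein, "n_cells") + pick(phospho, "n_cells") +
                          pick(rna, "n_cells"))
  n_obs <- as.integer(pick(protein, "n_obs") + pick(phospho, "n_obs") +
                        pick(rna, "n_obs"))
  psi <- if (n_obs > 0) sqrt(stotal) / n_obs else 0
  res <- list(protein = protein, phospho = phospho, rna = rna)
  tabs <- lapply(names(res), function(l) {
    if (is.null(res[[l]]) || !nrow(res[[l]]$residuals)) return(NULL)
    cbind(layer = l, res[[l]]$residuals, stringsAsFactors = FALSE)
  })
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  residuals <- if (length(tabs)) do.call(rbind, tabs) else data.frame(
    layer = character(), gene = character(), time_h = numeric(),
    y = numeric(), alpha = numeric(), residual = numeric(),
    contribution = numeric(), stringsAsFactors = FALSE
  )
  new("ObjectiveReport", sp = sp, sph = sph, srna = srna, stotal = stotal,
      psi = psi, n_cells = n_cells, n_obs = n_obs, residuals = residuals)
}

#' Fit summary Psi
#'
#' `Psi = sqrt(Stotal) / (m * n * r)`: the square root of the total
#' band-gated sum of squares divided by the number of replicate
#' measurements (m biomolecules, n time points, r replicates).
#'
#' @param stotal nonnegative total objective value.
#' @param n_biomolecules,n_times,n_replicates positive counts.
#' @return scalar Psi.
#' @export
#' @examples
#' psiSummary(2.72e7, 768, 5, 3)  # ~0.45
#' psiSummary(1.13e6, 768, 5, 3)  # ~0.09
psiSummary <- function(stotal, n_biomolecules, n_times, n_replicates) {
  if (stotal < 0) stop("stotal must be nonnegative")
  if (n_biomolecules <= 0 || n_times <= 0 || n_replicates <= 0) {
    stop("counts must be positive")
  }
  sqrt(stotal) / (n_biomolecules * n_times * n_replicates)
}

#' Score a full condition
#'
#' Convenience wrapper: simulate the condition, aggregate outputs, score
#' every measured layer with the appropriate mode and combine.
#'
#' @param model an [OdeModel-class].
#' @param sys its [ReactionSystem-class].
#' @param agg an [AggregationMatrices-class].
#' @param dataset an [ExperimentalDataset-class].
#' @param condition condition name.
#' @param K parameter vector (after any condition adjustment).
#' @param x0 optional initial state; defaults to
#'   [initialState()] from the condition's time-0 data.
#' @param ... passed to [simulateModel()].
#' @return an [ObjectiveReport-class].
#' @export
scoreCondition <- function(model, sys, agg, dataset, condition, K,
                           x0 = NULL, ...) {
  d <- datasetTable(dataset)
  d <- d[d$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("no data for condition '", condition, "'")
  times <- sort(unique(d$time_h))
  if (is.null(x0)) x0 <- initialState(dataset, sys, condition)
  traj <- simulateModel(model, x0, times, K, ...)
  Y <- aggregateOutputs(traj, agg)
  reports <- list(protein = NULL, phospho = NULL, rna = NULL)
  for (layer in DATA_LAYERS) {
    E <- replicateArray(dataset, condition, layer)
    if (!dim(E)[1] || is.null(Y[[layer]])) next
    mode <- if (dataset@absolute[[layer]]) "absolute" else "mean_normalized"
    reports[[layer]] <- layerObjective(Y[[layer]], E, mode)
  }
  totalObjective(protein = reports$protein, phospho = reports$phospho,
                 rna = reports$rna)
}

#' Flat-line baseline objective
#'
#' No-information predictor holding every biomolecule at its time-zero
#' replicate mean; its score is the reference a dynamic prediction must
#' beat.
#'
#' @param dataset an [ExperimentalDataset-class].
#' @param condition condition name.
#' @return an [ObjectiveReport-class].
#' @export
baselineObjective <- function(dataset, condition) {
  reports <- list(protein = NULL, phospho = NULL, rna = NULL)
  for (layer in DATA_LAYERS) {
    E <- replicateArray(dataset, condition, layer)
    if (!dim(E)[1]) next
    repmean0 <- apply(E[, 1, , drop = FALSE], 1, mean, na.rm = TRUE)
    Y <- matrix(rep(repmean0, dim(E)[2]), nrow = dim(E)[1],
                dimnames = dimnames(E)[1:2])
    mode <- if (dataset@absolute[[layer]]) "absolute" else "mean_normalized"
    reports[[layer]] <- layerObjective(Y, E, mode)
  }
  totalObjective(protein = reports$protein, phospho = reports$phospho,
                 rna = reports$rna)
}
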