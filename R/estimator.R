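#' Group parameters by state-variable equation
#'
#' One group per state variable: a parameter slot belongs to the group of
#' state `x_i` when its reaction has a nonzero net stoichiometry entry for
#' `x_i` or `x_i` appears in that reaction's rate product (catalysts, and
#' products of reversible reactions).  Groups may overlap; empty groups
#' are dropped.
#'
#' @param model an [OdeModel-class].
#' @return data.frame with columns `element` (state index), `name`,
#'   `repetition` (number of reactions involving the state) and
#'   list-column `slots` (parameter slot indices).
#' @export
groupParameters <- function(model) {
  stopifnot(is(model, "OdeModel"))
  n <- model@n
  Hd <- as.matrix(model@H) != 0
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    inH <- which(Hd[i, ])
    inR <- which(rowSums(model@XR == i) > 0)
    inPrev <- which(model@kb_idx > 0L & rowSums(model@XP == i) > 0)
    rx <- sort(unique(c(inH, inR, inPrev)))
    if (!length(rx)) next
    slots <- sort(unique(c(model@kf_idx[rx],
                           model@kb_idx[rx][model@kb_idx[rx] > 0L])))
    rows[[i]] <- data.frame(
      element = i, name = model@element_names[i],
      repetition = length(rx), slots = I(list(slots)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Order parameter groups into an optimization schedule
#'
#' State variables are ranked by how many reactions involve them (a
#' measure of their influence on the whole system) and visited from most
#' to least frequent; ties break by ascending state index, so the
#' schedule is deterministic and independent of reaction order.
#'
#' @param groups output of [groupParameters()].
#' @return the same data.frame sorted into schedule order, with a `rank`
#'   column.
#' @export
buildSchedule <- function(groups) {
  ord <- order(-groups$repetition, groups$element)
  out <- groups[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Optimize one parameter group with Nelder-Mead
#'
#' Runs a derivative-free simplex search over only the group's slots
#' (all other parameters frozen, bit-identical before and after), in
#' log10 parameter space to enforce positivity and span scales.  A trial
#' point whose simulation fails scores a large penalty and the search
#' continues.  The better of the incumbent and the candidate is
#' returned, so the objective never increases.
#'
#' @param objfn function(K) -> scalar objective (e.g. summed Stotal over
#'   training conditions).
#' @param K current full parameter vector (finite, positive).
#' @param slots integer indices of the group's parameter slots.
#' @param budget maximum simplex iterations (default 200 x group size);
#'   0 is a no-op.
#' @param reltol relative convergence tolerance of the simplex.
#' @return list with updated `K`, objective `value`, and `evaluations`
#'   used.
#' @export
optimizeGroup <- function(objfn, K, slots, budget = 200L * length(slots),
                          reltol = 1e-4) {
  stopifnot(all(is.finite(K)), all(K > 0))
  incumbent <- objfn(K)
  if (budget <= 0L || !length(slots)) {
    return(list(K = K, value = incumbent, evaluations = 0L))
  }
  evals <- 0L
  wrapped <- function(theta) {
    evals <<- evals + 1L
    K2 <- K
    K2[slots] <- 10^theta
    val <- tryCatch(objfn(K2), error = function(e) Inf)
    if (!is.finite(val)) 1e300 else val
  }
  fit <- stats::optim(
    par = log10(K[slots]), fn = wrapped, method = "Nelder-Mead",
    control = list(maxit = as.integer(budget), reltol = reltol,
                   warn.1d.NelderMead = FALSE)
  )
  if (is.finite(fit$value) && fit$value < incumbent) {
    K[slots] <- 10^fit$par
    incumbent <- fit$value
  }
  list(K = K, value = incumbent, evaluations = evals)
}

#' Apply a condition (intervention) to a parameter vector
#'
#' A condition multiplies the forward constants of the catalytic
#' reactions (phosphorylation, dephosphorylation, ubiquitination)
#' catalyzed by its target genes by an inhibition factor (0 = complete
#' knock-down).
#'
#' @param K parameter vector.
#' @param sys the [ReactionSystem-class].
#' @param condition list with `targets` (character, possibly empty) and
#'   `factor` (numeric).  Unknown list entries are rejected.
#' @return adjusted parameter vector.
#' @export
applyCondition <- function(K, sys, condition) {
  known <- c("name", "targets", "factor", "holdout")
  extra <- setdiff(names(condition), known)
  if (length(extra)) {
    stop("unknown condition spec key(s): ", paste(extra, collapse = ", "))
  }
  targets <- normalizeGeneIds(condition$targets %||% character())
  if (!length(targets)) return(K)
  fac <- condition$factor %||% 0
  rx <- reactionTable(sys)
  hit <- rx$rule %in% CATALYTIC_MECHANISMS & rx$src %in% targets
  K[rx$kf[hit]] <- K[rx$kf[hit]] * fac
  K
}

# Shared machinery: an objective closure summing Stotal over the training
# conditions, with the data side (initial states, replicate bands,
# normalizations) precomputed once.
.makeObjective <- function(model, sys, agg, dataset, conditions,
                           rtol = 1e-6, atol = 1e-9) {
  prep <- lapply(conditions, function(cond) {
    d <- datasetTable(dataset)
    d <- d[d$condition == cond$name, , drop = FALSE]
    if (!nrow(d)) stop("no data for condition '", cond$name, "'")
    times <- sort(unique(d$time_h))
    x0 <- initialState(dataset, sys, cond$name)
    layers <- list()
    n_obs <- 0L
    for (layer in DATA_LAYERS) {
      E <- replicateArray(dataset, cond$name, layer)
      if (!dim(E)[1]) next
      mode <- if (dataset@absolute[[layer]]) "absolute" else "mean_normalized"
      p <- .prepLayer(E, mode)
      layers[[layer]] <- p
      n_obs <- n_obs + sum(p$nobs[!p$skip, , drop = FALSE])
    }
    list(cond = cond, times = times, x0 = x0, layers = layers, n_obs = n_obs)
  })
  n_obs_total <- sum(vapply(prep, function(p) p$n_obs, 1))
  evaluate <- function(K) {
    total <- 0
    for (p in prep) {
      Kc <- applyCondition(K, sys, p$cond)
      traj <- simulateModel(model, p$x0, p$times, Kc,
                            rtol = rtol, atol = atol)
      Y <- aggregateOutputs(traj, agg)
      for (layer in names(p$layers)) {
        sc <- suppressWarnings(.scoreLayer(Y[[layer]], p$layers[[layer]]))
        total <- total + sc$S
      }
    }
    total
  }
  attr(evaluate, "n_obs") <- n_obs_total
  evaluate
}

#' Fit kinetic parameters by cyclic group-wise Nelder-Mead
#'
#' The block-coordinate estimator: parameters are grouped by
#' state-variable equation, groups are ranked by how often their state
#' appears across reactions, and a Nelder-Mead simplex repeatedly
#' optimizes each group (all other parameters frozen) from the most to
#' the least connected state.  After the last group a new cycle starts;
#' fitting stops when the relative improvement of the summed training
#' objective over a full cycle drops below `cycle_tolerance` or after
#' `max_cycles`.  The objective is the sum of the band-gated Stotal over
#' all training conditions.
#'
#' @param model an [OdeModel-class].
#' @param sys its [ReactionSystem-class].
#' @param agg an [AggregationMatrices-class].
#' @param dataset an [ExperimentalDataset-class] covering the training
#'   conditions.
#' @param conditions list of condition specs (each a list with `name`,
#'   `targets`, `factor`); the control condition has empty targets.
#' @param k_init initial parameter vector; `"ones"` for all slots at 1,
#'   `"random"` for log-uniform draws in `k_bounds` from `seed`.
#' @param k_bounds bounds of the log-uniform initial draw.
#' @param budget_per_param simplex iterations per group, multiplied by
#'   group size.
#' @param cycle_tolerance relative Stotal improvement per cycle below
#'   which the fit stops.
#' @param max_cycles cycle cap.
#' @param reltol per-group simplex tolerance.
#' @param seed integer seed (initial draw; the rest is deterministic).
#' @param verbose print per-cycle progress.
#' @return a [FitResult-class].
#' @export
fitParameters <- function(model, sys, agg, dataset, conditions,
                          k_init = c("ones", "random"),
                          k_bounds = c(1e-3, 1e3),
                          budget_per_param = 200L,
                          cycle_tolerance = 1e-3,
                          max_cycles = 50L,
                          reltol = 1e-4,
                          seed = 1L,
                          verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.character(k_init)) {
    k_init <- match.arg(k_init)
    K <- if (k_init == "ones") {
      rep(1, model@n_parameters)
    } else {
      set.seed(seed)
      10^stats::runif(model@n_parameters, log10(k_bounds[1]),
                      log10(k_bounds[2]))
    }
  } else {
    K <- as.numeric(k_init)
    stopifnot(length(K) == model@n_parameters)
  }
  objfn <- .makeObjective(model, sys, agg, dataset, conditions)
  n_obs <- attr(objfn, "n_obs")
  S <- tryCatch(objfn(K), error = function(e) Inf)
  if (!is.finite(S)) {
    stop("objective is not finite at the initial parameters; ",
         "try a different initial guess")
  }
  schedule <- buildSchedule(groupParameters(model))
  trace <- list()
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    S_cycle_start <- S
    for (g in seq_len(nrow(schedule))) {
      res <- optimizeGroup(objfn, K, schedule$slots[[g]],
                           budget = as.integer(budget_per_param *
                                                 length(schedule$slots[[g]])),
                           reltol = reltol)
      K <- res$K
      S <- res$value
      trace[[length(trace) + 1L]] <- data.frame(
        cycle = cycle, group = g, element = schedule$name[g],
        evaluations = res$evaluations, stotal = S,
        psi = if (n_obs > 0) sqrt(S) / n_obs else 0
      )
    }
    if (verbose) {
      message(sprintf("cycle %d: Stotal %.6g -> %.6g", cycle,
                      S_cycle_start, S))
    }
    if (S_cycle_start - S < cycle_tolerance * max(S_cycle_start,
                                                  .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  new("FitResult",
      k_hat = K, trace = do.call(rbind, trace),
      schedule = data.frame(rank = schedule$rank, element = schedule$name,
                            repetition = schedule$repetition,
                            size = lengths(schedule$slots)),
      converged = converged, seed = seed)
}

#' Simulate and score a (held-out) condition
#'
#' Applies the condition's intervention to the fitted parameters,
#' simulates from the condition's time-zero data and scores the result
#' against its measurements.
#'
#' @param model an [OdeModel-class].
#' @param sys its [ReactionSystem-class].
#' @param agg an [AggregationMatrices-class].
#' @param dataset dataset containing the condition's measurements.
#' @param k_hat fitted parameter vector.
#' @param condition condition spec (list with `name`, `targets`,
#'   `factor`).
#' @return list with `trajectory` (a [Trajectory-class]) and `report`
#'   (an [ObjectiveReport-class]).
#' @export
predictCondition <- function(model, sys, agg, dataset, k_hat, condition) {
  Kc <- applyCondition(k_hat, sys, condition)
  d <- datasetTable(dataset)
  d <- d[d$condition == condition$name, , drop = FALSE]
  if (!nrow(d)) stop("no data for condition '", condition$name, "'")
  times <- sort(unique(d$time_h))
  x0 <- initialState(dataset, sys, condition$name)
  traj <- simulateModel(model, x0, times, Kc)
  report <- scoreCondition(model, sys, agg, dataset, condition$name, Kc,
                           x0 = x0)
  list(trajectory = traj, report = report)
}
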