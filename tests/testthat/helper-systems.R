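# Helpers shared across the suite: hand-built reaction systems, a random
# system generator for oracle-equivalence checks, and a cache for the one
# expensive medium-fixture fit several tests inspect.

# Build a ReactionSystem directly from a compact description.
# reactions: list of list(r = reactant ids, p = product ids, rev = logical)
makeSystem <- function(n_elements, reactions,
                       forms = rep("protein", n_elements),
                       genes = sprintf("G%02d", seq_len(n_elements))) {
  el <- data.frame(
    id = seq_len(n_elements),
    name = sprintf("E%02d", seq_len(n_elements)),
    form = forms, gene = genes,
    genes = I(lapply(seq_len(n_elements), function(i) {
      if (forms[i] %in% c("rna", "dna_free")) character(0) else genes[i]
    })),
    phospho_genes = I(lapply(seq_len(n_elements), function(i) {
      if (forms[i] == "phospho_protein") genes[i] else character(0)
    })),
    stringsAsFactors = FALSE
  )
  slot <- 0L
  rows <- lapply(seq_along(reactions), function(i) {
    rx <- reactions[[i]]
    rev <- isTRUE(rx$rev)
    kf <- slot + 1L
    kb <- if (rev) slot + 2L else NA_integer_
    slot <<- slot + 1L + as.integer(rev)
    data.frame(
      id = i, name = paste0("R", i),
      reactants = I(list(as.integer(rx$r))), products = I(list(as.integer(rx$p))),
      reversible = rev,
      rate_law = rx$rate_law %||% "mass_action",
      hill_n = rx$hill_n %||% NA_real_,
      kf = kf, kb = kb,
      rule = "manual", src = NA_character_, tgt = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  rx <- do.call(rbind, rows)
  rownames(rx) <- NULL
  new("ReactionSystem", elements = el, reactions = rx,
      n_parameters = slot, dialect = "lumped")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random mass-action system for property tests: n in 3..8 elements,
# m in 1..10 reactions of arity 0..3 per side (never both sides empty).
randomSystem <- function() {
  n <- sample(3:8, 1)
  m <- sample(1:10, 1)
  reactions <- lapply(seq_len(m), function(i) {
    repeat {
      r <- sample(seq_len(n), sample(0:3, 1), replace = TRUE)
      p <- sample(seq_len(n), sample(0:3, 1), replace = TRUE)
      if (length(r) + length(p) > 0) break
    }
    # degradation-style reactions stay irreversible (backward from nothing
    # is a constant influx; legal but keep the generator conventional)
    list(r = r, p = p, rev = length(r) && length(p) && runif(1) < 0.4)
  })
  makeSystem(n, reactions)
}

# Cache for expensive shared fixtures (helpers persist across test files
# within one test run).
.cache <- new.env(parent = emptyenv())

cachedMediumFixture <- function() {
  if (is.null(.cache$medium)) {
    .cache$medium <- makeFixture(mediumFixtureSpec(seed = 7))
  }
  .cache$medium
}

# The one medium-fixture recovery fit: 10 genes, ~60 parameters,
# triplicates at 0/2/6/24/48 h, 10% CV, start perturbed 10x per slot.
cachedRecoveryFit <- function() {
  if (is.null(.cache$recovery)) {
    fix <- cachedMediumFixture()
    training <- Filter(function(cd) !cd$holdout, fix$conditions)
    set.seed(101)
    k0 <- fix$k_true * 10^sample(c(-1, 1), length(fix$k_true), replace = TRUE)
    fit <- fitParameters(
      fix$model, fix$system, fix$agg, fix$dataset, training,
      k_init = k0, budget_per_param = 50L, max_cycles = 3L,
      cycle_tolerance = 1e-3, seed = 101
    )
    .cache$recovery <- list(fix = fix, training = training, k0 = k0, fit = fit)
  }
  .cache$recovery
}

scoreTraining <- function(fix, training, K) {
  reports <- lapply(training, function(cd) {
    scoreCondition(fix$model, fix$system, fix$agg, fix$dataset, cd$name,
                   applyCondition(K, fix$system, cd))
  })
  list(
    stotal = sum(vapply(reports, objectiveTotal, 1)),
    psi = sqrt(sum(vapply(reports, objectiveTotal, 1))) /
      sum(vapply(reports, function(r) r@n_obs, 1L)),
    inband = mean(unlist(lapply(reports, function(r) r@residuals$alpha == 0)))
  )
}
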