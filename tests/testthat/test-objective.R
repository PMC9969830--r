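mkDataset <- function(rows) {
  experimentalDataset(do.call(rbind, rows))
}
row1 <- function(gene, layer, time, rep, value, condition = "control") {
  data.frame(gene = gene, layer = layer, condition = condition,
             time_h = time, replicate = rep, value = value,
             stringsAsFactors = FALSE)
}

test_that("initial state splits protein totals 30/70 and seeds DNA", {
  net <- interactionNetwork(
    c("A", "B"),
    data.frame(source = c("B", "A"), target = c("A", "B"),
               mechanism = c("phosphorylation", "transcriptional_regulation"),
               effect = "activation", stringsAsFactors = FALSE)
  )
  sys <- compileReactions(net)
  ds <- mkDataset(list(
    row1("A", "protein", c(0, 2), 1, c(10, 11)),
    row1("B", "protein", c(0, 2), 1, c(4, 5)),
    row1("B", "rna", c(0, 2), 1, c(16, 18))
  ))
  x0 <- initialState(ds, sys, "control", rna_as_counts = TRUE)
  expect_equal(unname(x0["A_p"]), 3)
  expect_equal(unname(x0["A"]), 7)
  # B has no phospho element: full total to the unmodified form
  expect_equal(unname(x0["B"]), 4)
  # RNA counts divided by the 8 ul cell volume
  expect_equal(unname(x0["RNA_B"]), 2)
  # regulated gene: two DNA copies per 8 ul, bound form empty
  expect_equal(unname(x0["DNA_B"]), 0.25)
  # A is phosphorylation-activated, so its active TF form is A_p
  expect_equal(unname(x0["DNA_B:TF_A_p"]), 0)
  # missing time-zero protein errors with the gene name
  ds2 <- mkDataset(list(row1("A", "protein", 2, 1, 10),
                        row1("B", "protein", c(0, 2), 1, c(4, 5))))
  expect_error(initialState(ds2, sys, "control"), "A")
})

test_that("aggregated outputs sum the element concentrations per layer", {
  edges <- data.frame(source = c("B", "A"), target = c("A", "B"),
                      mechanism = c("phosphorylation", "binding"),
                      effect = c("inhibition", "activation"),
                      stringsAsFactors = FALSE)
  net <- interactionNetwork(c("A", "B"), edges)
  sys <- compileReactions(net, housekeeping = FALSE)
  el <- elementTable(sys)
  agg <- buildAggregation(sys, list(protein = "A", phospho = "A"))
  x <- numeric(nElements(sys))
  x[el$name == "A"] <- 1; x[el$name == "A_p"] <- 2; x[el$name == "A:B"] <- 3
  traj <- new("Trajectory", times = c(0, 1),
              states = rbind(x, x))
  Y <- aggregateOutputs(traj, agg)
  expect_equal(unname(Y$protein["A", ]), c(6, 6))
  expect_equal(unname(Y$phospho["A", ]), c(2, 2))
  # zero state gives zero outputs
  traj0 <- new("Trajectory", times = c(0, 1),
               states = matrix(0, 2, nElements(sys)))
  expect_true(all(unlist(aggregateOutputs(traj0, agg)) == 0))
})

test_that("mean normalization matches its defining identity", {
  expect_equal(meanNormalize(c(2, 4, 6, 8, 10)),
               c(1/3, 2/3, 1, 4/3, 5/3))
  expect_equal(meanNormalize(rep(3, 5)), rep(1, 5))
  s <- meanNormalize(c(1, 5, 9))
  expect_equal(meanNormalize(s), s)  # idempotent
  expect_equal(mean(s), 1)
  expect_error(meanNormalize(c(0, 0, 0)), "mean")
})

test_that("alpha indicator gates on the replicate band", {
  expect_equal(alphaIndicator(2, c(1, 2, 3)), 0)
  expect_equal(alphaIndicator(5, c(1, 2, 3)), 1)
  expect_equal(alphaIndicator(3, c(1, 2, 3)), 0.5)  # literal sgn(0) = 0
  expect_equal(alphaIndicator(0.5, c(1, 2, 3)), 1)
  expect_error(alphaIndicator(1, numeric(0)), "replicate")
})

test_that("absolute-mode layer score matches hand computation", {
  # all simulated points inside bands: zero score
  E <- array(c(1, 1, 3, 3), dim = c(1, 2, 2),
             dimnames = list("A", c("0", "2"), c("1", "2")))
  Y <- matrix(c(2, 2), 1, dimnames = list("A", c("0", "2")))
  expect_equal(layerObjective(Y, E, "absolute")$S, 0)
  # single cell, replicates (1,1,1), y = 2: S = ((2-1)/1)^2 = 1
  E1 <- array(1, dim = c(1, 1, 3),
              dimnames = list("A", "0", c("1", "2", "3")))
  Y1 <- matrix(2, 1, 1, dimnames = list("A", "0"))
  r <- layerObjective(Y1, E1, "absolute")
  expect_equal(r$S, 1)
  expect_equal(r$n_cells, 1L)
  expect_equal(r$n_obs, 3L)
  # scale invariance: doubling simulation and data leaves S unchanged
  set.seed(5)
  E2 <- array(rlnorm(1 * 5 * 3, log(10), 0.2), dim = c(1, 5, 3),
              dimnames = list("A", as.character(0:4), c("1", "2", "3")))
  Y2 <- matrix(rlnorm(5, log(10), 0.4), 1, 5,
               dimnames = list("A", as.character(0:4)))
  expect_equal(layerObjective(2 * Y2, 2 * E2, "absolute")$S,
               layerObjective(Y2, E2, "absolute")$S)
})

test_that("zero-mean biomolecules are skipped with a warning in absolute mode", {
  E <- array(0, dim = c(1, 2, 2),
             dimnames = list("A", c("0", "2"), c("1", "2")))
  Y <- matrix(1, 1, 2, dimnames = list("A", c("0", "2")))
  expect_warning(r <- layerObjective(Y, E, "absolute"), "zero mean")
  expect_equal(r$S, 0)
  expect_equal(r$n_cells, 0L)
})

test_that("mean-normalized mode normalizes each replicate and the simulation", {
  # replicates proportional to simulation: score 0 regardless of scaling
  y <- c(1, 2, 3, 2, 1)
  E <- array(NA_real_, dim = c(1, 5, 3),
             dimnames = list("A", as.character(0:4), c("1", "2", "3")))
  for (r in 1:3) E[1, , r] <- y * r  # arbitrary per-replicate scale
  Y <- matrix(10 * y, 1, 5, dimnames = list("A", as.character(0:4)))
  out <- layerObjective(Y, E, "mean_normalized")
  expect_equal(out$S, 0, tolerance = 1e-24)
  # hand case: replicates constant 1 after normalization, y* deviates
  E2 <- array(rep(c(2, 2), each = 1), dim = c(1, 2, 1),
              dimnames = list("A", c("0", "2"), "1"))
  Y2 <- matrix(c(1, 3), 1, 2, dimnames = list("A", c("0", "2")))
  # y* = (0.5, 1.5), e* = (1, 1), both boundaries alpha = ... strictly out
  out2 <- layerObjective(Y2, E2, "mean_normalized")
  expect_equal(out2$S, 0.5^2 + 0.5^2)
})

test_that("widening a replicate band never increases the score", {
  set.seed(8)
  for (i in 1:20) {
    E <- array(rlnorm(3 * 5 * 3, log(5), 0.3), dim = c(3, 5, 3),
               dimnames = list(c("A", "B", "C"), as.character(0:4),
                               c("1", "2", "3")))
    Y <- matrix(rlnorm(15, log(5), 0.5), 3, 5,
                dimnames = list(c("A", "B", "C"), as.character(0:4)))
    s1 <- layerObjective(Y, E, "absolute")$S
    # add a replicate that widens each band just past the simulated value:
    # the alpha gate must zero every cell, whatever happens to the means
    lo <- apply(E, c(1, 2), min); hi <- apply(E, c(1, 2), max)
    extra <- ifelse(Y >= hi, Y * 1.01, ifelse(Y <= lo, Y * 0.99,
                                              (lo + hi) / 2))
    wide <- array(NA_real_, dim = c(3, 5, 4),
                  dimnames = list(c("A", "B", "C"), as.character(0:4),
                                  as.character(1:4)))
    wide[, , 1:3] <- E
    wide[, , 4] <- extra
    s2 <- layerObjective(Y, wide, "absolute")$S
    expect_equal(s2, 0)
    expect_lte(s2, s1)
  }
})

test_that("missing cells are excluded from sums and counts", {
  E <- array(NA_real_, dim = c(1, 3, 2),
             dimnames = list("A", c("0", "2", "6"), c("1", "2")))
  E[1, 1, ] <- c(1, 3)
  E[1, 3, ] <- c(1, 3)  # time 2 stays unmeasured
  Y <- matrix(c(10, 10, 2), 1, 3, dimnames = list("A", c("0", "2", "6")))
  r <- layerObjective(Y, E, "absolute")
  expect_equal(r$n_cells, 2L)
  expect_equal(r$n_obs, 4L)
})

test_that("layer totals add up and order does not matter", {
  a <- list(S = 1, n_cells = 2L, n_obs = 6L,
            residuals = data.frame(gene = "A", time_h = 0, y = 1, alpha = 1,
                                   residual = 1, contribution = 1))
  b <- list(S = 2, n_cells = 1L, n_obs = 3L, residuals = a$residuals[0, ])
  c3 <- list(S = 3, n_cells = 1L, n_obs = 3L, residuals = a$residuals[0, ])
  rep <- totalObjective(protein = a, phospho = b, rna = c3)
  expect_equal(objectiveTotal(rep), 6)
  expect_equal(rep@sp, 1); expect_equal(rep@sph, 2); expect_equal(rep@srna, 3)
  expect_equal(objectivePsi(rep), sqrt(6) / 12)
  # all layers absent
  empty <- totalObjective()
  expect_equal(objectiveTotal(empty), 0)
  expect_equal(objectivePsi(empty), 0)
})

test_that("the Psi summary is monotone and scales as defined", {
  expect_equal(psiSummary(0, 768, 5, 3), 0)
  expect_lt(psiSummary(1e6, 768, 5, 3), psiSummary(2e6, 768, 5, 3))
  expect_gt(psiSummary(1e6, 500, 5, 3), psiSummary(1e6, 768, 5, 3))
  expect_error(psiSummary(-1, 768, 5, 3), "nonnegative")
  expect_error(psiSummary(1, 0, 5, 3), "positive")
})
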