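edge1 <- function(src, tgt, mech, eff = "activation") {
  data.frame(source = src, target = tgt, mechanism = mech, effect = eff,
             stringsAsFactors = FALSE)
}
modesFor <- function(net) suppressWarnings(inferActiveModes(net))

test_that("binding expands to one reversible association", {
  net <- interactionNetwork(c("A", "B"), edge1("A", "B", "binding"))
  out <- expandEdge(edge1("A", "B", "binding"), modesFor(net))
  expect_equal(nrow(out$reactions), 1L)
  expect_true(out$reactions$reversible)
  expect_equal(max(c(out$reactions$kf, out$reactions$kb)), 2L)  # 2 slots
  expect_true("A:B" %in% out$elements$name)
  expect_equal(out$elements$form[out$elements$name == "A:B"], "complex")
})

test_that("lumped phosphorylation is one irreversible catalytic reaction", {
  net <- interactionNetwork(c("A", "B"),
                            edge1("B", "A", "phosphorylation", "inhibition"))
  modes <- modesFor(net)
  out <- expandEdge(edge1("B", "A", "phosphorylation", "inhibition"), modes)
  expect_equal(nrow(out$reactions), 1L)
  expect_false(out$reactions$reversible)
  expect_true(is.na(out$reactions$kb))
  # registry gains exactly the phospho form beyond the two proteins
  expect_setequal(out$elements$name, c("B", "A", "A_p"))
  rx <- out$reactions
  nm <- out$elements$name
  expect_setequal(nm[rx$reactants[[1]]], c("B", "A"))
  expect_setequal(nm[rx$products[[1]]], c("B", "A_p"))
})

test_that("enzymes act in their active form", {
  # B is activated by phosphorylation, so B_p catalyzes its edges
  edges <- rbind(edge1("C", "B", "phosphorylation", "activation"),
                 edge1("B", "A", "phosphorylation", "activation"))
  net <- interactionNetwork(c("A", "B", "C"), edges)
  sys <- compileReactions(net, housekeeping = FALSE)
  rx <- reactionTable(sys)
  nm <- elementTable(sys)$name
  cat_row <- rx[rx$src == "B" & !is.na(rx$src), ]
  expect_true("B_p" %in% nm[cat_row$reactants[[1]]])
})

test_that("transcriptional activation expands to bind/transcribe/translate", {
  net <- interactionNetwork(c("A", "B"),
                            edge1("A", "B", "transcriptional_regulation"))
  out <- expandEdge(edge1("A", "B", "transcriptional_regulation"),
                    modesFor(net))
  expect_equal(nrow(out$reactions), 3L)
  expect_equal(sum(out$reactions$reversible), 1L)
  expect_equal(max(c(out$reactions$kf, out$reactions$kb), na.rm = TRUE), 4L)
  nm <- out$elements$name
  expect_true(all(c("DNA_B", "DNA_B:TF_A", "RNA_B", "B") %in% nm))
  # transcription fires from the TF-bound DNA and conserves it
  tx <- out$reactions[out$reactions$rule == "transcription", ]
  expect_equal(nm[tx$reactants[[1]]], "DNA_B:TF_A")
  expect_setequal(nm[tx$products[[1]]], c("DNA_B:TF_A", "RNA_B"))
})

test_that("transcriptional inhibition transcribes from free DNA only", {
  e <- edge1("A", "B", "transcriptional_regulation", "inhibition")
  net <- interactionNetwork(c("A", "B"), e)
  out <- expandEdge(e, modesFor(net))
  nm <- out$elements$name
  tx <- out$reactions[out$reactions$rule == "transcription", ]
  expect_equal(nm[tx$reactants[[1]]], "DNA_B")
  # the TF still binds (sequestering the DNA)
  expect_equal(sum(out$reactions$rule == "tf_binding"), 1L)
})

test_that("detailed dialect splits catalysis into binding plus turnover", {
  e <- edge1("B", "A", "phosphorylation", "inhibition")
  net <- interactionNetwork(c("A", "B"), e)
  out <- expandEdge(e, modesFor(net), dialect = "detailed")
  expect_equal(nrow(out$reactions), 2L)
  expect_equal(sum(out$reactions$reversible), 1L)
  expect_equal(max(c(out$reactions$kf, out$reactions$kb), na.rm = TRUE), 3L)
})

test_that("compilation merges shared elements across edges", {
  # two modification edges acting on the same substrate share one phospho form
  edges <- rbind(edge1("A", "C", "phosphorylation", "activation"),
                 edge1("B", "C", "dephosphorylation", "inhibition"))
  net <- interactionNetwork(c("A", "B", "C"), edges)
  sys <- compileReactions(net, housekeeping = FALSE)
  el <- elementTable(sys)
  expect_equal(sum(el$form == "phospho_protein" & el$gene == "C"), 1L)
})

test_that("empty network with one measured protein is housekeeping only", {
  net <- interactionNetwork("A")
  sys <- compileReactions(net)
  rx <- reactionTable(sys)
  expect_equal(nrow(rx), 2L)
  expect_setequal(rx$rule, c("basal_synthesis", "degradation"))
  expect_equal(nParameters(sys), 2L)
})

test_that("six-node network with one of each mechanism matches hand counts", {
  edges <- rbind(
    edge1("G1", "G2", "phosphorylation", "activation"),
    edge1("G3", "G2", "dephosphorylation", "inhibition"),
    edge1("G1", "G4", "ubiquitination", "activation"),
    edge1("G4", "G5", "binding", "activation"),
    edge1("G2", "G6", "transcriptional_regulation", "activation")
  )
  net <- interactionNetwork(sprintf("G%d", 1:6), edges)
  sys <- compileReactions(net)
  # hand enumeration:
  # elements: 6 proteins, G2_p, G4_ub, G4:G5, DNA_G6, DNA_G6:TF_G2_p, RNA_G6
  expect_equal(nElements(sys), 12L)
  # reactions: 5 edge rules + tf gives 3 (bind/transcribe/translate) = 7,
  # basal synthesis for G1..G5 (G6 is regulated) = 5,
  # degradation for all 10 non-DNA elements
  expect_equal(nReactions(sys), 22L)
  # parameters: 22 forward + 2 backward (binding, tf_binding)
  expect_equal(nParameters(sys), 24L)
  # the active (phosphorylated) G2 is the transcription factor
  el <- elementTable(sys)
  expect_true("DNA_G6:TF_G2_p" %in% el$name)
})

test_that("housekeeping rules follow regulation status", {
  # unregulated gene: both basal synthesis and degradation
  net <- interactionNetwork("A")
  rx <- reactionTable(compileReactions(net))
  expect_setequal(rx$rule, c("basal_synthesis", "degradation"))
  # regulated gene gets no basal protein synthesis
  net2 <- interactionNetwork(c("A", "B"),
                             edge1("A", "B", "transcriptional_regulation"))
  rx2 <- reactionTable(compileReactions(net2))
  expect_false("B" %in% rx2$tgt[rx2$rule == "basal_synthesis"])
  expect_true("A" %in% rx2$tgt[rx2$rule == "basal_synthesis"])
  # every gene's protein has exactly one production route
  el2 <- elementTable(compileReactions(net2))
  for (g in c("A", "B")) {
    prot <- el2$id[el2$form == "protein" & el2$gene == g]
    produced_by <- rx2[vapply(rx2$products, function(p) prot %in% p, TRUE) &
                         rx2$rule %in% c("basal_synthesis", "translation"), ]
    expect_equal(nrow(produced_by), 1L, info = g)
  }
  # complexes are degraded too
  net3 <- interactionNetwork(c("A", "B"), edge1("A", "B", "binding"))
  rx3 <- reactionTable(compileReactions(net3))
  el3 <- elementTable(compileReactions(net3))
  cplx <- el3$id[el3$form == "complex"]
  deg_of_cplx <- rx3[rx3$rule == "degradation" &
                       vapply(rx3$reactants, function(r) cplx %in% r, TRUE), ]
  expect_equal(nrow(deg_of_cplx), 1L)
  # measured-but-unregulated RNA gets basal transcription
  rx4 <- reactionTable(compileReactions(net3, measured_rna = "A"))
  expect_true("basal_transcription" %in% rx4$rule)
})

test_that("ubiquitinated forms use only the universal degradation", {
  net <- interactionNetwork(c("A", "B"), edge1("B", "A", "ubiquitination"))
  sys <- compileReactions(net)
  el <- elementTable(sys)
  rx <- reactionTable(sys)
  ub <- el$id[el$form == "ubiq_protein"]
  deg <- rx[vapply(rx$reactants, function(r) identical(r, ub), TRUE) &
              rx$rule == "degradation", ]
  expect_equal(nrow(deg), 1L)
})

test_that("compilation is deterministic and edge-order invariant", {
  spec <- smallFixtureSpec(seed = 9)
  net <- makeToyNetwork(spec)
  sysA <- suppressWarnings(compileReactions(net))
  sysB <- suppressWarnings(compileReactions(net))
  fa <- tempfile(); fb <- tempfile()
  writeReactionSystem(sysA, fa); writeReactionSystem(sysB, fb)
  expect_identical(readLines(fa), readLines(fb))
  # permuted edge order: identical compiled system
  e <- edgeTable(net)
  set.seed(1)
  perm <- interactionNetwork(nodeIds(net), e[sample(nrow(e)), ])
  sysP <- suppressWarnings(compileReactions(perm))
  expect_equal(nElements(sysP), nElements(sysA))
  expect_equal(nReactions(sysP), nReactions(sysA))
  fp <- tempfile(); writeReactionSystem(sysP, fp)
  expect_identical(readLines(fp), readLines(fa))
})

test_that("every parameter slot is used exactly once", {
  for (seed in 1:3) {
    sys <- suppressWarnings(
      compileReactions(makeToyNetwork(smallFixtureSpec(seed = seed)))
    )
    rx <- reactionTable(sys)
    slots <- c(rx$kf, rx$kb[!is.na(rx$kb)])
    expect_equal(sort(slots), seq_len(nParameters(sys)))
  }
})

test_that("unresolved active modes stop compilation with the gene name", {
  net <- interactionNetwork(c("A", "B"),
                            edge1("B", "A", "phosphorylation"))
  modes <- inferActiveModes(net)
  modes$active_form[modes$gene_id == "A"] <- "unresolved"
  expect_error(compileReactions(net, modes), "A")
})

test_that("aggregation rows select the right element sets", {
  edges <- rbind(edge1("B", "A", "phosphorylation", "inhibition"),
                 edge1("A", "B", "binding"))
  net <- interactionNetwork(c("A", "B"), edges)
  sys <- compileReactions(net, measured_rna = character())
  agg <- buildAggregation(sys, list(protein = c("A", "B"), phospho = "A",
                                    rna = character()))
  el <- elementTable(sys)
  # oracle: set membership over the element registry
  a_row <- which(agg@protein["A", ] != 0)
  expect_setequal(el$name[a_row], c("A", "A_p", "A:B"))
  ph_row <- which(agg@phospho["A", ] != 0)
  expect_setequal(el$name[ph_row], "A_p")
  # RNA layer for a gene with no RNA element errors
  expect_error(buildAggregation(sys, list(rna = "A")), "matches no element")
})

test_that("aggregation of disjoint genes is block-diagonal when gene-sorted", {
  edges <- rbind(edge1("A", "B", "binding"), edge1("C", "D", "binding"))
  net <- interactionNetwork(c("A", "B", "C", "D"), edges)
  sys <- compileReactions(net, housekeeping = FALSE)
  el <- elementTable(sys)
  ord <- order(vapply(el$genes, function(g) min(g), ""))  # gene-sorted cols
  agg <- buildAggregation(sys, list(protein = c("A", "B", "C", "D")))
  M <- as.matrix(agg@protein)[, ord]
  ab <- M[c("A", "B"), ]
  cd <- M[c("C", "D"), ]
  # columns used by {A,B} and by {C,D} do not overlap
  expect_equal(sum(colSums(ab != 0) * colSums(cd != 0)), 0)
})
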