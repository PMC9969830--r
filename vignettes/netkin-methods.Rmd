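---
title: "From interaction networks to fitted kinetic models: the netkin methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From interaction networks to fitted kinetic models: the netkin methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkin)
```

# Scope and model

netkin converts a curated, signed, typed protein-interaction snapshot into
a mass-action kinetic model and estimates its rate constants from
replicate multi-layer time courses.  The pipeline has four stages —
network harvesting, reaction compilation, ODE construction/simulation, and
block-coordinate parameter estimation — each usable on its own.

The modeled quantities are absolute concentrations in copies per
microliter; time is in hours.  Three measured layers are supported:
total protein and RNA (absolute scales) and phosphoprotein (relative
intensities, compared after mean normalization).

# Network harvesting

Snapshots are tab-separated files in the SIGNOR dialect (`ENTITYA`,
`ENTITYB`, `EFFECT`, `MECHANISM`, `DIRECT`, `PMID`; the mapping is
configurable).  Only five mechanisms are retained — phosphorylation,
dephosphorylation, ubiquitination, binding, transcriptional regulation —
and effects are reduced to activation/inhibition from the
"up-regulates"/"down-regulates" vocabulary.  Identifiers are uppercased
and trailing numeric isoform suffixes stripped, so isoforms and
transcript variants collapse onto one biomolecule.  Every discarded input
row is logged with a reason (unsupported mechanism, unknown effect,
endpoint outside the gene list, duplicate), so the input edge count is
always conserved between the kept and dropped tables.

`harvestSubnetwork()` retains exactly the edges with *both* endpoints in
the supplied gene list; isolated genes stay in the node set because they
still contribute basal synthesis/degradation dynamics and measurements.

## Active modification forms

Each protein is modeled with at most one phosphorylation site, and one
form is designated active.  The inference is a vote over incoming
modification edges: phosphorylation-activation and
dephosphorylation-inhibition imply phosphorylated-active;
phosphorylation-inhibition and dephosphorylation-activation imply
unmodified-active.  Ubiquitination routes degradation and casts no vote.
Conflicting votes are resolved by majority; an exact tie resolves to
phosphorylated-active and emits a warning.  We chose majority voting
because it is deterministic, order-free, and reported (the `conflict` and
`tie` columns persist in the returned table); a hard error would make
large curated snapshots — where annotation conflicts are routine —
uncompilable, while silent choice would hide the decision.  The
one-site/one-active-form scheme is a deliberate simplification; partial
activities and multi-site phosphorylation are out of scope.

# Reaction compilation

Each edge expands through a dictionary of elementary reactions.  The
default **lumped** dialect uses one reaction per catalytic event, with
the enzyme in its active form on both sides:

| edge | reactions (slots) |
|------|-------------------|
| phosphorylation B→A | `B_act + A -> B_act + A_p` (1) |
| dephosphorylation B→A | `B_act + A_p -> B_act + A` (1) |
| ubiquitination B→A | `B_act + A -> B_act + A_ub` (1) |
| binding A–B | `A_act + B_act <-> A:B` (2) |
| transcriptional activation A→B | `TF_A + DNA_B <-> DNA_B:TF_A` (2); `DNA_B:TF_A -> DNA_B:TF_A + RNA_B` (1); `RNA_B -> RNA_B + B` (1) |
| transcriptional inhibition A→B | TF binding sequesters the promoter (2); transcription proceeds from free DNA only (1); translation (1) |

A **detailed** dialect splits every catalytic edge into reversible
enzyme–substrate binding plus irreversible catalysis (3 slots), for
studies that need explicit complex intermediates.  The lumped default
keeps desk-scale fits tractable and avoids parameters that triplicate
five-point time courses cannot constrain.  Substrates enter
phosphorylation in the unphosphorylated form and dephosphorylation in the
phospho form; ubiquitinated species are removed by the universal
degradation reaction rather than a second, unidentifiable fast-decay
constant.

Housekeeping closes the system: genes without incoming transcriptional
regulation get one basal protein synthesis reaction; genes whose RNA is
measured but unregulated get one basal transcription reaction (so the
trajectory is fittable at all); every element except DNA forms gets one
degradation reaction.  DNA is not degraded — each regulated gene carries
two promoter copies in an 8 µl cell volume, and free + bound DNA is a
conserved total, which doubles as an integration test.

Promoters are modeled one bound TF at a time (no combinatorial
co-occupancy): with *k* regulators a gene has *k* bound-promoter states,
not 2^k.  When several transcriptional edges target one gene, the
translation (and free-DNA transcription) reactions they share are
collapsed to a single reaction before parameter slots are assigned —
duplicate slots on identical reactions would be structurally
unidentifiable.

Compilation walks edges in a canonical sort order, so the emitted system
— element ids, reaction order, slot numbering, serialized JSON — is
byte-identical across runs and independent of the row order of the input
file.

## Aggregation

A measured biomolecule spreads over several elements.  The binary
aggregation matrices map states to observations: the protein row of gene
g sums free g, its phospho and ubiquitinated forms, every complex
containing it, and its DNA-bound TF form; the phospho row sums
phospho-containing forms; the RNA row is the mRNA element.  Simulated
observables are then one sparse matrix product per layer.

# The ODE system

Reaction j has the mass-action rate
$v_j = k^F_j \prod_r x_{r} - k^B_j \prod_p x_{p}$
(backward term absent for irreversible reactions).  Rates for the whole
system evaluate as a fixed chain of element-wise products over padded
index tables: table slot (j, s) holds the index of the s-th
reactant/product of reaction j, and unused slots point at a reserved
constant-one pseudo-state.  Derivatives are $\dot X = H\,V(X,K)$ with
H the **net** stoichiometry matrix: +1 per product occurrence, −1 per
reactant occurrence, so a catalyst nets 0 while still entering the rate
product.  The net convention keeps the algebraic per-species sum of
reaction-rate contributions exact for species appearing on both sides.
`naiveDerivatives()` is a deliberately unvectorized per-reaction loop
kept as the reference oracle; the test suite holds the two paths to
within 1e−12 relative error over a thousand random system/state pairs.
Michaelis–Menten (`v = kcat·E·S/(Km+S)`) and Hill
(`v = Vmax·S^h/(K^h+S^h)`) laws are available per reaction for
single-substrate steps; mass action is the default everywhere.

Integration uses the stiff BDF family (deSolve's `lsode`) at relative
tolerance 1e−6 and absolute tolerance 1e−9, with the analytic Jacobian
assembled from H and the index tables (compiled kernels evaluate both the
rate vector and the Jacobian).  The tolerances are configurable; the
defaults resolve the fastest binding equilibria in the synthetic studies
without visible drift in the conserved DNA totals.  States are clipped to
zero in reports only for excursions within −1e−9.  On integrator failure
the error names the fastest reactions at the last reachable state, which
in practice identifies the stiff subnetwork immediately.

# The objective

Measurements are replicate matrices indexed by biomolecule and time.
For each simulated value y and replicate set e, the band indicator is
$\alpha = \tfrac12\,\mathrm{sgn}\big((y-\max e)(y-\min e)\big) + \tfrac12$:
0 strictly inside the replicate min–max band (the residual is ignored),
1 strictly outside, 0.5 exactly on a boundary (the literal sign
convention is kept; boundaries have measure zero on real data).

Absolute layers (protein, RNA) score
$S = \sum_i \sum_j \alpha_{ij}\,(d_{ij}/\tilde e_i)^2$, where d is the
difference from the replicate mean and $\tilde e_i$ is the biomolecule's
time-averaged mean concentration — the score is invariant under joint
rescaling of simulation and data, which puts nanomolar and
thousands-per-µl species on one scale.  Biomolecules with zero mean are
skipped with a warning rather than dividing by zero.  The phospho layer
has no absolute scale: each replicate series and the simulated series are
first normalized to mean one over the time points, and the unscaled
squared residual is used.  Cells with no measurement are excluded from
both the sums and the effective counts.

$S_{total} = S_p + S_{ph} + S_{RNA}$, and the summary
$\Psi = \sqrt{S_{total}}/(m\,n\,r)$ divides by the number of replicate
measurements (m biomolecules, n time points, r replicates; effective
counts when the design is unbalanced).  Counts are always taken from the
data, never hard-coded.

Initial states come from the time-zero data: measured protein totals are
split 30% phosphorylated / 70% unmodified (the split is a configurable
approximation — when a gene has no phospho form the full total goes to
the unmodified element), complexes and bound forms start empty, measured
RNAs take their time-zero concentration, and each regulated gene's
promoter starts as 2 copies / 8 µl of free DNA.

# Parameter estimation

Rate constants are positive and span orders of magnitude, so all
searching happens in log10 space.  The estimator exploits the sparsity
of the equations: the parameter group of state x_i contains every slot
whose reaction either changes x_i or contains x_i in its rate product;
groups are ranked by how many reactions involve their state (hubs first,
ties by state index) and a Nelder–Mead simplex optimizes one group at a
time with all other parameters frozen.  Counting *reaction appearances*
(rather than raw symbol occurrences) makes the ranking deterministic and
order-free.  Each group keeps the better of incumbent and candidate, so
the training objective is non-increasing at every group boundary — an
invariant the test suite asserts from the fit trace.  A trial point whose
simulation fails scores a large penalty and the search continues.  After
the last group a new cycle starts; fitting stops when a full cycle
improves the objective by less than a relative tolerance (default 1e−3)
or at the cycle cap.  Sub-problem budgets default to 200 simplex
iterations per parameter in the group with 1e−4 simplex tolerances;
neither the sub-problem stopping rule nor the cycle tolerance has a
canonical value, so both are configuration.

Multi-condition fitting sums the objective over training conditions.
Interventions (kinase-inhibitor analogues) enter as multiplicative
knock-downs of the forward constants of the catalytic reactions the
target genes catalyze (factor 0 = complete inhibition).  This encoding is
deliberately config-isolated: pharmacology could equally be modeled as
partial knock-down or state clamping, and nothing outside
`applyCondition()` assumes one choice.

Estimated parameters are not claimed to be unique — band-gated objectives
have flat regions by construction and kinetic parameters of
overparameterized networks are notoriously non-identifiable.  The fit is
judged by its predictive score on held-out conditions, not by parameter
distance.

# Synthetic study designs

The fixture generator emulates the experimental design the package
targets: triplicate measurements at 0, 2, 6, 24 and 48 h across the
three layers, under a control plus kinase-knock-down conditions with a
held-out double knock-down.  Noise is multiplicative —
replicates are lognormal with mean equal to the simulated value and a
per-layer CV (default 10%) — because concentration noise is
scale-dependent and must not produce negative values.  The phospho layer
is multiplied by a random per-biomolecule scale so only its
mean-normalized shape is informative, forcing the relative-intensity
code path.  True rate constants are log-uniform in [1e−3, 1] per hour,
which yields visible but non-explosive dynamics over 48 h at the default
abundances (median 50 copies/µl protein, 2 copies/µl RNA); time-zero
states follow the same 30/70 split the initial-state builder assumes, so
noise-free data round-trip to an exactly zero objective.

Two presets are used throughout the tests: a small design (4 genes,
~9 elements, ~20 parameters) for unit tests and a medium design
(10 genes, ~28 elements, ~57 parameters, 15 edges across all five
mechanisms) for recovery studies.  The recovery study fits from a start
where every parameter is individually perturbed by a factor of 10 (up or
down), with 50 simplex iterations per group parameter and up to three
cycles — sizes chosen so a recovery run completes in minutes on a
single core while still showing an order-of-magnitude objective
reduction.

What the generator does *not* emulate: mass-spectrometry missingness,
batch effects, measurement-correlated noise, model misspecification (the
fitted network is the generating network).  Passing recovery tests
therefore demonstrates the correctness and behavior of the machinery,
not that five-point triplicate data identify real cellular rate
constants.

A statistical note on band coverage: with three replicates, the
probability that a noiseless prediction falls strictly inside the
replicate min–max band is at most 1 − p³ − (1−p)³ ≤ 75% per cell (p the
probability of one replicate falling below the prediction).  Even the
true parameters therefore leave a quarter of the cells outside their
bands in expectation — only the time-zero cells of absolute layers,
where the initial state is anchored to the replicate mean, escape this
bound.  Fitted models can exceed the truth's coverage only by absorbing
replicate noise.  This ceiling is a property of min–max bands at r = 3,
not of the optimizer.

# Numerical choices and degenerate inputs

* Empty networks compile to housekeeping-only systems; empty layers
  contribute zero to the objective and nothing to the counts.
* A flat-zero series cannot be mean-normalized: `meanNormalize()` errors,
  and the scoring path substitutes a zero-mean-guard (a zero simulated
  phospho series scores against the normalized data directly) so a
  knocked-out pathway does not crash the optimizer.
* Ties in the active-mode vote and in the schedule rank have fixed,
  documented tie-breaks; nothing depends on hash or file order.
* All randomness (fixture generation, initial parameter draws) flows
  from explicit integer seeds; two runs with the same seed produce
  identical networks, data, and fit traces.

# Known limitations

One phosphosite per protein; no promoter co-occupancy; no delays,
transport, or stochastic kinetics; inhibitors as rate knock-downs rather
than mechanistic drug binding; no identifiability analysis.  The
`detailed` dialect and the Michaelis–Menten/Hill laws are implemented and
tested but the shipped studies use the lumped mass-action form
throughout.
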