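---
title: "Generality-oriented catalyst design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generality-oriented catalyst design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design problem

A "general" asymmetric catalyst performs well — in both enantioselectivity and
turnover — across a broad, diverse substrate scope, not just on the model
substrate it was optimized against. gencat implements an inverse-design
pipeline for the asymmetric Pictet–Spengler condensation of tryptamine
derivatives (SubA) with carbonyl compounds (SubB): catalyst candidates are
assembled combinatorially from fragment libraries, scored by fast surrogate
models on a diversity-maximizing substrate panel, and evolved by a genetic
algorithm whose fitness makes generality — median performance and its spread
across the panel — the primary target.

Two properties define performance:

* **Selectivity.** The enantiomeric ratio maps to a free-energy splitting of
  the diastereomeric transition states, ΔΔG‡ = RT·ln(er), stored throughout as
  a non-negative magnitude in kcal/mol (with R = 0.0019872 kcal/(mol·K)).
  Percent ee follows as 100·tanh(ΔΔG‡/2RT). These conversions are exact
  bijections and are property-tested as such.
* **Activity.** Turnover is estimated with the energy-span model from the
  relative Gibbs free-energy profile of the catalytic cycle, via TOF volcano
  curves whose x-axis is a single descriptor: the relative energy of the
  protonated tetrahydro-β-carboline intermediate (state 2 of the cycle),
  written ΔG_RRS(2).

# The catalytic cycle and the volcano model

The cycle is modelled with two pathways for the cyclization of the iminium
ion (state 1): concerted attack at C2 of the indole through TS2, or stepwise
attack at C3 through TS1 and the aza-spiroindolenine 1B, followed by C–C
migration. Both converge at the protonated carboline 2, which is deprotonated
through TS3 to release the product.

For a profile with transition-state energies $T_i$, intermediate energies
$I_j$ (the separated reactants define the zero reference) and reaction free
energy $\Delta G_r$, the energy span is

$$\delta E = \max_{i,j}\; T_i - I_j + \Delta G_r \,[\text{if TS } i \text{
precedes } j],\qquad \mathrm{TOF} = \frac{k_B T}{h}\, e^{-\delta E / RT}.$$

`tof_energy_span()` implements the full pairwise scan (the default), and the
smooth summed form
$\mathrm{TOF} = (k_BT/h)\,(1 - e^{\Delta G_r/RT}) / \sum_{ij} e^{E_{ij}/RT}$
as `method = "sum"`. The summed form drives `degree_of_tof_control()`, the
central-difference sensitivity of ln TOF to each TS energy, which is
non-negative and sums to 1. The pairwise form is preferred as the default
because it is closed-form testable against a brute-force scan; where one
(TS, intermediate) pair dominates the two forms agree.

Volcano curves are built by regressing every cycle state (and $\Delta G_r$)
linearly on the descriptor across a set of profiles (`fit_lfesr()`), then
reconstructing the profile from the fitted lines on a descriptor grid and
applying the energy span (`build_volcano()`). The 95% bands propagate each
state's regression prediction interval conservatively: the lower envelope
raises every TS and lowers every intermediate by its interval half-width.
The peak is the grid argmax refined by golden-section search, so its location
is accurate well below the grid step.

# Fitness: four objectives, hierarchically scalarized

A candidate is evaluated on every reaction of the substrate panel with a fixed
context (toluene; benzoic acid as co-catalyst for selectivity calls, acetic
acid for descriptor calls). Activity is folded into a unit-peak Gaussian merit
$f = \exp(-(x - x^\*)^2 / 2\sigma^2)$ around the volcano peak
$x^\* = -9$ kcal/mol. Four objectives are ranked hierarchically
(`chimera_scalarize()`):

1. median ΔΔG‡ across the panel — must exceed an absolute 2.0 kcal/mol;
2. median $f$ — maximized, with a 10% degradation allowance;
3. sd of ΔΔG‡ — minimized, with a 25% compromise;
4. sd of $f$ — minimized, with a 25% compromise.

The scalarizer carves regions: the threshold of each relative objective is
`best − fraction·range`, computed over the candidates that satisfy all
previous objectives. Candidates are tiered by the number of leading objectives
they satisfy and ranked within a tier by the first unsatisfied (or the last)
objective. As the tolerances shrink to zero, the ordering becomes strictly
lexicographic — this limit is the property the test suite checks against a
brute-force oracle, since the published description of the achievement
scalarizer pins down ordering behavior rather than a formula.

The Gaussian width σ defaults to 3 kcal/mol. It is a tunable: nothing in the
method fixes it, and it sets how sharply activity differences away from the
peak are discriminated; 3 kcal/mol spans the visible plateau of the volcano
around its peak.

# The genetic algorithm

Chromosomes are (template, per-slot fragment) assignments; assembly is literal
substitution of fragment SMILES into named `{slot}` scaffold tokens followed
by canonicalization, so every candidate is a checkable molecule. Defaults
follow the study conditions: 10 individuals, 50 generations, 10% per-gene
mutation, 25% truncation selection, one elite. Design choices where the
method description is silent:

* **Crossover** is uniform per-slot between two parents; cross-template pairs
  inherit one parent's template and re-draw incompatible slots, so all
  offspring are valid.
* **Symmetric slot groups** (e.g. the 6/6′ positions of a
  BINOL/SPINOL-phosphoric acid) are one gene: they mutate and cross over as a
  unit.
* **Duplicate offspring** are re-mutated (up to a bounded number of attempts)
  when they clone a member of the forming population, and given a few extra
  attempts when they duplicate an already-scored chromosome. Fitness is
  memoized by chromosome, so duplicates that do slip through cost no model
  calls; the soft novelty bias simply keeps a 10-individual population from
  collapsing onto a handful of genotypes.
* **Best-candidate tracking** uses a pairwise two-row scalarization — a
  transitive, population-independent total order — so with elitism the
  incumbent's merit is monotone non-decreasing by construction. The run's
  reported optimum re-ranks every evaluated candidate in one joint
  scalarization, exactly how the brute-force oracle ranks the full space.
* **Failed assemblies or featurizations** demote a candidate to the worst
  tier instead of aborting the run.
* **Random initial candidates** are drawn uniformly over the assignment
  space (templates weighted by their assignment counts), which makes
  frequency tests over small spaces well-defined regardless of how unevenly
  the templates' spaces are sized.

# Reaction representation and surrogates

Reactions are featurized as concatenated per-component fingerprint blocks
(catalyst, co-catalyst, SubA, SubB, solvent; 1024 bits each; absent components
contribute zero blocks). The fingerprints are Open Babel FP2 hashed
linear-fragment fingerprints; the configuration retains a `radius` field as
metadata for circular-fingerprint backends, which FP2 does not consume.
Chemical-space maps reduce the concatenated fingerprints to 100 principal
components (exact, deterministic) and then to 2D with t-SNE (perplexity 30,
seeded, single-threaded). Substrate panels are chosen by farthest point
sampling of the SubA+SubB map: the first point is the one farthest from the
centroid and ties break to the lowest index, so a panel is reproducible
without storing a seed. Sampling directly in fingerprint space with Jaccard
distances is available (`select_panel(space = "fingerprint")`) but is not the
default: the map keeps the selection consistent with what the 2D reaction
maps visualize.

Surrogates are XGBoost regressors (gradient-boosted trees by default; the
library's random-forest mode is exposed as `booster = "rf"` since the method
description names both). An ensemble holds 100 members trained on independent
random 90/10 splits; predictions average the members and report the member
spread, and out-of-fold predictions give the MAE/MSE report. Descriptor
models follow the mechanism conventions: cinchona-flagged reactions are
excluded, carboxylic-acid co-catalysts are represented by acetic acid, and
the solvent block is dropped. Splits are unstratified uniform draws.

# The synthetic benchmark

Real reaction databases and DFT profile sets cannot be bundled, so
`make_landscape()` plants a fully known ground truth with the statistical
structure the pipeline assumes:

* **Additive landscape.** ΔΔG‡ truth = template base + per-gene fragment
  effects + substrate effects (+ optional sparse fragment×substrate
  interactions), truncated at 0. Effect sizes (base ≈ 1.1 kcal/mol, fragment
  sd 0.45, substrate sd 0.35, noise sd 0.3) are chosen so the population
  median sits near 1 kcal/mol — most combinations poorly selective — while
  the best candidates clear the 2.0 kcal/mol objective, mirroring the
  observed landscape of the reaction. Effects are centered per category, so
  the configured levels are population means by construction.
* **Activity tension.** Descriptor truth is centered at +7 kcal/mol (the
  weak-binding slope of the volcano, where most real reactions sit) and its
  fragment effects are positively coupled to the selectivity effects through
  a `tradeoff` parameter: fragments that raise ΔΔG‡ push the descriptor away
  from the −9 kcal/mol peak, reproducing the selectivity/activity conflict
  the optimizer must negotiate.
* **Planted scaling relations.** Profile states follow fixed lines in the
  descriptor whose crossing places the volcano peak at −9.0 kcal/mol
  analytically; `emit_profiles()` adds per-state Gaussian noise but pins
  state 2 to the descriptor exactly. The planted peak is recomputed
  numerically at construction, not hard-coded.
* **Real SMILES, synthetic effects.** All molecules are genuine substituted
  indoles/tryptamines, carbonyls and urea-type catalysts so fingerprints are
  chemically meaningful — but effects attach to fragment identity, not
  chemistry. Passing tests therefore demonstrate statistical recovery of a
  planted additive structure, not chemical accuracy on real reactions.

The benchmark library spans 180 candidates (a 2-slot urea and a
3-slot dual-HBD urea with one symmetric arm pair), small enough for
`brute_force_optimum()` to enumerate, which anchors the GA acceptance test.

# Problem sizes and numerical choices

The shipped tests run the GA oracle comparison at 100 seeds on the
180-candidate space; surrogate accuracy on a 500-row table with noise
σ = 0.2 (100 splits); end-to-end recovery at 10 seeds with 350-row tables,
8-member ensembles and 30 generations; and volcano recovery on 44-profile
sets (the size of a realistic scaling-relations set). These sizes were chosen
as the smallest at which the distributional claims are meaningful.

Other numerical choices: xgboost runs single-threaded for determinism; the
scalarizer treats ties by giving identical rows identical merit and all
downstream argmax operations take the lowest index; consistency of redundant
selectivity encodings in input tables is enforced to 1e−6; profile state
energies are kcal/mol relative to separated reactants at 0.

# Known limitations

* FP2 fingerprints replace circular (Morgan) fingerprints; block structure,
  width and determinism contracts are identical, but bit semantics differ
  from radius-based neighborhoods.
* The combinatorial count is over assignments; distinct assignments that
  assemble to the same canonical molecule are counted separately (the count
  is a product formula, and assembly is injective on the shipped libraries).
* t-SNE coordinates are deterministic given a seed but not comparable across
  seeds or implementations; only the deterministic PCA stage carries
  geometric guarantees (duplicate inputs coincide there).
* The summed TOF expression requires an exergonic cycle; profiles with
  ΔG_r ≥ 0 can only use the max-span form.
* Surrogate uncertainties are ensemble spreads over resampled splits, not
  calibrated predictive intervals.
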