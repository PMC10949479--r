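---
title: "Constraint-based analysis of bifidobacterial HMO fermentation: models and methods"
author: "bifidflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of bifidobacterial HMO fermentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidflux)
```

## The scientific problem

*Bifidobacterium longum* subsp. *infantis* dominates the breast-fed infant gut
because it imports and ferments human milk oligosaccharides (HMOs). Its
central metabolism is the bifid shunt: hexose phosphates are cleaved by
fructose-6-phosphate phosphoketolase, rearranged by transaldolase and
transketolase through the pentose-phosphate pool, and cleaved again by
phosphoketolase, so that two hexoses end up as three acetyl-phosphates and two
glyceraldehyde-3-phosphates. Acetate kinase and lumped lower glycolysis then
fix the energetic signature of the pathway: **2 glucose → 3 acetate +
2 lactate + 5 ATP**, i.e. 2.5 ATP and a 3:2 acetate:lactate ratio per hexose.
Different HMOs differ only in their feeder pathways — lactose and galactose
enter through β-galactosidase and the Leloir route, 3′-fucosyllactose (3′FL)
adds a fucose branch ending in lactaldehyde reductase and 1,2-propanediol,
6′-sialyllactose (6′SL) a sialic-acid branch, and lacto-N-neotetraose (LNnT) a
GlcNAc branch, the last two converging on the aminosugar pathway into
fructose-6-phosphate.

`bifidflux` implements the complete constraint-based toolchain for studying
this system: a genome-scale model container with gene–protein–reaction (GPR)
boolean logic and JSON/SBML-FBC/TSV input/output, linear-programming engines
(FBA, parsimonious FBA, flux variability analysis, product-ratio constraints,
blocked-reaction detection, yields), GIMME-style transcriptome integration,
single-gene essentiality scans, growth-prediction scoring, and flux-coupling
network analysis with topology and cross-condition rewiring metrics. A
synthetic bifid-shunt model ships with the package so every stage is testable
without external data.

## The optimization models

**FBA.** Growth is the solution of
$$\max_v \; \mu = v_{\mathrm{biomass}} \quad \text{s.t.} \quad S v = 0,\;
\mathrm{lb} \le v \le \mathrm{ub},$$
with $S$ the stoichiometric matrix and fluxes in mmol·gDCW⁻¹·h⁻¹
($\mu$ in h⁻¹). Exchange reactions are written export-positive
(`met_e →`), so uptake is a negative flux bounded below by minus the uptake
bound.

**pFBA.** FBA optima are usually degenerate. `pfba()` re-solves with the
objective pinned at its optimum (minus a $10^{-9}$ relative slack, because a
strict equality at the floating-point optimum can be infeasible) and minimises
$\sum_i |v_i|$, reversible reactions being split into nonnegative halves.
This selects the enzymatically cheapest alternate optimum and suppresses
futile cycles.

**FVA.** `fva()` reports per-reaction flux ranges subject to the objective
staying at or above a fraction of its optimum; the default fraction is 0.99
(ranges within 99 % of optimal growth). Blocked reactions are those whose
unconstrained range is `[0, 0]`.

**Product-ratio constraint.** Measured acetate:lactate secretion ratios are
imposed as a homogeneous equality $v_{\mathrm{EX\_ac}} - r\, v_{\mathrm{EX\_lac}} = 0$
appended to the steady-state system. It is applied to the exchanges — the
measured extracellular products — not to internal kinases, and the zero flux
vector always stays feasible. The workflow default is $r = 1.75$ (3.5:2), the
value used for the condition analyses.

**GIMME.** Transcriptome integration maps normalized counts onto reactions
through the GPR rules (`and` → minimum across subunits, `or` → maximum across
isozymes; reactions without GPR are never thresholded), computes a percentile
threshold $t$ over the per-gene distribution (default: 30th percentile,
linear interpolation), and solves
$$\min_v \sum_{i\,:\,x_i < t} (t - x_i)\,|v_i| \quad \text{s.t.}\quad
S v = 0,\; \mathrm{lb} \le v \le \mathrm{ub},\; \mu \ge f\,\mu^\*,$$
with $f = 0.9$ by default (the canonical required-functionality fraction of
the algorithm; it is a configuration knob). Two further lexicographic stages
make the solution canonical: at minimal penalty the biomass flux is maximised,
and at that growth the total flux is minimised. Below-threshold reactions that
carry no flux in this solution are deactivated (bounds zeroed) in the returned
context model; a below-threshold reaction that is the sole route to biomass is
retained and contributes to the inconsistency score. Deactivation is post-hoc
rather than pre-solve bound clamping precisely so that growth stays feasible
in every condition.

A subtlety worth knowing: the *below-threshold set* and the *inconsistency
score* grow monotonically with the percentile (the penalties are pointwise
non-decreasing), but the *deactivated count* need not — on the 6′SL fixture
the pyruvate-formate-lyase redox valve is flux-free at the 50th percentile yet
becomes the penalty-cheaper NADH sink once more reactions are penalised at the
70th, re-entering the active set. The test suite asserts the monotone
invariants, not count monotonicity.

**Essentiality.** `single_gene_deletions()` disables, per gene, every
reaction whose GPR evaluates to false without it, re-solves plain FBA (the
classification depends only on the optimum, so pFBA would change nothing but
the runtime), and classifies: essential when the knockout optimum is at or
below $10^{-6}$ h⁻¹, reduced growth when the ratio to wild type falls below
$1 - 0.05$, no effect otherwise. Scans run on the medium-bounded models
*without* the acetate:lactate ratio row: the ratio is a measurement-derived
constraint on flux estimation, not physiology, and keeping it would make the
redox-valve genes artifactually essential on a small model.

**Growth-prediction scoring.** Binary growth calls (predicted $\mu$ above
$10^{-6}$ h⁻¹ vs. observed growth) are tallied into TP/FP/TN/FN and scored
with $F = \mathrm{TP} / (\mathrm{TP} + \tfrac12(\mathrm{FP} + \mathrm{FN}))$
and the Matthews correlation coefficient; a zero MCC denominator returns 0
with a `degenerate` flag. Growth-rate RMSE is available when measured rates
exist. Prediction media are applied without the ratio row (binary capability,
not flux estimation).

**Flux coupling.** `fca()` classifies reaction pairs from the geometry of the
flux cone (bounds contribute only their signs). Two reactions are *fully*
coupled when their fluxes keep a fixed nonzero ratio in every steady state,
*partially* coupled when each forces the other without a fixed ratio,
*directionally* coupled one way, or uncoupled. Blocked reactions are removed
first; on the remaining consistent subnetwork, fixed flux ratios are exactly
proportional rows of the nullspace of $S$, which yields the fully-coupled
classes and their ratios without optimisation. Relations between classes are
then decided by signed feasibility LPs ("is there a steady state using
reaction a but not b?"), evaluated over all sign-consistent flux directions of
reversible reactions. Ratios of antiparallel fully-coupled pairs are reported
negative. The whole classifier is validated in the tests against a
brute-force oracle that enumerates extreme rays of the cone per sign-orthant.

**Coupled networks, topology, rewiring.** `build_coupled_network()` anchors
the network on the end-product exchanges (lactate, acetate, succinate,
formate, ethanol, 1,2-PD), keeping the connected full/partial coupling
components that touch a seed; directional relations do not create edges, and a
blocked seed stays as an isolated node. Because mutual forcing is an
equivalence relation, these networks are unions of cliques — the clustering
structure is real, not an artefact. `topology_metrics()` reports node/edge
counts, the mean local clustering coefficient with degree-below-2 nodes
counted as 0 (the convention of mainstream graph tools, needed for
comparability), degree sequences, unweighted edge betweenness, and a
descriptive power-law fit to the degree distribution (no pass/fail threshold:
scale-freeness is reported, not asserted). `dn_rewiring()` builds the
consensus network (union of nodes and edges, each edge annotated with the
number of condition networks containing it) and a per-node rewiring score: the
mean Euclidean distance between each network's binary neighbour-incidence
vector (over the union of the node's neighbours across networks containing it)
and their centroid, normalised by the node's mean degree. The literature names
this score but prints no formula; the definition above is this package's
documented interpretation, chosen so that the score is 0 exactly when the
neighbourhood is identical in every network containing the node.

## The linear-programming engine

No LP package suitable for degenerate metabolic systems is assumed;
`bifidflux` ships its own bounded-variable two-phase primal simplex
(`R/simplex.R`). It handles the linearly dependent equality rows every
stoichiometric matrix has (an independent row subset is selected by QR, and
final residuals are verified), supports infinite upper bounds natively (the
flux cone of coupling analysis), reports infeasible/unbounded outcomes as
statuses rather than numbers, and guards against cycling with Dantzig pricing
that switches to Bland's rule, plus periodic basis refactorization. Solver
pivot tolerance is $10^{-9}$; all downstream zero tests use $10^{-6}$ — one
order of separation so that classifications (blocked, essential, coupled) do
not flap on solver noise. The engine is cross-validated in the test suite
against exhaustive vertex enumeration on 200 random small networks and
against the extreme-ray oracle for coupling.

## The synthetic fixture: what it does and does not emulate

`build_bifid_fixture()` generates a ~70-reaction, ~50-gene model whose core
is the exact bifid-shunt stoichiometry, with carbon-balanced reactions
(formulas are carried and checked elementally in the tests), ATP/ADP/Pi and
NAD/NADH bookkeeping, phosphate and ammonium exchanges, a biomass
pseudo-reaction (5 G6P + 0.25 pyruvate + GAM·ATP per gDCW; GAM defaults to
40 mmol ATP·gDCW⁻¹, with 20 as the common alternative — the stoichiometric
anchors hold for both because they are pre-biomass drains), feeder pathways
for all four substrates, a pyruvate-formate-lyase/alcohol-dehydrogenase NADH
valve, and a deliberately flux-disabled succinate stub (expressed but blocked,
exercising the consistency-gap report; it also reproduces the
succinate-as-isolated-node behaviour of the coupled networks).

Two design points deserve explanation:

* **NADH economy and the feasible ratio window.** In the fixture, NADH comes
  only from lumped lower glycolysis (one per glyceraldehyde-3-phosphate), so
  lactate export can never exceed what the hexose flux can reduce. Imposed
  acetate:lactate ratios below ≈3.1:2 are infeasible at nonzero growth — a
  genome-scale reconstruction has amino-acid and nucleotide metabolism
  providing redox slack that a ~70-reaction core cannot. The ratio-sweep test
  therefore covers 1.55–1.75, where growth is analytically constant.
* **Aminosugar spill-over valves.** At a 3.5:2 ratio the deacetylase acetate
  released from sialic-acid and GlcNAc catabolism would exceed the
  NADH-limited lactate capacity and abolish growth on 6′SL/LNnT. The fixture
  therefore gives free sialic acid and GlcNAc export-only exchanges, letting
  the optimiser spill part of the aminosugar — mirroring the experimental
  observation that *B. infantis* does not fully use sialic acid.

The expression generator emulates the transcriptional layout of HMO growth:
housekeeping/shunt genes high everywhere (~400 normalized counts),
own-condition feeder genes high (~250), off-condition feeder genes low (~15,
below the 30th-percentile threshold), redox-valve and succinate genes low
(~18), a configurable fraction (default 0.15) of "crossed" off-condition
genes at moderate levels (~120, e.g. a fucosidase expressed on lactose), all
under multiplicative log-normal noise (σ = 0.2) from a seeded generator that
saves and restores the global RNG state. The growth-table generator pairs a
designed phenotype table with per-substrate media so the evaluation pipeline
reproduces a designed confusion matrix exactly (including an absent-substrate
TN and a fucose FN — the fixture cannot make biomass from fucose alone
because its biomass draws on glucose-6-phosphate).

What passing fixture tests do **not** show: the fixture has none of the
scale, redundancy, cofactor diversity, or annotation noise of a real
genome-scale reconstruction (hundreds of genes, ~1000 reactions, blocked
subsystems, amino-acid/vitamin biosynthesis). Quantities that are properties
of a particular reconstruction — total deactivated-reaction counts,
essentiality percentages, network sizes and clustering coefficients, absolute
yields — are reproduced here in structure and direction, not in value.

## Parameters at a glance

| Parameter | Default | Units / meaning |
|---|---|---|
| `base_uptake_bound` | 10 | mmol·gDCW⁻¹·h⁻¹ for the reference substrate (lactose) |
| medium mole-normalisation | MW(lactose)/MW(substrate) | equal 2 % wt/vol loadings compared on moles |
| `ratio` | 1.75 | acetate:lactate secretion ratio (3.5:2) |
| `fva_fraction` | 0.99 | FVA optimality fraction |
| `gimme_percentile` | 30 | expression-threshold percentile |
| `biomass_fraction` | 0.9 | GIMME growth retention |
| `gam` | 40 (alt. 20) | mmol ATP·gDCW⁻¹ in biomass; NGAM unconstrained (0) |
| `zero_tol` | 1e-6 | h⁻¹; essentiality/growth threshold |
| `reduction_tol` | 0.05 | relative growth loss called "reduced" |
| LP tolerance | 1e-9 | simplex pivot/optimality |

## Degenerate inputs and tie-breaks

Empty GPR rules always evaluate active and are never expression-thresholded;
genes missing from a profile count as unmeasured (treated as above threshold,
with a warning), never as silent. Knockouts of genes absent from all GPRs
return the wild-type optimum without a solve. An all-zero GIMME penalty
returns the growth-maximal solution with inconsistency 0. A seed exchange
without couplings is kept as an isolated network node with a warning. Ratio
constraints on reactions forced to zero remain feasible (the homogeneous row
is satisfied at zero). Model I/O errors name the offending field; bound
violations (`lb > ub`) are schema errors at read time.

## Problem sizes used by the checks

The shipped checks run the fixture at its native size (~70 reactions), the
LP property tests on 200 random networks of up to 8 reactions against
exhaustive vertex enumeration, the coupling oracle on networks of up to
6 reactions, the GIMME sweep at percentiles {10, 30, 50, 70} across all four
conditions, and the determinism check as two complete four-condition pipeline
runs compared byte for byte.

## Known limitations

* Plain FBA-family methods only: no thermodynamic (loopless-MILP) variants,
  no dynamic FBA, no quadratic objectives.
* The dense simplex is built for models up to a few hundred reactions; a
  genome-scale reconstruction (thousands of columns) would need a sparse
  industrial solver behind the same `solve_lp()` interface.
* The SBML reader consumes the Level 3 + FBC subset the writer emits; it is
  not a general SBML validator.
* The rewiring score follows this package's documented formula; other tools
  implementing a "Dn-score" may normalise differently, so compare trends, not
  absolute values.
* Expression integration supports GIMME only (no iMAT/INIT/FASTCORE), and
  count normalisation is an upstream concern: profiles are taken as given.
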