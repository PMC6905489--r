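---
title: "Modelling the evolution of C4 photosynthesis with constraint-based methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of C4 photosynthesis with constraint-based methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4flux)
library(dplyr)
```

## The model and its assumptions

`c4flux` analyses leaf metabolism as a linear steady-state system. A
metabolic network with stoichiometric matrix $S$ is assumed to operate at
steady state, $S\,v = 0$, with every reaction flux $v_i$ (in
$\mu\mathrm{mol}\,\mathrm{m}^{-2}\,\mathrm{s}^{-1}$) confined to bounds
$v_{\min} \le v \le v_{\max}$. Flux balance analysis (FBA) optimizes a
linear objective $c^\top v$ over this polytope. Because FBA optima are
usually degenerate, every analysis in this package ends in a parsimonious
step (pFBA): among all flux distributions attaining the objective optimum,
the one minimizing the total absolute flux $\sum_i |v_i|$ is returned. The
parsimony step encodes the biological assumption that a leaf achieves its
output with a minimal investment in enzymatic machinery — resource
efficiency as a selective pressure.

Three further constraint types carry the leaf physiology:

* **Flux-ratio constraints** $v_a = r\,v_b$, implemented as extra zero-rows
  of the constraint matrix (never by bound manipulation). They pin the
  phloem sap composition (sucrose : amino acids $= 2.2$, sucrose : starch
  $= 1$) and the photorespiration level, the oxygenation : carboxylation
  ratio of Rubisco, $v_{RBO}/v_{RBC}$. The ratio can be derived from the
  Rubisco specificity $S_R$ and the gas partial pressures as
  $(1/S_R)\,p_{O_2}/p_{CO_2}$ (`photorespiration_ratio_from_gas()`); under
  ambient conditions it is fixed at $0.1$.
* **Coupling constraints** $l \le \sum_k a_k v_k \le u$, used for the
  two-cell photon budget (total and mesophyll/bundle-sheath split) and for
  nutrient-limitation scans summing uptake over both cells.
* **Fixed maintenance fluxes**: non-growth-associated ATP hydrolysis
  (`NGAM_c/h/m`) with both bounds fixed, so every feasible solution pays
  the cost of protein turnover. The peroxisome has no adenylate pool and
  its cost is folded into the cytosol.

Multi-objective questions (maximal phloem output, then minimal
photorespiration, then minimal total flux) are solved lexicographically:
each stage's optimum is pinned as a constraint, with a relative tolerance
of $10^{-6}$, before the next stage runs. Flux variability analysis (FVA)
reports, per reaction, the attainable flux interval while the stage optima
are held and the total-flux minimum may deviate by a stated fraction
(1.5% in the transporter analyses).

## The reduced leaf network generator

All analyses run against a deterministically generated, reduced leaf
network (`build_reduced_leaf_network()`): roughly 115 reactions and 110
metabolites across cytosol (c), chloroplast (h), mitochondrion (m) and
peroxisome (p). It contains lumped light reactions with a thylakoid-lumen
proton pool and a 3 H$^+$/ATP synthase, cyclic electron flow, a lumped
Calvin cycle, the complete photorespiratory salvage loop (phosphoglycolate
phosphatase through glycolate oxidase, the aminotransferases, glycine
decarboxylase + serine hydroxymethyltransferase with an explicit
THF/CH$_2$-THF pair, hydroxypyruvate reductase and glycerate kinase), the
full C4 enzyme set (carbonic anhydrase, PEPC, PPDK, NADP-/NAD-malic
enzyme, PEP carboxykinase, malate dehydrogenases, Ala/Asp
aminotransferases), TCA cycle and oxidative phosphorylation with an
alternative oxidase, nitrate assimilation through GS/GOGAT, and
sucrose/starch/amino-acid synthesis.

Carbon and nitrogen are conserved exactly by construction: every species
carries element counts (cofactors carry their true counts so redox and
adenylate pairs cancel), and `check_conservation()` verifies that no
internal reaction creates or destroys either element. Exports use the
phloem carbon convention — sucrose 12 C, a starch pseudo-unit of 12 C, and
a lumped mean phloem amino acid of 5.5 C and 1 N. The lumped amino acid
replaces the 18-species phloem vector of real exudate data, whose exact
stoichiometry is not public; the export ratio constraint is unaffected by
this lumping.

Two deliberate stoichiometric choices matter for the results. First, the
lumped linear electron flow yields 2 NADPH and 8 lumen protons per
8 photons — an ATP:NADPH ratio of 4:3, below the Calvin-cycle demand of
3:2 — so cyclic electron flow must top up ATP, as in the real thylakoid.
(A yield at or above the demand ratio would force a permanent futile
ATP-burning cycle into every solution.) Second, the photorespiratory loop
is deliberately *not* collapsed into one reaction: its step count, its
transport burden and its energy overhead are what make high oxygenation
expensive, which is the selective pressure the analysis studies.

The pre-curation variant (`curated = FALSE`) carries the classical defects
that model curation historically fixed: NADP-dependent malate
dehydrogenases outside the chloroplast, missing cyclic electron flow,
alternative oxidases, alanine aminotransferases and organelle carriers,
wrong H$^+$/ATP stoichiometries (14/3 and 3 instead of 3 and 4), and
reversible decarboxylases. The packaged `default_curation()` action set —
declarative data, not code — transforms it into the curated network
exactly, including the per-compartment proton sink/source reactions that
absorb the unknown protonation states of transport substrates. The
zero-flux assumptions (chloroplastic NADP dehydrogenase, plastoquinol
oxidase, chloroplastic ADP/ATP carrier) are applied as bound fixes.

## The two-cell composition

`compose_two_cell()` duplicates the one-cell model into `[M]` (mesophyll)
and `[B]` (bundle sheath) copies, each with its own maintenance, boundary
and ratio constraints, and connects the cytosols with one reversible
`[MB]` transporter per transportable metabolite (amino acids, sugars,
phosphorylated sugars, carboxylic acids, glyceric acids,
glycolate/glycerate, triose phosphates, CO$_2$; oxaloacetate, protons,
bicarbonate, phosphate and all cofactors are excluded). Positive interface
flux runs mesophyll to bundle sheath.

The bundle sheath receives two Rubisco populations. The CO$_2$ pool is
split: CO$_2$ delivered by the mesophyll enters an *external* pool
(`[B]_CO2_ex_c`) that may only move to the chloroplast
(`[B]_Tr_CO2h_Ex`) and react with the native carboxylation
`[B]_RBC_h_Ex`, which is tied to the oxygenase `[B]_RBO_h` by the forced
photorespiration ratio. CO$_2$ released by bundle-sheath reactions
(decarboxylases, glycine decarboxylase, respiration) forms the *internal*
pool, which only the CCM-dependent population — the retained `[B]_RBC_h` —
may fix, free of any oxygenation constraint. The internal pool is sealed:
it cannot leave the cell, which both prevents the concentration mechanism
from being short-circuited and forces refixation of respiratory CO$_2$
(so the CCM population carries a small flux, about 2% of uptake, even at
photorespiration ratio 0).

Two-cell bounds: mesophyll CO$_2$ uptake up to 40
$\mu\mathrm{mol}\,\mathrm{m}^{-2}\,\mathrm{s}^{-1}$, bundle-sheath import
closed, total photon uptake budgeted (default at most 1000) with the
bundle sheath receiving no more than the mesophyll — except in light-grid
mode, where the total is forced and the split fixed, covering splits up
to 2. The objective is the phloem output *of the bundle sheath*
(`[B]_Ex_Suc + [B]_Ex_AA`), reflecting that the veins are wrapped by the
bundle sheath; mesophyll exports stay open but unrewarded and are idle in
parsimonious optima.

## Parameters that matter

| Parameter | Default | Units | Where |
|---|---|---|---|
| CO$_2$ uptake cap, one-cell | 20 | $\mu$mol m$^{-2}$ s$^{-1}$ | `default_boundary_spec()` |
| CO$_2$ uptake cap, mesophyll | 40 | $\mu$mol m$^{-2}$ s$^{-1}$ | `set_two_cell_bounds()` |
| Photorespiration ratio, ambient | 0.1 | – | `compose_one_cell()` |
| Photorespiration ratio, stressed | 1/3 | – | `compose_two_cell()` |
| Sucrose : amino acids | 2.2 | – | `compose_one_cell()` |
| Sucrose : starch | 1 | – | `compose_one_cell()` |
| Maintenance c/h/m/p | 0.0427/0.1527/0.0091/0.0076 | $\mu$mol m$^{-2}$ s$^{-1}$ | `default_maintenance()` |
| H$^+$/ATP chloroplast, mitochondria | 3, 4 | – | `fixture_config()` |
| Unbounded-flux proxy | $10^6$ | $\mu$mol m$^{-2}$ s$^{-1}$ | `INF_PROXY` argument defaults |
| Lexicographic stage tolerance | $10^{-6}$ | relative | `lexicographic_solve()` |
| FVA deviation | 0.015 | relative | `transport_fva()` |
| Photorespiration grid | 0–1, step 0.05 | – | `photorespiration_scan()` |
| Light grid | 0–1000 × 0.1–2 | $\mu$mol m$^{-2}$ s$^{-1}$ × – | `light_scan()` |

## Numerical choices

Linear programs are solved by the GNU Linear Programming Kit through a
minimal C binding. The simplex runs with GLPK's default tolerances; a
verdict other than a proven optimum (including a cold-start "no feasible
solution", which can be spurious on problems whose bound proxies span six
orders of magnitude) is re-checked from a fresh basis with the presolver.
Lexicographic stages and all FVA subproblems warm-start from the previous
stage's optimal basis, which makes the marginal stage-pinned problems
(optimum held within $10^{-6}$) reliable and fast. All solving is
deterministic: identical models yield bit-identical solutions, and scans
carry no randomness at all — the only randomized helper is
`perturb_fixture()`, which is a pure function of its seed. Degenerate
parsimonious optima (several flux patterns with the same minimal total
flux) are resolved by the solver's deterministic pivoting and are
documented as solver-dependent; the FVA intervals, not the point solution,
are the robust statement about such alternatives.

Infinite bounds are approximated by $\pm 10^6$, following the boundary
table convention. The pFBA absolute values use the standard auxiliary-
variable construction ($t_i \ge \pm v_i$, minimize $\sum t_i$), so reported
fluxes are the native signed values, not split pairs.

## What the generator does and does not emulate

The fixture reproduces, at reduced scale, the qualitative phenomenology
the analysis requires, and the tests assert it: carbon-limited C3
operation at the CO$_2$ bound with photons near 200
$\mu$mol m$^{-2}$ s$^{-1}$; a C3$\to$C2$\to$C4 transition along the
photorespiration axis (PEPC from anaplerotic-only to carrying the full
uptake of 40, an intermediate glycine-decarboxylase CO$_2$ shuttle peaking
near 4.5, PEP-CK yielding to NADP-ME); a functional C4 cycle for each
decarboxylation enzyme alone, with identical core mesophyll fluxes; an
aspartate/alanine near-optimal alternative to the malate/pyruvate shuttle
for NAD-ME (and only minor variability for NADP-ME); PEP-CK preference
under light limitation; and ATP production almost entirely by the light
reactions.

Passing these tests does **not** show that real leaf data would behave
identically, and four fixture-scale deviations are known:

* Water limitation cannot bind: no transpiration is modelled and the
  network's metabolic water balance is net-positive, so `limitation_scan()`
  over H$_2$O shows no effect.
* Aspartate-dominated transport ratios do not single out PEP-CK: the
  reduced bundle sheath can convert aspartate to malate at (near-)equal
  flux cost, so the decarboxylase choice is degenerate there. The
  malate-dominated preference for NADP-ME does hold.
* Under *forced* high light (the light grid fixes photon uptake), the C4
  shuttle overcycles to dissipate energy through the alternative oxidase;
  decarboxylase flux can then exceed the CO$_2$ uptake, so flux-per-uptake
  shares above 1 and simultaneous malic-enzyme activity occur at some
  saturated grid points. At light-limited points shares stay within
  $[0, 1]$.
* Quantities that depend on the full genome-scale stoichiometry (total
  photon demand 193.7, O$_2$ export 20.9, sucrose export 0.5, the 97.2%
  ATP share, the exact 400 $\mu$mol m$^{-2}$ s$^{-1}$ light threshold) are
  not reproduction targets of the fixture, although several land close.

With no photons the fixed maintenance demand is unsatisfiable, so
zero-light grid points are reported `infeasible` rather than as an
all-zero optimum; no phloem sap can be produced either way.

## Problem sizes

The test suite and the acceptance script run entirely on generated
networks: the one-cell model has 122 reactions after composition, the
two-cell model 265; scans in the tests use 2–8 grid points per axis and
the full default grids (21 points per axis) complete in seconds. These
sizes were chosen so that every documented experiment can be re-run
interactively while exercising the identical code paths as a full-scale
model read from SBML.

## A worked composition

```{r compose}
one <- compose_one_cell()
sol <- solve_pfba(one)
glance(sol)
round(fluxes(sol, c("Im_CO2", "Ex_Suc", "Ex_AA", "Ex_starch", "RBO_h",
                    "RBC_h", "Im_hnu")), 4)
```

```{r two-cell}
two <- compose_two_cell(one)
scan <- photorespiration_scan(two, ratios = c(0, 0.1, 1/3, 0.75, 1))
select(as_tibble(scan), ratio, pepc, gdc, pep_ck, nadp_me,
       rubisco_b_ccm, co2_uptake)
```

```{r fva, fig.width = 7, fig.height = 4}
fva <- transport_fva(two, keep = "NAD_ME")
ggplot2::autoplot(fva)
```
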