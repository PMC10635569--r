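---
title: "Constraint-based modeling of gut bacterial fermentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of gut bacterial fermentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfgem)
```

# The model

A genome-scale metabolic model (GEM) represents an organism's metabolism as
a stoichiometric matrix $S$ (metabolites $\times$ reactions) together with
per-reaction flux bounds $l \le v \le u$ in mmol per gram dry weight per
hour. Flux balance analysis (FBA) assumes a quasi-steady state for all
internal metabolites and predicts a flux distribution by linear
programming:

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where $c$ selects the biomass pseudo-reaction, whose flux is the specific
growth rate $\mu$ (1/h). The assumptions are the standard ones: balanced
growth (no metabolite accumulation), no kinetic or regulatory constraints,
and a boundary drawn through exchange reactions. An exchange is a
pseudo-reaction `met_e <=>` over a single extracellular metabolite; by the
universal sign convention negative exchange flux is uptake, positive is
secretion, so a medium is fully described by a map from exchange id to a
maximal uptake rate (`medium_spec()`).

This package implements that formulation for fermentative, anaerobic gut
bacteria of the *Bacteroides* type: a sugar-limited network that disposes
of excess carbon as short-chain fatty acids and other carboxylic products,
with growth governed by the ATP economy rather than by redox machinery.

## Conventions and default parameters

| Quantity | Default | Unit | Why |
|---|---|---|---|
| Reversible reaction bounds | $\pm 1000$ | mmol/gDW/h | effectively unbounded, finite for the LP |
| Irreversible lower bound | 0 | mmol/gDW/h | reversibility is encoded in the bounds |
| Exchange uptake cap | 20 (10 for disaccharide-like substrates) | mmol/gDW/h | the common physiological cap; a two-hexose substrate carries twice the carbon, so half the molar cap |
| Flux-zero tolerance | $10^{-6}$ | mmol/gDW/h | below this a reaction is "blocked" and growth is "no growth" |
| Essentiality threshold | $10^{-6}$ | 1/h | binary no-growth call after a knockout |
| Growth window for envelopes | $[0.95\,\mu^*, \mu^*]$ | — | releases the optimizer from the single optimal vertex while staying near-optimal |
| Screen positivity threshold | 0.01 | 1/h | a growth gain below this is noise at the scale of these models |
| Co-metabolism improvement threshold | 0.001 | 1/h | finer than the screen threshold because both regimes share the base medium |
| Growth-efficiency carbon offer | 120 | C-mmol/gDW/h | equalizes carbon across substrates (20 mmol/gDW/h of a hexose) |
| Supplementation flux | 10 | C-mmol/gDW/h | a half-substrate-scale perturbation |

Charge is deliberately not tracked, and elemental balance is enforced for
every element *except hydrogen*: without charges, proton bookkeeping
cannot be made consistent, so hydrogen is the designated slack element.
Carrier molecules that are cycled rather than consumed (tRNAs,
acyl-carrier proteins, nucleotide sugars) carry the pseudo-element `R`,
which is legal in formulas, must itself balance in every reaction, and has
zero mass.

# The LP engine

No linear-programming backend is part of this package's dependency set, so
`R/lp.R` implements a dense two-phase primal simplex with explicit variable
bounds. Design points:

* **All bounds finite.** Models use $\pm 1000$ as "unbounded", so the flux
  polytope is a polytope and every LP attains its optimum at a vertex.
  `unbounded` can still be reported defensively.
* **Determinism.** Pivot selection is Dantzig pricing (largest reduced
  cost, first index on ties) for the first 500 iterations, then Bland's
  least-index rule, which guarantees termination; both are deterministic
  functions of the input, so repeated runs return bitwise-identical
  objective values even when the optimal flux vector is degenerate.
* **Tolerances.** Reduced-cost optimality $10^{-9}$, pivot threshold
  $10^{-10}$, phase-1 feasibility residual $10^{-7}$. The basis system is
  re-solved from scratch each iteration (problems here have tens of rows,
  so numerical hygiene is cheaper than factor updates).
* **Validation.** The test suite compares the solver against exhaustive
  vertex enumeration — every choice of basic columns crossed with every
  assignment of nonbasic variables to their bounds — on dozens of seeded
  networks with up to 8 reactions, at $10^{-8}$ agreement, plus hand-derived
  optima on the fixtures.

Growth-window devices (flux variability analysis at a fraction of the
optimum, production envelopes) are imposed by tightening the objective
reaction's own bounds to $[f\mu^*, \mu^*]$. Because the objective is
always a single reaction, this is exactly the usual
$c^\top v \ge f\,\mu^*$ row without inequality machinery.

## Producibility of carrier-bound biomass components

Testing whether a biomass precursor can be synthesized is done by adding a
temporary demand reaction and maximizing it. For carrier-charged
components this naive probe is always zero: the free carrier is only
regenerated by the biomass reaction itself, so a demand that swallows the
charged form starves the carrier pool. The probe therefore mirrors the
biomass reaction's own treatment — it consumes the charged form *and
releases the free carrier*. When the model was built in-session the
carrier pairs are known; for a model read from a file they are recovered
structurally: any `R`-containing metabolite co-consumed by a reaction able
to produce the charged form is a candidate free carrier, and the probe
takes the best candidate. If no producer exists the component is
unproducible under either convention, so the fallback never changes a
verdict, only recovers the correct one when synthesis is possible.

## Dead ends

A metabolite is a dead end when, accounting for reversibility, it can only
ever be produced or only ever be consumed. A metabolite touched by exactly
one reversible reaction is also flagged: production and consumption would
be the same reaction run in opposite directions, which cancels at steady
state, so the reaction is silent regardless.

# Biomass assembly

The biomass objective is built from measured macromolecular composition:

1. **Category mass fractions** of dry weight (protein, carbohydrate,
   lipid, DNA, RNA); anything unmeasured is the cofactor/mineral
   remainder.
2. **Monomer distributions** within each category, on a mass or mole
   basis. Mole-basis tables are converted through free-monomer molar
   masses. Assays that cannot resolve some monomers (classically
   asparagine, glutamine, and tryptophan in amino-acid analyses) are
   completed by `redistribute_missing()`, which divides the unaccounted
   abundance equally among the named absentees. Lipid assays resolving
   chain classes but not head groups go through `equal_split_lipids()`,
   which splits each class's mass equally over the model's representative
   species.
3. **Carrier incorporation.** Monomers polymerized via carriers are
   consumed in the charged form with the free carrier released, which
   forces flux through the charging reactions and charges the ATP they
   cost to the biomass budget.
4. **Normalization.** Molar coefficients are scaled so that
   $\sum_i n_i \cdot MW_i^{\text{free}} = 1$ g per gDW, using the *free*
   monomer's mass always (carriers weigh nothing). The builder guarantees
   this to machine precision; the acceptance criterion allows 0.1%.
   Polymerization water loss is knowingly ignored — the free-monomer rule
   slightly overcounts monomer mass, a documented simplification.

Growth-associated ATP maintenance (GAM, mmol ATP/gDW) is an ATP-hydrolysis
term inside the biomass reaction; non-growth-associated maintenance (NGAM,
mmol ATP/gDW/h) is a dedicated hydrolysis reaction with a forced lower
bound. The ATPM reaction is installed (at lower bound 0) even when NGAM is
zero so surplus catabolic ATP always has a hydrolysis sink.

# Maintenance calibration

`calibrate_maintenance()` fits (GAM, NGAM) to observed growth rates by
minimizing the *maximum* relative error over conditions — a minimax
objective that constrains the worst-predicted condition — with
Nelder-Mead from the conventional start (100, 6). Numerical choices:

* The simplex is run through `stats::optim`'s Nelder-Mead (the
  `fminsearch` family, standard reflection/expansion/contraction
  coefficients) with `reltol` tightened to $10^{-10}$–$10^{-12}$, and
  restarted from the incumbent with a fresh simplex until no improvement:
  on a piecewise-linear minimax surface a collapsed simplex can stall at a
  kink, and a restart costs little. This replaces a bespoke
  diameter-based stopping rule with the established implementation plus
  restarts; the parameter-recovery tolerance (relative $10^{-3}$ on
  noiseless designs with at least two distinct-yield media) is met with
  margin.
* Negative parameters are excluded by a large penalty.
* A condition whose prediction is zero growth (e.g. NGAM above the
  medium's ATP capacity) contributes relative error 1 regardless of how
  infeasible the parameters are — a plateau that strands simplex iterates.
  Such conditions instead contribute $1 + 10^{-3}(GAM + NGAM)$, a mild
  slope toward feasibility that is invisible wherever all conditions grow.
* `grid_restarts = k` probes basin uniqueness from a $k \times k$ grid of
  starts; on the fixtures every start converges to the same optimum.

Identifiability requires at least two media with distinct ATP yields: on
the ATP-limited fermenter $\mu = (yU - NGAM)/GAM$ is linear in the uptake
$U$, so two $(U, \mu)$ pairs pin both coefficients, and the noiseless
recovery test exploits exactly this closed form.

# Gap filling

`gap_fill()` is greedy and component-driven, mirroring manual curation:
with all exchanges open, each pool reaction is scored by the number of
biomass components it makes producible; the best strictly-improving
candidate is added (ties broken by lexicographic id, so runs are
deterministic), until everything is producible or nothing helps.
Reactions that only increase flux magnitudes are never added. Because two
serial reactions can be needed at once, pairs are scored when no single
reaction helps, under a budget (`max_pairs`, default 200) — an explicit
extension of the one-at-a-time procedure, on by default. Minimality is
not claimed; on fixtures with a unique single-reaction repair, exactly
that reaction is chosen. A per-medium mode (`medium =`) restricts the
loop to one growth condition. Added reactions are flagged for downstream
evidence review (sequence or literature support is out of scope here).

# The synthetic fermenter

`toy_fermenter()` generates the study system: a hexose-like substrate, one
glycolysis-like branch per fermentation product with an explicit ATP
stoichiometry (defaults 4 and 2 ATP per substrate — distinct yields so the
optimal allocation is unique), synthesis of three amino-acid analogues and
a lipid from branch products, carrier charging for two amino acids and the
carbohydrate monomer (tRNA and nucleotide-sugar analogues), a
composition-derived biomass, and GAM/NGAM of 30 and 5 — energy parameters
of the magnitude typical for anaerobic heterotrophs, chosen once for the
fixtures. Two of the amino acids have exchange reactions and transporters;
the third deliberately has none, which is what makes its synthesis genes
differentially essential when amino acids are supplemented — the same
asymmetry curated models show for amino acids lacking annotated
transporters. Gene rules cover the interesting GPR cases: an isozyme pair
(branch 2), an enzyme complex (first amino-acid synthesis), and porin-like
transports with no gene association.

Every fixture is elementally balanced (except hydrogen, by policy), passes
model validation, and ships with a *hand-derived* optimum:
`toy_expected_growth()` re-derives the biomass coefficients and solves the
substrate/ATP allocation in closed form, independently of the LP engine,
and the engine must agree to $10^{-8}$. All randomness (composition
jitter, gap sampling, decoy pools, observation noise) is seed-parameterized
and restores the caller's RNG state.

What the toys emulate: the topology classes the analyses assume — chains,
competing branches with distinct ATP yields, carrier cycling, joint gaps,
importable vs non-importable precursors. What they do not: the scale
(tens, not thousands, of reactions), pathway redundancy, realistic
cofactor networks, or the content of any curated reconstruction. Passing
tests therefore demonstrate correctness of the *methods* on networks where
ground truth is computable, not fidelity to any particular organism's
published model; running the same pipelines on a distributed model file
only requires `read_model()` on its SBML or JSON form.

## Problem sizes

The suite and the acceptance script run entirely at desk scale: LP oracle
comparisons on networks of 4–8 reactions, all pipelines on the 27-reaction
fermenter, calibration on a 13-reaction ATP toy with 2–3 media, and a
3×3 restart grid — sizes chosen so every quantity recomputes from scratch
in seconds while still exercising each code path.

# Known limitations

* No pFBA, MOMA, sampling, dynamic or thermodynamic FBA — the analyses
  here need none of them.
* Off-diagonal envelope entries are one optimal vertex among possibly
  many; only diagonal (maximized) entries are reproducible predictions.
  The solver's determinism makes them *repeatable*, not unique.
* The SBML subset covers FBC v2 constraint-based content (species,
  formulas, bounds-as-parameters, gene associations, objectives, SBO-coded
  pseudo-reaction kinds); it is not a general SBML implementation, and
  `.mat` workspaces are not read.
* Fractional formula counts and the `R` pseudo-element are accepted in
  `fbc:chemicalFormula`, which strict FBC validators may flag.
* The gap filler is greedy: it can repair with more reactions than the
  minimum, and triple-or-larger joint gaps are found only through
  intermediate gains.
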