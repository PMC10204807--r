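---
title: "Constraint-based modeling of C3 leaf carbon metabolism with leafcbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of C3 leaf carbon metabolism with leafcbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcbm)
```

## The model

leafcbm implements flux balance analysis (FBA) for compartmentalized leaf
carbon metabolism. A stoichiometric model is a set of metabolites
distributed over compartments (cytosol, chloroplast, mitochondrion,
peroxisome, plus the external space), reactions with flux bounds in
mmol/gDW/day, boolean gene associations (GPRs), and a linear objective.
The core prediction problem is the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; LB \le v \le UB,$$

where $S$ is the stoichiometric matrix over internal metabolites, and the
objective is the flux of a biomass pseudo-reaction draining carbohydrate,
protein, fiber and lipid precursors in fixed mass proportions -- its flux
is the leaf growth rate. Two constraint families extend the plain LP:

* **Ratio coupling.** RuBisCO is represented as separate carboxylase
  ($V_c$) and oxygenase ($V_o$) reactions; `apply_ratio_constraint()`
  adds the equality $v_{V_c} - r\, v_{V_o} = 0$. Ambient air corresponds
  to $r = 3$; drought-like conditions push $r$ toward 1. Ratio
  constraints are only accepted between irreversible reactions, since a
  flux ratio is ill-defined when signs can flip.
* **Photon supply.** `set_photon_constraint()` derives the photon
  exchange bound from a net photosynthesis rate and a light-use
  efficiency ($P_N/\mathrm{LUE}$). By default the influx is *pinned*
  (lower = upper bound) rather than capped: absorbed photons drive
  electron transport, and the network has no radiative escape (no
  non-photochemical quenching reaction), so surplus energy under carbon
  limitation must be rerouted through metabolism. This is the premise of
  the drought scenarios; a cap is available via `pin = FALSE`.

### Alternate optima and the canonical solution

FBA optima are generically non-unique, so per-reaction fluxes (PEPC in
particular) would be meaningless without a tie-break. All reported fluxes
come from `canonicalize()`: the total absolute flux $\sum_j |v_j|$ is
minimized subject to the original constraints with the objective pinned
at its optimum (parsimonious FBA, implemented by splitting each flux into
forward/backward parts). The objective is preserved to 1e-9 relative;
futile cycles are driven to zero. The two-stage max-biomass /
min-total-flux procedure is this package's choice of secondary criterion.

### Numerical machinery

The package's linear programs are solved by its own dense
bounded-variable two-phase primal simplex (`lp_solve_bounded()`),
written for the highly degenerate equality systems stoichiometric models
produce: nonbasic variables sit at either bound,
bound flips are handled without basis changes, and pivoting switches from
Dantzig to Bland's rule after a run of degenerate steps to guarantee
termination. Tolerances: reduced-cost/ratio pivots 1e-9, steady-state
residual guard 1e-6, phase-1 feasibility 1e-7. The test suite checks the
solver against an independent brute-force vertex-enumeration oracle on
dozens of random toy models and validates every optimal solution against
$|Sv| \le 10^{-6}$ and the bounds.

## The synthetic leaf model

`build_fixture_leaf_model()` constructs a hand-curated core model
(111 reactions, 109 species, 5 compartments) emulating a mature
photoautotrophic C3 mesophyll cell: lumped photosystems (linear electron
flow producing NADPH with 1.28 coupled ATP per NADPH; cyclic flow
producing ATP alone), the Calvin-Benson cycle with lumped reduction and
regeneration phases, the complete photorespiratory glycolate route
(chloroplast PGP, peroxisomal GOX/GGAT/SGAT/HPR, mitochondrial GDC
releasing CO2 and ammonium, GS/GOGAT refixation in the chloroplast),
cytosolic glycolysis, sucrose and cell-wall synthesis, the oxidative
pentose phosphate pathway, the TCA cycle and mitochondrial electron
transport (P/O 2.5), fatty-acid synthesis, nitrate/sulfate assimilation,
and the C4-module: carbonic anhydrase, PEPC, PEPCK, NADP-malic enzyme
(chloroplast), NAD-malic enzyme (mitochondrion), with malate/oxaloacetate
shuttles and ATP/ADP translocators. Gas species are compartment-specific
with explicit diffusion reactions, so an "intracellular CO2 pool" and its
refixation are representable. Free ammonia export is closed (zero bound),
forcing GS/GOGAT refixation of photorespiratory ammonium.

Only carbon, nitrogen, phosphorus and sulfur are tracked in the elemental
formulas; protons, oxygen stoichiometry of water, and charge are
deliberately untracked, as is usual for lumped central-metabolism
reconstructions. `element_balance()` audits every internal reaction for
C/N/P/S balance, and the carbon-conservation test closes the balance over
exchanges plus the biomass drain in every scenario.

### Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `biomass_fractions` | 0.55/0.20/0.17/0.08 | g/g | carbohydrate/protein/fiber/lipid mass fractions; placeholder leaf composition, converted to mmol/gDW via monomer masses (glucan 162.14, residue 110, palmitate 256.43 g/mol) |
| `net_photosynthesis` | 100 | mmol CO2/gDW/day | baseline assimilation rate used for calibration |
| `lue` | `NULL` (calibrated) | mol CO2/mol photon | explicit light-use efficiency; `NULL` derives the photon budget from the model itself |
| `maintenance_atp` | 7.5 | mmol/gDW/day | non-growth ATP demand, pinned as an equality |
| `vc_vo_default` | 3 | -- | ambient-air carboxylation/oxygenation ratio |

**Photon calibration.** With `lue = NULL` the model is solved once with
the CO2 uptake capped at `net_photosynthesis` and photons free; the
photon influx is then pinned at the canonical photon demand of that
optimum. Light supply is thereby exactly consistent with the configured
assimilation rate -- the baseline has no slack energy, so any scenario
that restricts carbon immediately creates a measurable energy surplus.
The default build pins 1636.3 mmol photons/gDW/day, an implied maximum
light-use efficiency of about 0.061 mol CO2 per mol photons, inside the
physiological range for C3 leaves.

### Design decisions that make the drought mechanism identifiable

Three structural choices determine where surplus absorbed light can go,
and therefore whether the CO2-recycling response is forced:

1. **No free redox sink.** There is no Mehler/NPQ reaction and no
   alternative oxidase; an earlier draft's lumped ascorbate-glutathione
   NADPH sink was removed because any unbounded "energy to heat" shortcut
   lets the optimizer dissipate surplus light without touching carbon
   metabolism. ROS scavenging in vivo is demand-driven, not a photon
   dump. The only true energy sinks are the maintenance ATPase (fixed)
   and ATP-consuming metabolic cycles.
2. **Export-only chloroplast adenylate translocator.** Daytime stromal
   ATP import is essentially inactive in mature leaves; allowing it lets
   mitochondrial respiration power Calvin-cycle dissipation and hides
   the PEPC response at mild stress. The stroma tops up ATP via cyclic
   electron flow instead.
3. **Bounded cyclic electron flow.** CEF is a minor path in vivo; its
   capacity (150 mmol/gDW/day, ~18% of the photon budget) covers the
   stromal ATP deficit at baseline but cannot absorb a large surplus,
   which therefore propagates into the carbon network.

With these in place the cytosolic PEPC-PEPCK cycle (carbonic anhydrase +
PEPC + PEPCK, net ATP hydrolysis) is the terminal valve for surplus
energy, and the qualitative stress structure emerges from optimization
alone, with no scenario-specific switches: restricting CO2 uptake raises
canonical PEPC flux monotonically while carboxylation is retained well
above the proportional level (internal CO2 is refixed); lowering Vc/Vo
raises the whole glycolate route and lowers PEPC; forcing PEPC tenfold
lowers biomass and redirects carbon to sucrose export while PEPCK and the
CO2 pool turnover rise. These are exactly the sign structures asserted by
the test suite.

### Scenario semantics

* `run_drought(f)` pins the CO2 exchange at `f` times the baseline
  canonical uptake (stomatal closure restricts the *atmospheric* influx;
  internally produced CO2 remains free to be refixed).
* `run_pepc_elevation(k)` sets the PEPC lower bound to `k` times its
  baseline canonical flux -- a lower bound, not an equality, so the
  program stays feasible while guaranteeing the stated activity -- and
  pins CO2 uptake at the baseline value, so carbon supply is unchanged
  while the enzyme is perturbed. Infeasible demands surface as solver
  status, never silently.
* `run_photorespiration_sweep(ratios)` re-solves with the Vc/Vo equality
  at each ratio, uptake left free; infeasible points are recorded as
  rows and the sweep continues.

All fold changes use `log2((|v|+\epsilon)/(|v_0|+\epsilon))` with
$\epsilon = 10^{-9}$ (stable under $\epsilon \in \{10^{-9}, 10^{-8}\}$ by
test) and a $\pm 0.1$ log2 no-change band, mirroring the treatment of
near-unity expression ratios as unchanged.

## Analysis layer

The flux-sum of metabolite $i$, $\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$,
is a turnover proxy for its pool; at steady state the producing and
consuming halves each equal $\Phi_i$, an identity the suite asserts for
every internal metabolite in every scenario. `co2_source_attribution()`
aggregates producer contributions over all intracellular CO2 species by
pathway tag (transports and exchanges move CO2 between pools and are
excluded from production); the combined flux-sum of those species
operationalizes the "intracellular CO2 pool", with per-compartment values
also emitted since the aggregation level is a convention.
`energy_turnover_report()` identifies ATP/NADH/NADPH by annotation tags
rather than id matching, and reports the named shuttle fluxes
(translocators and malate/oxaloacetate shuttles, positive in their
canonical export direction).

`concordance()` compares predicted flux-change signs with expression
log2 fold changes, aggregating a reaction's detected GPR genes by their
mean log2FC (per-gene rows are also emitted; the aggregation rule is a
package convention) and treating $|\text{mean}| \le 0.1$ as unchanged.
Reactions without GPRs, without detected genes, or inactive in both
conditions are not comparable. `synth_expression()` plants a known
sign-agreement probability with log-normal magnitudes under a fixed seed;
the suite recovers planted rates of 0.5/0.8/1.0 within the 95% binomial
interval at 200 comparable reactions.

## What the synthetic model does and does not show

The generator reproduces the structural assumptions of a compartmentalized
C3 leaf reconstruction and the qualitative drought/PEPC mechanism, at
roughly a quarter of the reaction count of a full leaf model and without
measured uptake constraints. Quantitative magnitudes therefore differ
from values obtained on full reconstructions calibrated against gas
exchange data -- the acceptance script reports, for example, a
carboxylation retention near 100% at half uptake (a small network refixes
essentially all internal CO2) and a biomass reduction under tenfold PEPC
set by the size of the anaplerotic baseline flux. Passing tests
demonstrate internal consistency and the directional mechanism, not
numerical agreement with any particular measured leaf.

Known limitations: no thermodynamic or kinetic constraints; lumped
electron transport fixes the ATP:NADPH coupling at 1.28; protons, oxygen
and charge are untracked; nucleotide sugars are lumped onto an ATP
economy; the protein residue mix is a six-amino-acid stand-in; dynamic
(time-resolved) behavior is out of scope.

## Problem sizes and runtime

The packaged model solves an LP with 111 flux variables and about 100
internal balances; a canonical (split) solve doubles the variables. A
full scenario battery (baseline, five-ratio sweep, drought, PEPC
elevation, analyses) completes in a few seconds on one CPU; the property
suite, including the enumeration-oracle comparisons on dozens of random
toy models, runs in about a minute.

## Reproducing a run

```{r, eval = FALSE}
model <- leaf_core_model()
base <- run_baseline(model)
drought <- run_drought(model, 0.5, baseline = base)
pepc <- run_pepc_elevation(model, 10, baseline = base)
fold_change_table(drought, base)[1:5, ]
cmd_run(out_dir = "leafcbm_run")   # writes TSV/JSON outputs + manifest
```

Every output directory contains a `manifest.json` sufficient to reproduce
it; all numeric output uses 9 significant digits so repeated runs are
byte-identical.
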