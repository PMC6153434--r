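---
title: "Modeling hypoxia-activated prodrug bystander effects with hapabm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hypoxia-activated prodrug bystander effects with hapabm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapabm)
```

## The scientific problem

Hypoxia-activated prodrugs (HAPs) such as SN30000 and PR104A are inert
until one-electron reductases — chiefly P450 oxidoreductase (POR) —
reduce them under low oxygen to cytotoxic metabolites. Whether those
metabolites kill only the cell that produced them, or also neighboring
cells that cannot activate the prodrug, is the *bystander effect*
question, and it is intrinsically spatial: it is decided by the
reaction–diffusion balance between prodrug penetration into tissue,
metabolite release from activating cells, and metabolite stability.

`hapabm` simulates this balance in the three culture systems used to
measure it: monolayers (uniform exposure, used for calibration),
multicellular layers (MCLs; a tissue slab between a donor and a
receiver compartment, used to measure tissue transport), and
multicellular spheroid co-cultures of "activator" cells
(POR-overexpressing) and "target" cells (POR-knockout). Each cell is an
agent on a cubic lattice with its own lineage, volume, intracellular
concentrations and survival probability.

## Model structure

### Lattice and geometry

Cells occupy sites of a regular 3D lattice. A cubic site has twice the
mean cell volume, so an occupied site is half cell, half extracellular
space (cell volume fraction 0.5, as measured for HCT116 multicellular
cultures). The mean HCT116 cell volume is not published; we assume
2,500 µm³ (a typical value for this line), giving a lattice spacing of
`(2 x 2500)^(1/3) = 17.1` µm. Both are configurable
(`build_lattice()`, `parameter_registry()`).

The whole culture is modeled, not the spheroid alone: the well's
unstirred medium column (default 0.2 mL, 6.1 mm deep for growth; 80 µL
for drug exposures) is represented as a 1D axial stack of nodes coupled
flux-conservatively to the boundary of the 3D fine grid, with a
gas-phase oxygen boundary condition at the medium–air interface. The
medium is well mixed at the moment of drug addition and unstirred
thereafter.

### Transport

Each diffusible solute obeys a Method-of-Lines reaction–diffusion
system on the lattice: 6-point-stencil diffusion on the extracellular
field (`D_tissue` inside the occupied hull, `D_medium` outside,
harmonic-mean conductance at the interface), first-order membrane
exchange (`K_in`, `K_out`; their ratio encodes lipophilic
partitioning), first-order losses in medium and cell, and the
intracellular metabolic chain Prodrug → Metabolite 1 → Metabolite 2 →
untracked products with stoichiometric (1:1) conversion. Vacant sites
carry only the extracellular equation.

The discrete equations are advanced by a one-step θ-scheme
(Crank–Nicolson, θ = 0.5) in which diffusion, exchange, decay and
metabolism are assembled into a single linear operator — there is no
operator splitting. The intracellular unknowns are eliminated
algebraically (a Schur complement), so each step per solute reduces to
one solve with a symmetric positive-definite sparse matrix whose
Cholesky factor is reused across steps; the factor is refreshed only
when the oxygen field has shifted the metabolism coefficients by more
than 5%. We chose this scheme over an adaptive explicit Runge–Kutta
integrator because the diffusion operator is stiff at this resolution
(stability would force steps of ~0.02 s for oxygen), while the
semi-implicit step is unconditionally stable and second-order accurate;
with the default `dt = 2` s the computed survivals agree with `dt = 4`
s to four decimal places, and a closed system conserves the solute
chain to machine precision (see the test suite). The 1D monolayer and
MCL systems are small and are integrated with `deSolve::lsoda()`
(adaptive, stiff-switching) instead.

Oxygen is treated as a single well-equilibrated compartment per site
(no membrane barrier) with Michaelis–Menten consumption per cell
(assumed `V_max` = 6e-17 mol cell⁻¹ s⁻¹, `K_m` = 1.3 µM). Because the
fine-grid oxygen field relaxes in seconds while the medium column
evolves over minutes to hours, the grid field is solved quasi-steadily
(Newton iteration) against the transient column — a time-scale
separation, not an extra model assumption. The depletion boundary
layer in the medium around a consuming spheroid extends several cell
diameters; the quasi-steady solve therefore includes eight vacant
shells around the occupied hull by default (the surface oxygen value
is converged at that margin).

### Pharmacodynamics

Cell killing is hazard-based. Two laws are available
(`kill_model()`):

* **metabolism-rate law** (SN30000): hazard rate `K_c * M'`, with `M' =
  K_met(O2) * C_i` the cell's own prodrug-activation rate. The proximal
  cytotoxin (an oxidizing radical) never leaves the cell, so killing
  tracks activation and there is *no* bystander effect by construction.
* **concentration law** (PR104A metabolites): hazard rate `K_c * C_i`
  on the intracellular concentration of a diffusible cytotoxin, the
  route by which bystander killing arises.

Survival over an exposure is `exp(-∫ hazard dt)` — the continuous limit
of the discrete per-step kill probability — accumulated per cell with
exact trapezoidal integration, which makes survival independent of the
step subdivision. Two simultaneous cytotoxins combine as
`P_kill = 1 - (1 - P1)(1 - P2)`, i.e. survival probabilities multiply.
Activators and targets are assumed equally sensitive to the same
intracellular cytotoxin exposure; they differ only in `K_met0`.
Oxygen inhibits activation as `K_met = K_met0 * K_O2 / (K_O2 + O2)`
(for PR104A, `K_O2 = 0.126` µM, which is what makes dissolved-oxygen
contamination of nominally anoxic exposures consequential).

Prodrug-kill and hypoxia-driven death are independent competing
processes; clonogen counts exclude death-tagged cells.

### Growth

Cells grow exponentially in volume at rate `ln 2 / doubling_time`
scaled by local oxygen (Michaelis–Menten with an assumed 1 µM
half-saturation), and divide when volume doubles from birth; the birth
volume is `mean_cell_volume * ln 2` so the time-average volume of a
growing cell equals the mean. Doubling times: 38 h for POR-G, 31 h for
the other lines. A daughter takes an adjacent vacancy; when none
exists, a chain of cells is displaced outward. Two placement details
differ deliberately from naive choices: the daughter takes the *most
compact* adjacent vacancy (closest to the spheroid center, random
among ties), and the displacement direction is sampled with
alignment-weighted probability over the outward hemisphere rather than
fixed to the best-aligned lattice ray. Uniform-random placement and
deterministic rays both produce dendritic, spiky aggregates — lattice
artifacts; the chosen rules keep spheroids compact and near-spherical
while remaining fully reproducible given the seed.

Severe hypoxia (O₂ < 0.15 µM) sustained beyond 24 h tags a cell for
death; tagged cells lyse (their site reverts to vacant) after an
assumed further 24 h, producing central necrosis in sufficiently large
spheroids. Glucose dependence is deliberately omitted (medium
replenishment makes it non-limiting in the modeled experiments).

With the assumed cell volume and oxygen parameters, seeding 1,000
cells and growing 4 days yields a ~434 µm spheroid, matching the ~430
µm day-4 spheroids of the reference experiments; 3,000-cell seedings
grow larger (~620 µm) because oxygen only mildly limits growth under
these assumptions. The day-4 diameter is recorded, not promised: it
depends on the assumed growth parameters.

## Parameter provenance

Every number a simulation consumes resolves to one entry of a
provenance-tagged registry (`default_registry()`): `PAPER` entries are
published values (e.g. `K_met0` for SN30000 of 1.88 min⁻¹ in parental
HCT116, adjusted to 1.3 min⁻¹ for PORko-G targets and 14 min⁻¹ for
POR-R activators; `K_O2 = 0.126` µM for PR104A; potencies 0.092 and
0.05 mM⁻¹s⁻¹ for the two PR104A metabolite classes), `FITTED` entries
were estimated from data, and `ASSUMED` entries are defaults we chose
once and expose for override. Simulations can report every `ASSUMED`
entry they depended on (`registry_provenance()`, `run_manifest()`).

Two groups of assumptions deserve emphasis:

* **PR104A metabolite transport.** The measured diffusivities and
  stabilities live in supplementary tables not available here. We
  encode the published qualitative facts — metabolite 1 (PR104H+M) is
  the dominant *intracellular* metabolite (slow membrane exchange,
  0.003 s⁻¹), metabolite 2 (the dichloro mustards A+B) is fourfold more
  stable and more lipophilic (`K_in/K_out = 2`), with a greater tissue
  diffusion range — and then set the two lineage `K_met0` values by
  calibrating the forward monolayer model to the published monolayer
  IC90s (17 µM for pure targets, 1 µM for pure activators), giving 9.3
  and 0.13 min⁻¹. The fitted ratio (~70) exceeds the ~24-fold
  reductase-probe differential because activator kill saturates in
  `K_met` (metabolism becomes uptake-limited), so the IC90 ratio is not
  the `K_met0` ratio.
* **SN30000 potency.** `K_c` defaults to 1.0 mM⁻¹ as a fitted
  placeholder; the calibration module estimates it from monolayer
  survival curves, which is also how the recovery tests exercise it.

## What the simulations reproduce

Under the defaults, the full pipeline reproduces the qualitative
structure of the reference experiments:

* SN30000: target (and activator) log kill in spheroids *decreases* as
  the activator fraction rises 0 → 10 → 50% — rapid metabolic
  consumption limits prodrug penetration, and with a non-diffusing
  cytotoxin nothing compensates. The MCL assay shows the transport side
  of the same coin: receiver AUC falls, and the inert downstream oxide
  pool rises, with activator fraction.
* PR104A, "PR104H+M" model: using only the short-range metabolite 1,
  predicted target kill *decreases* with activator fraction — the
  documented failure of that model, reproduced as such.
* PR104A, "dichloro metabolites" model: adding the stable, lipophilic
  metabolite 2 reverses the prediction — target kill *increases* with
  activator fraction (an efficient bystander effect), while metabolite
  1 dominates killing in monolayers. Metabolite-contribution
  decomposition (`decompose_metabolite_contributions()`) runs the
  counterfactuals with each potency zeroed, transport unchanged.
* Oxygen contamination: a 2.5 µM dissolved-O₂ bolus added with the
  drug leaves ~0.25–0.29 µM at the surface of a 430 µm spheroid
  (quasi-steady balance of consumption against diffusion from the
  unstirred medium) and measurably spares the outer cell ranks
  relative to a fully anoxic exposure; monolayers clear the same bolus
  much faster because of their higher cell/medium ratio.
* Spatial heterogeneity: spheroids grown from 20 seeded cells at 10%
  activators develop patchy activator distributions and show lower,
  more variable target kill than spheroids grown from dense seedings
  to the same diameter.

## Synthetic data and what passing tests mean

The synthetic-data module generates the two dataset shapes the
analysis consumes: monolayer dose–response tables (log-linear survival
with mean-corrected lognormal replicate noise, CV 0.15, censored at
the colony-count floor 10^-4.5) and MCL time courses (additive
Gaussian noise at 2% of the donor bolus, with the 100 µL
sampling-volume depletion per draw). Lognormal noise keeps synthetic
SF positive and multiplicative, matching clonogenic-assay scatter;
true parameters are embedded in the output headers so recovery studies
score themselves. The generators emulate inter-replicate scatter only
— not plating-efficiency drift, counting error structure, or
between-batch effects — so parameter-recovery results certify the
identifiability and correctness of the estimation machinery, not
performance on real assay data.

Identifiability is enforced, not just documented: in the no-depletion
limit a single lineage's monolayer curve determines only the product
`K_c * K_met0`, so the fitter refuses to free both from single-lineage
data.

## Numerical choices and limitations

* θ = 0.5, `dt = 2` s default (4 s for the long direction suites —
  results agree to 4 decimals), outer medium/oxygen updates every 60 s,
  prodrug-operator refresh at 5% `K_met` drift.
* Concentrations are clipped at zero; clip events below −1e-12 µM are
  counted and reported.
* The monolayer model resolves depth with 20 nodes (6 for fitting,
  where the well is near-well-mixed); the MCL slab uses 10 nodes; the
  spheroid medium column 12–16 nodes.
* Problem sizes in the test suite: the acceptance-style direction
  suite runs on day-4 spheroids grown from 250 seeded cells (~275 µm)
  and the heterogeneity contrast on 20- vs 2,000-cell seedings grown to
  250 µm, sizes at which the directional claims are robust; the
  acceptance script runs the reference 1,000-cell/430 µm versions.
* Limitations: no cell-cycle structure, no shedding, no
  extracellular-matrix or mechanics beyond radial displacement, no
  aerobic prodrug toxicity, no glucose dependence, and compartments
  are either well-stirred or purely diffusive. The MCL chamber is
  assumed well-stirred on both sides of the slab (the physical chamber
  is gas-stirred), and its support membrane is treated as transparent.

## A worked example

```{r example, eval = FALSE}
model <- prodrug_model("pr104a_dichloro")
lines <- model_cell_lines(model)

# monolayer dose-response and IC90
dr <- run_monolayer_assay(model, list(lines$target),
                          exposure_protocol(c(8, 12, 17, 24, 34)))
ic90(dr, "PORko-R")

# day-4 co-culture spheroid, 1-h anoxic exposure at 30 uM
sph <- grow_to_day(4, 1000, 0.5,
                   list(activator = lines$activator,
                        target = lines$target), seed = 1)
sph <- trim_lattice(sph)
ex <- simulate_spheroid_exposure(sph, model, 30, duration = 3600)
surviving_fraction(ex$cells, lineage = "PORko-R",
                   lines = sph$lines)
```
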