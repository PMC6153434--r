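parameters:
  mean_cell_volume:
    value: 2500.0
    units: um3
    provenance: ASSUMED
    cite: typical HCT116 cell size; lattice site volume is twice this
  hypoxia_threshold:
    value: 4.0
    units: uM
    provenance: PAPER
    cite: fraction of hypoxia (O2 < 4 uM)
  severe_hypoxia_threshold:
    value: 0.15
    units: uM
    provenance: PAPER
    cite: severe hypoxia (O2 < 0.15 uM)
  death_tag_delay:
    value: 24.0
    units: h
    provenance: PAPER
    cite: persists for more than 24 h, cells are 'tagged' for death
  lysis_delay:
    value: 24.0
    units: h
    provenance: ASSUMED
    cite: cells starved of oxygen eventually undergo cytolysis; delay not printed
  growth_O2_half_sat:
    value: 1.0
    units: uM
    provenance: ASSUMED
    cite: half-saturation of the O2-dependent growth-rate scaling
  medium_volume:
    value: 0.2
    units: mL
    provenance: PAPER
    cite: typically 0.2 mL
  medium_depth:
    value: 6.1
    units: mm
    provenance: PAPER
    cite: and 6.1 mm, respectively
  exposure_volume:
    value: 80.0
    units: uL
    provenance: PAPER
    cite: final volume of 80 uL/well
  well_area:
    value: 32.8
    units: mm2
    provenance: ASSUMED
    cite: medium_volume / medium_depth; 96-well footprint
  monolayer_n_cells:
    value: 100000.0
    units: cells
    provenance: PAPER
    cite: seeded at 10^5 cells/0.15 mL
  monolayer_volume:
    value: 0.15
    units: mL
    provenance: PAPER
    cite: seeded at 10^5 cells/0.15 mL
  gas_O2_growth:
    value: 200.0
    units: uM
    provenance: ASSUMED
    cite: air-equilibrated medium under 5% CO2
  o2_bolus:
    value: 2.5
    units: uM
    provenance: PAPER
    cite: initial average oxygen concentration ... was 2.5 uM
  mcl_thickness:
    value: 150.0
    units: um
    provenance: ASSUMED
    cite: chamber dimensions not printed
  mcl_compartment_volume:
    value: 8.5
    units: mL
    provenance: ASSUMED
    cite: donor/receiver volumes not printed
  mcl_area:
    value: 0.3
    units: cm2
    provenance: ASSUMED
    cite: exposed MCL area not printed
  mcl_donor_bolus:
    value: 100.0
    units: uM
    provenance: PAPER
    cite: SN30000 (100 uM) ... added to the donor compartment
  O2_D_medium:
    value: 2000.0
    units: um2/s
    provenance: ASSUMED
    cite: O2 diffusivity in medium
  O2_D_tissue:
    value: 1700.0
    units: um2/s
    provenance: ASSUMED
    cite: O2 diffusivity in tissue
  O2_Vmax:
    value: 6.0e-17
    units: mol/cell/s
    provenance: ASSUMED
    cite: maximal per-cell O2 consumption
  O2_Km:
    value: 1.3
    units: uM
    provenance: ASSUMED
    cite: O2 consumption half-saturation
  doubling_time_POR-G:
    value: 38.0
    units: h
    provenance: PAPER
    cite: doubling times of 38 h for POR-G
  doubling_time_POR-R:
    value: 31.0
    units: h
    provenance: PAPER
    cite: 31 h for the other cell lines
  doubling_time_PORko-R:
    value: 31.0
    units: h
    provenance: PAPER
    cite: 31 h for the other cell lines
  doubling_time_PORko-G:
    value: 31.0
    units: h
    provenance: PAPER
    cite: 31 h for the other cell lines
  doubling_time_HCT116:
    value: 31.0
    units: h
    provenance: PAPER
    cite: 31 h for the other cell lines
  PR104A_D_medium:
    value: 400.0
    units: um2/s
    provenance: ASSUMED
    cite: prodrug diffusivity, medium
  PR104A_D_tissue:
    value: 100.0
    units: um2/s
    provenance: ASSUMED
    cite: prodrug diffusivity, tissue
  PR104A_K_in:
    value: 0.2
    units: 1/s
    provenance: ASSUMED
    cite: membrane exchange
  PR104A_K_out:
    value: 0.2
    units: 1/s
    provenance: ASSUMED
    cite: membrane exchange
  K_O2_PR104A:
    value: 0.126
    units: uM
    provenance: PAPER
    cite: (K_O2 = 0.126 uM)
  K_met0_PR104A_POR-G:
    value: 9.3
    units: 1/min
    provenance: FITTED
    cite: calibrated so the monolayer IC90 of pure activators is ~1 uM
  K_met0_PR104A_PORko-R:
    value: 0.13
    units: 1/min
    provenance: FITTED
    cite: calibrated so the monolayer IC90 of pure targets is ~17 uM
  PR104HM_D_medium:
    value: 400.0
    units: um2/s
    provenance: ASSUMED
    cite: metabolite 1 diffusivity
  PR104HM_D_tissue:
    value: 100.0
    units: um2/s
    provenance: ASSUMED
    cite: metabolite 1 diffusivity
  PR104HM_K_in:
    value: 0.003
    units: 1/s
    provenance: ASSUMED
    cite: metabolite 1 membrane exchange
  PR104HM_K_out:
    value: 0.003
    units: 1/s
    provenance: ASSUMED
    cite: metabolite 1 membrane exchange
  PR104HM_k_loss_cell:
    value: 0.001
    units: 1/s
    provenance: ASSUMED
    cite: intracellular reactions of the Br/mesylate mustards
  PR104HM_k_decay_medium:
    value: 0.0005
    units: 1/s
    provenance: ASSUMED
    cite: instability of PR104H in medium (t1/2 ~ 23 min)
  K_c_PR104HM:
    value: 0.092
    units: 1/mM/s
    provenance: PAPER
    cite: (0.092 mM-1s-1 for PR104H)
  PR104HM_k_convert:
    value: 0.001
    units: 1/s
    provenance: ASSUMED
    cite: chloride displacement of the mustard leaving groups
  dichloro_D_medium:
    value: 400.0
    units: um2/s
    provenance: ASSUMED
    cite: metabolite 2 diffusivity
  dichloro_D_tissue:
    value: 150.0
    units: um2/s
    provenance: ASSUMED
    cite: greater tissue diffusion range of the dichloro mustards
  dichloro_K_in:
    value: 0.1
    units: 1/s
    provenance: ASSUMED
    cite: lipophilic partitioning (K_in/K_out = 2)
  dichloro_K_out:
    value: 0.05
    units: 1/s
    provenance: ASSUMED
    cite: lipophilic partitioning (K_in/K_out = 2)
  dichloro_k_loss_cell:
    value: 0.0005
    units: 1/s
    provenance: ASSUMED
    cite: fourfold longer half-life than PR104H
  dichloro_k_decay_medium:
    value: 0.000125
    units: 1/s
    provenance: ASSUMED
    cite: fourfold longer half-life than PR104H
  K_c_dichloro:
    value: 0.05
    units: 1/mM/s
    provenance: PAPER
    cite: Fitting the potency parameter K_c for metabolite 2 gave an estimate of 0.05
      mM-1s-1
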