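# Synthetic population PK parameter sets for chloroquine simulation.
#
# These are NOT the published NONMEM estimates: they are stand-in values with
# the published models' structural form (2-compartment whole-blood /
# 3-compartment plasma disposition, transit-compartment absorption,
# log-normal between-subject variability, allometric scaling from 70 kg),
# calibrated once so that the typical 70 kg whole-blood simulation reproduces
# reported exposure summaries for the simulated regimens (median C_max of
# ~10.7 umol/L under 600 mg base twice daily for 10 days; ~3x lower under the
# 3-day malaria regimen; plasma clearance ~4x whole-blood clearance so the
# two matrices agree in the median under the whole blood:plasma ratio of 4,
# with a narrower healthy-volunteer plasma spread). See the package vignette.
#
# Units: clearances L/h, volumes L, MTT h, F dimensionless (dose fraction).
molar_mass_g_mol: 319.87
models:
  whole_blood_2cpt:
    matrix: whole_blood
    provenance: >
      Synthetic stand-in, calibrated to reported whole-blood exposure
      summaries in adults; not the published malaria-patient estimates.
    ref_weight_kg: 70
    n_transit: 6
    theta:
      CL: 11.9
      VC: 600.0
      Q: 80.0
      VP: 1500.0
      MTT: 2.0
      F: 1.0
    omega:
      CL: 0.22
      VC: 0.25
      Q: 0.25
      VP: 0.25
      MTT: 0.40
      F: 0.11
  plasma_3cpt:
    matrix: plasma
    provenance: >
      Synthetic stand-in, calibrated so plasma medians match the whole-blood
      model under the x4 partition ratio; not the unpublished
      healthy-volunteer estimates.
    ref_weight_kg: 70
    n_transit: 5
    theta:
      CL: 24.0
      VC: 2450.0
      Q1: 330.0
      VP1: 5500.0
      Q2: 30.0
      VP2: 18000.0
      MTT: 1.5
      F: 1.0
    omega:
      CL: 0.12
      VC: 0.15
      Q1: 0.15
      VP1: 0.15
      Q2: 0.15
      VP2: 0.15
      MTT: 0.25
      F: 0.05
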