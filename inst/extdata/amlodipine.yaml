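# Amlodipine (as besylate) — simulation input parameters.
# Dose is the free-base-equivalent label strength; the besylate molecular
# weight is used only where molar quantities are needed.
name: amlodipine
molecular_weight_g_mol: 567.051
log_d: 2.66
log_d_ph: 7.4
pka_values: [8.7]
pka_species: base
ref_solubility_mg_ml: 0.774
ref_solubility_ph: 7.4
peff_cm_s: 0.0743e-4
peff_assay: caco2
dose_mg: 5
dose_volume_ml: 250
mean_precipitation_time_s: 900
diffusion_coefficient_cm2_s: 4.2e-8
particle_density_g_ml: 1.2
particle_radius_um: 25
blood_plasma_ratio: 1
fraction_unbound_pct: 2
clearance_l_h: 28
vc_l_kg: 17
half_life_h: 27.03
body_weight_kg: 70
simulation_time_h: 144
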