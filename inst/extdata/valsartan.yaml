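# Valsartan — simulation input parameters.
# Clearance is not usable as printed in the source table and is derived
# from Vc and the elimination half-life (one-compartment relation).
name: valsartan
molecular_weight_g_mol: 435.53
log_d: -0.34
log_d_ph: 7.0
pka_values: [3.9, 4.73]
pka_species: acid
ref_solubility_mg_ml: 16.8
ref_solubility_ph: 8.0
peff_cm_s: 0.262e-4
peff_assay: rat
dose_mg: 80
dose_volume_ml: 250
mean_precipitation_time_s: 900
diffusion_coefficient_cm2_s: 1.1e-8
particle_density_g_ml: 1.2
particle_radius_um: 25
blood_plasma_ratio: 1
fraction_unbound_pct: 5
# Disposition is biphasic (two-compartment); the 0.23 L/kg distribution
# volume is the steady-state volume, which with the printed half-life
# gives CL = ln2*Vss/t_half = 2.0 L/h in the fast-distribution limit.
# Central volume 0.08 L/kg with inter-compartmental clearance 4.5 L/h
# (k12 = Q/V1, k21 = Q/V2, Vss = V1 + V2) reconstructs the distribution
# (~0.5 h) and terminal (~7 h) phases reported for intravenous dosing.
vc_l_kg: 0.23
vc_central_l_kg: 0.08
k12_per_h: 0.8036
k21_per_h: 0.4286
half_life_h: 5.58
body_weight_kg: 70
simulation_time_h: 72
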