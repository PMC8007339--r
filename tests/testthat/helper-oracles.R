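# Independent oracle implementations and small fixture builders used across
# the test files.  These deliberately re-derive quantities by direct formula
# evaluation, separate from the package's code paths.

# f1/f2 by direct transcription of the defining formulas
oracle_f1 <- function(r, t) 100 * sum(abs(r - t)) / sum(r)
oracle_f2 <- function(r, t) {
  50 * log10(100 / sqrt(1 + sum((r - t)^2) / length(r)))
}

# Bateman curve, ng/mL
oracle_bateman <- function(t, dose_mg, f, ka, cl, vc) {
  ke <- cl / vc
  f * dose_mg * 1000 / vc * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# classical closed-form fraction absorbed for a 7-compartment CAT chain
oracle_cat_fa <- function(ka, total_transit_h, n = 7) {
  1 - (1 + ka * total_transit_h / n)^(-n)
}

# a generic test drug: freely soluble weak base, one-compartment kinetics
make_test_drug <- function(peff = 2e-4, dose_mg = 10, clearance_l_h = 5,
                           vc_l_kg = 0.5, solubility = 50) {
  drug_substance(
    name = "probe", molecular_weight = 400,
    log_d = 2, log_d_ph = 7.4,
    pka_values = 9, pka_species = "base",
    ref_solubility = solubility, ref_solubility_ph = 7.4,
    peff = peff, peff_assay = "human",
    dose_mg = dose_mg, dose_volume_ml = 250,
    diffusion_coefficient_cm2_s = 8e-6,
    clearance_l_h = clearance_l_h, vc_l_kg = vc_l_kg,
    body_weight_kg = 70
  )
}

# stomach + 7 identical absorbing small-intestinal compartments, no colon;
# radius chosen so that ka = 2*Peff*3600/radius equals `ka_target`.  The
# non-absorbing stomach only delays the chain, so the closed-form Fa is
# unaffected by its transit time (kept short but grid-resolvable).
make_cat_physiology <- function(peff, ka_target, total_transit_h = 3.3) {
  radius <- 2 * peff * 3600 / ka_target
  data.frame(
    name = c("stomach", paste0("si", 1:7)),
    volume_ml = c(250, rep(100, 7)),
    ph = c(1.3, rep(6.5, 7)),
    transit_time_h = c(0.1, rep(total_transit_h / 7, 7)),
    radius_cm = c(10, rep(radius, 7)),
    absorption_scale_factor = c(0, rep(1, 7)),
    absorbing = c(FALSE, rep(TRUE, 7)),
    stringsAsFactors = FALSE
  )
}

solution_config <- function(duration_h = 24, step = 0.05, ...) {
  simulation_config(duration_h = duration_h, output_step_h = step,
                    dissolution_mode = "solution", asf_model = "none", ...)
}

table3_profiles <- function(drug) reference_dissolution(drug)
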