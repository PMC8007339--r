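#' Define a drug substance
#'
#' Collects the physicochemical, biopharmaceutic and pharmacokinetic
#' parameters that drive the gastrointestinal absorption simulator and the
#' disposition model.  Units are carried in the argument names.
#'
#' @param name Drug name.
#' @param molecular_weight Molecular weight, g/mol (salt form if the dose is
#'   expressed on a salt basis; here label doses are free-base/free-acid).
#' @param log_d Partition/distribution coefficient at `log_d_ph`.
#' @param log_d_ph pH at which `log_d` was measured.
#' @param pka_values Numeric vector of pKa values (ordered).
#' @param pka_species Either `"acid"` or `"base"`, applied to all sites
#'   (monoprotic base or polyprotic acid are the supported ionization
#'   patterns), or a character vector, one tag per site.
#' @param ref_solubility Aqueous solubility, mg/mL, at `ref_solubility_ph`.
#' @param ref_solubility_ph pH of the reference solubility measurement.
#' @param peff Effective intestinal permeability, cm/s.
#' @param peff_assay Assay the permeability comes from: `"human"`, `"caco2"`
#'   or `"rat"`.
#' @param dose_mg Dose, mg (label strength, free-form equivalent).
#' @param dose_volume_ml Volume of fluid taken with the dose, mL.
#' @param mean_precipitation_time_s First-order time constant with which a
#'   supersaturated lumen reverts to solid, s.
#' @param diffusion_coefficient_cm2_s Aqueous diffusion coefficient, cm2/s.
#' @param particle_density_g_ml Density of the solid particles, g/mL.
#' @param particle_radius_um Initial (monodisperse) particle radius, um.
#' @param blood_plasma_ratio Blood:plasma concentration ratio.
#' @param fraction_unbound_pct Percent unbound in plasma.
#' @param clearance_l_h Systemic clearance, L/h, or `NA` to derive it from
#'   `vc_l_kg` and `half_life_h` (see [derive_disposition()]).
#' @param vc_l_kg Volume of distribution, L/kg.  For a one-compartment
#'   drug this is the central (= total) volume; when distribution
#'   micro-constants are supplied it is read as the steady-state volume and
#'   `vc_central_l_kg` carries the central volume.
#' @param vc_central_l_kg Central volume, L/kg, for a two-compartment drug
#'   (required when `k12_per_h`/`k21_per_h` are given).
#' @param half_life_h Elimination half-life, h.
#' @param body_weight_kg Body weight, kg.
#' @param k12_per_h,k21_per_h Optional two-compartment distribution
#'   micro-constants, 1/h.  When both are supplied the disposition model is
#'   two-compartmental.
#'
#' @return An object of class `drug_substance`.
#' @seealso [amlodipine()], [valsartan()], [solubility_at_ph()]
#' @export
drug_substance <- function(name,
                           molecular_weight,
                           log_d = NA_real_,
                           log_d_ph = NA_real_,
                           pka_values,
                           pka_species,
                           ref_solubility,
                           ref_solubility_ph,
                           peff,
                           peff_assay = c("human", "caco2", "rat"),
                           dose_mg,
                           dose_volume_ml = 250,
                           mean_precipitation_time_s = 900,
                           diffusion_coefficient_cm2_s,
                           particle_density_g_ml = 1.2,
                           particle_radius_um = 25,
                           blood_plasma_ratio = 1,
                           fraction_unbound_pct = 100,
                           clearance_l_h = NA_real_,
                           vc_l_kg,
                           vc_central_l_kg = NA_real_,
                           half_life_h = NA_real_,
                           body_weight_kg = 70,
                           k12_per_h = NA_real_,
                           k21_per_h = NA_real_) {
  peff_assay <- match.arg(peff_assay)
  stopifnot(
    is.character(name), length(name) == 1L,
    molecular_weight > 0,
    dose_mg >= 0,
    ref_solubility > 0,
    peff >= 0,
    particle_density_g_ml > 0,
    diffusion_coefficient_cm2_s > 0,
    dose_volume_ml > 0,
    mean_precipitation_time_s > 0,
    particle_radius_um > 0,
    body_weight_kg > 0
  )
  pka_values <- as.numeric(pka_values)
  if (length(pka_values) < 1L)
    stop("pka_values must be non-empty for an ionizable drug", call. = FALSE)
  pka_species <- match.arg(pka_species[1L], c("acid", "base"))
  n_avail <- sum(!is.na(c(clearance_l_h, vc_l_kg, half_life_h)))
  if (n_avail < 2L)
    stop("at least two of clearance, Vc and half-life are required",
         call. = FALSE)
  if (xor(is.na(k12_per_h), is.na(k21_per_h)))
    stop("k12 and k21 must be supplied together", call. = FALSE)
  if (!is.na(k12_per_h) && is.na(vc_central_l_kg))
    stop("a two-compartment drug needs vc_central_l_kg (vc_l_kg is then ",
         "the steady-state volume)", call. = FALSE)
  structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      log_d = log_d,
      log_d_ph = log_d_ph,
      pka_values = pka_values,
      pka_species = pka_species,
      ref_solubility = ref_solubility,
      ref_solubility_ph = ref_solubility_ph,
      peff = peff,
      peff_assay = peff_assay,
      dose_mg = dose_mg,
      dose_volume_ml = dose_volume_ml,
      mean_precipitation_time_s = mean_precipitation_time_s,
      diffusion_coefficient_cm2_s = diffusion_coefficient_cm2_s,
      particle_density_g_ml = particle_density_g_ml,
      particle_radius_um = particle_radius_um,
      blood_plasma_ratio = blood_plasma_ratio,
      fraction_unbound_pct = fraction_unbound_pct,
      clearance_l_h = clearance_l_h,
      vc_l_kg = vc_l_kg,
      vc_central_l_kg = vc_central_l_kg,
      half_life_h = half_life_h,
      body_weight_kg = body_weight_kg,
      k12_per_h = k12_per_h,
      k21_per_h = k21_per_h
    ),
    class = "drug_substance"
  )
}

#' @export
print.drug_substance <- function(x, ...) {
  cat(sprintf("<drug_substance> %s\n", x$name))
  cat(sprintf("  MW %.3f g/mol | %s, pKa %s\n", x$molecular_weight,
              x$pka_species, paste(x$pka_values, collapse = "/")))
  cat(sprintf("  solubility %.4g mg/mL at pH %.2f | Peff %.3e cm/s (%s)\n",
              x$ref_solubility, x$ref_solubility_ph, x$peff, x$peff_assay))
  cat(sprintf("  dose %g mg in %g mL | CL %s L/h, Vc %g L/kg, t1/2 %s h\n",
              x$dose_mg, x$dose_volume_ml,
              ifelse(is.na(x$clearance_l_h), "(derived)",
                     format(x$clearance_l_h)),
              x$vc_l_kg,
              ifelse(is.na(x$half_life_h), "(derived)",
                     format(x$half_life_h))))
  invisible(x)
}

## Ionization factor I(pH): total/unionized concentration ratio.
## Monoprotic base: 1 + 10^(pKa - pH).
## Polyprotic acid: 1 + 10^(pH - pKa1) + 10^(2 pH - pKa1 - pKa2) + ...
ionization_factor <- function(ph, pka_values, species) {
  pka_values <- sort(pka_values)
  if (species == "base") {
    if (length(pka_values) != 1L)
      stop("only monoprotic bases are supported", call. = FALSE)
    1 + 10^(pka_values - ph)
  } else if (species == "acid") {
    k <- seq_along(pka_values)
    1 + sum(10^(k * ph - cumsum(pka_values)))
  } else {
    stop("unknown ionization species tag: ", species, call. = FALSE)
  }
}

#' pH-dependent solubility
#'
#' Henderson-Hasselbalch scaling of the reference solubility, capped at a
#' maximum solubilization ratio.  The intrinsic (unionized) solubility is
#' back-calculated from the reference measurement so that
#' `solubility_at_ph(drug, drug$ref_solubility_ph)` returns the reference
#' value exactly.
#'
#' @param drug A [drug_substance()].
#' @param ph pH at which solubility is required (scalar or vector, 1-9).
#' @param sr_max Maximum solubilization ratio relative to the intrinsic
#'   solubility (cap on the Henderson-Hasselbalch factor).  The default of
#'   1000 reflects the roughly thousand-fold solubility gain reported for
#'   carboxylic-acid drugs such as valsartan between pH 4 and 6; an uncapped
#'   factor would imply physically absurd intrinsic solubilities.
#'
#' @return Solubility in mg/mL (vectorized over `ph`).
#' @export
solubility_at_ph <- function(drug, ph, sr_max = 1000) {
  stopifnot(inherits(drug, "drug_substance"))
  if (!is.numeric(sr_max) || length(sr_max) != 1L || sr_max < 1)
    stop("sr_max must be a single number >= 1", call. = FALSE)
  if (any(ph < 1 | ph > 9))
    stop("ph must lie in [1, 9]", call. = FALSE)
  hh <- function(p) vapply(p, ionization_factor, numeric(1L),
                           pka_values = drug$pka_values,
                           species = drug$pka_species)
  s0 <- drug$ref_solubility / min(hh(drug$ref_solubility_ph), sr_max)
  s0 * pmin(hh(ph), sr_max)
}

#' Effective human permeability
#'
#' Converts an assay permeability to the human jejunal scale through a
#' per-assay multiplicative factor.  The default factor is 1 for every assay:
#' the bundled parameter tables list the assay values directly under the
#' human-permeability input, so identity is the faithful default.  A
#' user-supplied linear scale per assay is permitted.
#'
#' @param drug A [drug_substance()].
#' @param conversion Named numeric vector mapping assay name to scale factor.
#' @return Effective permeability, cm/s.
#' @export
effective_permeability <- function(drug,
                                   conversion = c(human = 1, caco2 = 1,
                                                  rat = 1)) {
  stopifnot(inherits(drug, "drug_substance"))
  if (!(drug$peff_assay %in% names(conversion)))
    stop("no conversion factor for assay: ", drug$peff_assay, call. = FALSE)
  f <- conversion[[drug$peff_assay]]
  if (is.na(f))
    stop("no conversion factor for assay: ", drug$peff_assay, call. = FALSE)
  if (f < 0) stop("conversion factor must be non-negative", call. = FALSE)
  drug$peff * f
}

#' Distribution coefficient at an arbitrary pH
#'
#' Shifts the measured logD to another pH assuming only the unionized
#' species partitions: `logD(pH) = logD(ref) + log10(I(ref)/I(pH))` where
#' `I` is the Henderson-Hasselbalch ionization factor.  Used by the
#' absorption-scale-factor model.
#'
#' @param drug A [drug_substance()].
#' @param ph Target pH (vectorized).
#' @return logD at `ph`.
#' @export
log_d_at_ph <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_substance"))
  if (is.na(drug$log_d) || is.na(drug$log_d_ph))
    stop("drug has no reference logD measurement", call. = FALSE)
  i_ref <- ionization_factor(drug$log_d_ph, drug$pka_values, drug$pka_species)
  i_ph <- vapply(ph, ionization_factor, numeric(1L),
                 pka_values = drug$pka_values, species = drug$pka_species)
  drug$log_d + log10(i_ref / i_ph)
}

read_drug_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  drug_substance(
    name = y$name,
    molecular_weight = y$molecular_weight_g_mol,
    log_d = y$log_d,
    log_d_ph = y$log_d_ph,
    pka_values = unlist(y$pka_values),
    pka_species = y$pka_species,
    ref_solubility = y$ref_solubility_mg_ml,
    ref_solubility_ph = y$ref_solubility_ph,
    peff = y$peff_cm_s,
    peff_assay = y$peff_assay,
    dose_mg = y$dose_mg,
    dose_volume_ml = y$dose_volume_ml,
    mean_precipitation_time_s = y$mean_precipitation_time_s,
    diffusion_coefficient_cm2_s = y$diffusion_coefficient_cm2_s,
    particle_density_g_ml = y$particle_density_g_ml,
    particle_radius_um = y$particle_radius_um %||% 25,
    blood_plasma_ratio = y$blood_plasma_ratio,
    fraction_unbound_pct = y$fraction_unbound_pct,
    clearance_l_h = y$clearance_l_h %||% NA_real_,
    vc_l_kg = y$vc_l_kg,
    vc_central_l_kg = y$vc_central_l_kg %||% NA_real_,
    k12_per_h = y$k12_per_h %||% NA_real_,
    k21_per_h = y$k21_per_h %||% NA_real_,
    half_life_h = y$half_life_h %||% NA_real_,
    body_weight_kg = y$body_weight_kg
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled reference drugs
#'
#' The two actives of the 5/80 mg amlodipine/valsartan combination product,
#' parameterized from the published simulation-input table: amlodipine a
#' monoprotic base (pKa 8.7, dosed 5 mg free-base equivalent, besylate MW
#' used only for molar quantities) and valsartan a diprotic carboxylic acid
#' (pKa 3.9/4.73, dosed 80 mg).  Valsartan's clearance entry is not usable
#' as printed and is left to be derived from Vc and the half-life
#' ([derive_disposition()]).
#'
#' @return A [drug_substance()].
#' @export
amlodipine <- function() {
  read_drug_yaml(system.file("extdata", "amlodipine.yaml",
                             package = "suspeq", mustWork = TRUE))
}

#' @rdname amlodipine
#' @export
valsartan <- function() {
  read_drug_yaml(system.file("extdata", "valsartan.yaml",
                             package = "suspeq", mustWork = TRUE))
}
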