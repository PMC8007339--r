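#' Observed reference pharmacokinetics of the source tablet
#'
#' The published in vivo Cmax (ng/mL) and AUC(0-inf) (ng*h/mL) of both
#' actives after the 5/80 mg immediate-release combination tablet, used for
#' percent-prediction-error verification of the simulation.
#'
#' @param drug `"amlodipine"` or `"valsartan"`.
#' @return A list with `cmax_ng_ml` and `auc_0_inf`.
#' @export
observed_tablet_pk <- function(drug = c("amlodipine", "valsartan")) {
  drug <- match.arg(drug)
  obs <- jsonlite::read_json(system.file("extdata", "observed_pk.json",
                                         package = "suspeq",
                                         mustWork = TRUE),
                             simplifyVector = TRUE)
  as.list(obs[[drug]])
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the drug, the dosage form
#' to simulate, the dissolution profiles of both products (reference tablet
#' and test suspension) per medium, optional physiology/disposition
#' overrides, the observed pharmacokinetics for verification, and optional
#' virtual-bioequivalence settings.
#'
#' @param drug A [drug_substance()].
#' @param dosage_form `"ir_tablet"` or `"ir_suspension"` — which product's
#'   dissolution drives the simulated absorption.
#' @param reference_profiles,test_profiles Lists of
#'   [dissolution_profile()]s (tablet and suspension respectively), one per
#'   medium.
#' @param observed Optional list with `cmax_ng_ml`, `auc_0_inf` for percent
#'   prediction error.
#' @param physiology Optional physiology override
#'   (default [default_fasted_physiology()]).
#' @param disposition Optional `disposition_params` override (default
#'   [derive_disposition()] on the drug).
#' @param duration_h Simulation time, h (default 144 for amlodipine, 72 for
#'   valsartan, else 72).
#' @param output_step_h Output grid step, h.
#' @param vbe Optional list with `n_subjects`, `seed` and optional
#'   `variability` enabling the virtual-bioequivalence stage (the seed is
#'   mandatory there).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(drug,
                            dosage_form = c("ir_tablet", "ir_suspension"),
                            reference_profiles, test_profiles,
                            observed = NULL, physiology = NULL,
                            disposition = NULL, duration_h = NULL,
                            output_step_h = 0.05, vbe = NULL) {
  dosage_form <- match.arg(dosage_form)
  stopifnot(inherits(drug, "drug_substance"),
            length(reference_profiles) >= 1, length(test_profiles) >= 1)
  if (is.null(duration_h))
    duration_h <- switch(drug$name, amlodipine = 144, valsartan = 72, 72)
  if (!is.null(vbe) && is.null(vbe$seed))
    stop("vbe settings must carry a seed (stochastic stage)", call. = FALSE)
  structure(
    list(drug = drug, dosage_form = dosage_form,
         reference_profiles = reference_profiles,
         test_profiles = test_profiles, observed = observed,
         physiology = physiology, disposition = disposition,
         duration_h = duration_h, output_step_h = output_step_h,
         vbe = vbe),
    class = "pipeline_config"
  )
}

#' Run the full equivalence pipeline
#'
#' Executes, in order: dissolution comparison (f1/f2 and release
#' classification per medium), gastrointestinal absorption simulation
#' driven by the selected product's tabulated dissolution, compartmental
#' disposition, non-compartmental analysis, percent-prediction-error
#' verification against the observed values, and (optionally) Monte-Carlo
#' virtual bioequivalence of suspension vs tablet.  When `out_dir` is
#' given, writes `plasma.csv`, `pk_parameters.json`, `evaluation.json` and
#' `summary.txt` there; partial outputs are preserved if a later stage
#' fails.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Log each stage to the console.
#' @return An object of class `suspeq_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  report <- list(drug = config$drug$name, dosage_form = config$dosage_form)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  result <- tryCatch({
    stage <- "dissolution"
    say("stage %s: f1/f2 and release classification", stage)
    media <- vapply(config$reference_profiles, `[[`, numeric(1L),
                    "medium_ph")
    diss <- lapply(seq_along(config$reference_profiles), function(i) {
      r <- config$reference_profiles[[i]]
      t_ <- config$test_profiles[[which(vapply(config$test_profiles,
                                               `[[`, numeric(1L),
                                               "medium_ph") == media[i])]]
      f1 <- f1_difference(r, t_)
      f2 <- f2_similarity(r, t_)
      list(medium_ph = media[i], f1 = f1, f2 = f2,
           verdict = similarity_verdict(f1, f2),
           release_reference = classify_release(r),
           release_test = classify_release(t_))
    })
    report$dissolution <- diss

    stage <- "absorption"
    sim_profiles <- if (config$dosage_form == "ir_tablet")
      config$reference_profiles else config$test_profiles
    sim_cfg <- simulation_config(
      duration_h = config$duration_h,
      output_step_h = config$output_step_h,
      dissolution_mode = "tabulated",
      tabulated_profiles = sim_profiles)
    say("stage %s: %s, %g h", stage, config$dosage_form, config$duration_h)
    asim <- simulate_absorption(
      config$drug,
      config$physiology %||% default_fasted_physiology(),
      sim_cfg)
    report$fraction_absorbed <- asim$fa
    report$mass_balance_error_mg <- asim$mass_balance_error

    stage <- "disposition"
    disp <- config$disposition %||% derive_disposition(config$drug)
    say("stage %s: %d-compartment, CL %.3g L/h", stage,
        disp$n_compartments, disp$clearance_l_h)
    prof <- simulate_disposition(asim, disp,
                                 step_h = config$output_step_h)
    report$disposition <- disp
    report$plasma <- prof

    stage <- "nca"
    params <- nca(prof)
    report$pk_parameters <- params
    say("stage %s: Cmax %.4g ng/mL, AUCinf %.6g ng*h/mL", stage,
        params$cmax_ng_ml, params$auc_0_inf)

    stage <- "prediction_error"
    if (!is.null(config$observed)) {
      report$prediction_error <- list(
        cmax = percent_prediction_error(params$cmax_ng_ml,
                                        config$observed$cmax_ng_ml,
                                        parameter = "cmax"),
        auc_inf = percent_prediction_error(params$auc_0_inf,
                                           config$observed$auc_0_inf,
                                           parameter = "auc_inf"))
      say("stage %s: |%%PE| Cmax %.2f, AUC %.2f", stage,
          report$prediction_error$cmax$pe_abs_pct,
          report$prediction_error$auc_inf$pe_abs_pct)
    }

    stage <- "virtual_be"
    if (!is.null(config$vbe) && config$drug$dose_mg > 0) {
      mk <- function(profiles) list(
        drug = config$drug,
        physiology = config$physiology,
        disposition = config$disposition,
        config = simulation_config(
          duration_h = config$duration_h,
          output_step_h = config$output_step_h,
          dissolution_mode = "tabulated",
          tabulated_profiles = profiles))
      say("stage %s: n=%d seed=%d", stage, config$vbe$n_subjects %||% 24,
          config$vbe$seed)
      report$bioequivalence <- virtual_bioequivalence(
        test_config = mk(config$test_profiles),
        reference_config = mk(config$reference_profiles),
        variability = config$vbe$variability %||%
          c(clearance = 20, vc = 20, stomach_transit = 20, peff = 20),
        n_subjects = config$vbe$n_subjects %||% 24,
        seed = config$vbe$seed)
    }
    report
  }, error = function(e) {
    report$error <- list(stage = stage, message = conditionMessage(e))
    report
  })

  class(result) <- "suspeq_report"
  if (!is.null(out_dir)) write_report(result, out_dir, config)
  result
}

report_eval_list <- function(x, config) {
  ev <- list(
    drug = x$drug, dosage_form = x$dosage_form,
    dissolution = x$dissolution,
    fraction_absorbed = x$fraction_absorbed,
    mass_balance_error_mg = x$mass_balance_error_mg,
    resolved_config = list(
      duration_h = config$duration_h,
      output_step_h = config$output_step_h,
      dose_mg = config$drug$dose_mg,
      clearance_l_h = x$disposition$clearance_l_h %||% NA,
      vc_l = x$disposition$vc_l %||% NA,
      n_compartments = x$disposition$n_compartments %||% NA,
      vbe_seed = config$vbe$seed %||% NA))
  if (!is.null(x$prediction_error))
    ev$prediction_error <- lapply(x$prediction_error, unclass)
  if (!is.null(x$bioequivalence))
    ev$bioequivalence <- as.data.frame(x$bioequivalence)
  if (!is.null(x$error)) ev$error <- x$error
  ev
}

write_report <- function(x, out_dir, config) {
  if (!is.null(x$plasma))
    write_plasma_csv(x$plasma, file.path(out_dir, "plasma.csv"))
  if (!is.null(x$pk_parameters))
    jsonlite::write_json(unclass(x$pk_parameters),
                         file.path(out_dir, "pk_parameters.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report_eval_list(x, config),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(utils::capture.output(print(x)),
             file.path(out_dir, "summary.txt"))
  invisible(x)
}

#' @export
print.suspeq_report <- function(x, ...) {
  cat(sprintf("== suspeq pipeline report: %s (%s) ==\n",
              x$drug, x$dosage_form))
  if (!is.null(x$dissolution)) {
    cat("dissolution similarity (tablet = reference, suspension = test):\n")
    for (d in x$dissolution)
      cat(sprintf("  pH %-4.1f f1 %5.2f  f2 %6.2f  %s | release ref/test: %s/%s\n",
                  d$medium_ph, d$f1, d$f2, d$verdict,
                  d$release_reference, d$release_test))
  }
  if (!is.null(x$fraction_absorbed))
    cat(sprintf("fraction absorbed: %.4f (mass-balance error %.2g mg)\n",
                x$fraction_absorbed, x$mass_balance_error_mg))
  if (!is.null(x$pk_parameters)) {
    p <- x$pk_parameters
    cat(sprintf("PK: Cmax %.4g ng/mL at %.3g h | AUC(0-inf) %.6g ng*h/mL\n",
                p$cmax_ng_ml, p$tmax_h, p$auc_0_inf))
  }
  if (!is.null(x$prediction_error)) {
    cat("prediction error vs observed:\n")
    for (pe in x$prediction_error)
      cat(sprintf("  %-8s predicted %.6g vs observed %.6g -> |%%PE| %.2f\n",
                  pe$parameter, pe$predicted, pe$observed, pe$pe_abs_pct))
  }
  if (!is.null(x$bioequivalence)) print(x$bioequivalence)
  if (!is.null(x$error))
    cat(sprintf("ERROR in stage '%s': %s\n", x$error$stage,
                x$error$message))
  invisible(x)
}
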