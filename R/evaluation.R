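#' Percent prediction error
#'
#' `%PE = (predicted - observed) / observed * 100`.  Both the signed value
#' and its magnitude are returned (model-verification tables conventionally
#' report magnitudes).
#'
#' @param predicted Model-predicted value.
#' @param observed Observed (in vivo) value; must be non-zero.
#' @param parameter Optional parameter name for reporting.
#' @return An object of class `pe_result` with fields `parameter`,
#'   `predicted`, `observed`, `pe_pct` (signed), `pe_abs_pct`.
#' @export
percent_prediction_error <- function(predicted, observed, parameter = "") {
  if (any(observed == 0))
    stop("percent prediction error is undefined for observed == 0",
         call. = FALSE)
  pe <- (predicted - observed) / observed * 100
  structure(
    list(parameter = parameter, predicted = predicted, observed = observed,
         pe_pct = pe, pe_abs_pct = abs(pe)),
    class = "pe_result"
  )
}

#' @export
print.pe_result <- function(x, ...) {
  cat(sprintf("<pe_result> %s predicted %.6g vs observed %.6g: %%PE %+.3f (|%%PE| %.3f)\n",
              x$parameter, x$predicted, x$observed, x$pe_pct, x$pe_abs_pct))
  invisible(x)
}

#' Bioequivalence verdict from a 90\% confidence interval
#'
#' Pass if and only if the whole interval lies within the 80-125\% window.
#'
#' @param ci_lo,ci_hi Confidence-interval bounds, percent.
#' @return `"pass"` or `"fail"`.
#' @export
be_verdict <- function(ci_lo, ci_hi) {
  stopifnot(ci_lo <= ci_hi)
  if (ci_lo >= 80 && ci_hi <= 125) "pass" else "fail"
}

#' Monte-Carlo virtual bioequivalence
#'
#' Simulates a virtual crossover: for each subject, lognormal multipliers
#' (median 1, given CV) are drawn for the parameters in `variability` and
#' the SAME multipliers perturb the test and the reference configuration;
#' both full absorption + disposition simulations are run; per-subject log
#' ratios of Cmax and AUC(0-inf) (test/reference) yield the geometric mean
#' ratio with its 90\% confidence interval from the t distribution.
#'
#' Recognized variability parameters: `clearance`, `vc`, `stomach_transit`,
#' `peff` (CV in percent).  The whole run is reproducible for a fixed seed.
#'
#' @param test_config,reference_config Lists with elements `drug`
#'   ([drug_substance()]), `config` ([simulation_config()]), and optional
#'   `physiology` and `disposition`.
#' @param variability Named numeric vector of CVs in percent.
#' @param n_subjects Number of virtual subjects (>= 2).
#' @param seed Integer seed (mandatory: virtual bioequivalence is a
#'   stochastic stage).
#' @param conf_level Confidence level (default 0.90).
#' @return An object of class `be_result`: a data frame with one row per
#'   metric (`cmax`, `auc_inf`) holding `gmr_pct`, `ci90_lo_pct`,
#'   `ci90_hi_pct`, `n_subjects`, `seed`, `verdict`, plus the per-subject
#'   ratios in the `"subject_ratios"` attribute.
#' @export
virtual_bioequivalence <- function(test_config, reference_config,
                                   variability = c(clearance = 20, vc = 20,
                                                   stomach_transit = 20,
                                                   peff = 20),
                                   n_subjects = 24, seed,
                                   conf_level = 0.90) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for virtual bioequivalence", call. = FALSE)
  stopifnot(n_subjects >= 2, all(variability >= 0))
  unknown <- setdiff(names(variability),
                     c("clearance", "vc", "stomach_transit", "peff"))
  if (length(unknown))
    stop("unknown variability parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  run_one <- function(cfg, mult) {
    drug <- cfg$drug
    phys <- cfg$physiology
    if (is.null(phys)) phys <- default_fasted_physiology()
    disp <- cfg$disposition
    if (is.null(disp)) disp <- derive_disposition(drug)
    if (!is.na(mult["peff"])) drug$peff <- drug$peff * mult[["peff"]]
    if (!is.na(mult["stomach_transit"]))
      phys$transit_time_h[1L] <-
        phys$transit_time_h[1L] * mult[["stomach_transit"]]
    if (!is.na(mult["clearance"]) || !is.na(mult["vc"])) {
      cl <- disp$clearance_l_h *
        (if (is.na(mult["clearance"])) 1 else mult[["clearance"]])
      vc <- disp$vc_l * (if (is.na(mult["vc"])) 1 else mult[["vc"]])
      disp <- disposition_params(cl, vc, disp$k12_per_h, disp$k21_per_h)
    }
    sim <- simulate_absorption(drug, phys, cfg$config)
    prof <- simulate_disposition(sim, disp,
                                 step_h = cfg$config$output_step_h)
    p <- nca(prof)
    c(cmax = p$cmax_ng_ml, auc_inf = p$auc_0_inf)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  cv <- variability / 100
  sdlog <- sqrt(log(1 + cv^2))
  failures <- 0L
  ratios <- matrix(NA_real_, nrow = n_subjects, ncol = 2L,
                   dimnames = list(NULL, c("cmax", "auc_inf")))
  for (s in seq_len(n_subjects)) {
    mult <- stats::setNames(exp(stats::rnorm(length(sdlog), 0, sdlog)),
                            names(variability))
    res <- tryCatch(
      rbind(test = run_one(test_config, mult),
            ref = run_one(reference_config, mult)),
      error = function(e) NULL)
    if (is.null(res) || anyNA(res)) {
      failures <- failures + 1L
      if (failures > 0.1 * n_subjects)
        stop("more than 10% of virtual subjects failed to simulate",
             call. = FALSE)
      next
    }
    ratios[s, ] <- res["test", ] / res["ref", ]
  }
  ratios <- ratios[stats::complete.cases(ratios), , drop = FALSE]
  n_ok <- nrow(ratios)

  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - alpha / 2, df = n_ok - 1L)
  summarize <- function(r) {
    lr <- log(r)
    m <- mean(lr)
    se <- stats::sd(lr) / sqrt(length(lr))
    if (!is.finite(se)) se <- 0  # degenerate zero-variability case
    c(gmr = exp(m) * 100,
      lo = exp(m - tcrit * se) * 100,
      hi = exp(m + tcrit * se) * 100)
  }
  rows <- lapply(colnames(ratios), function(metric) {
    s <- summarize(ratios[, metric])
    data.frame(metric = metric, gmr_pct = s[["gmr"]],
               ci90_lo_pct = s[["lo"]], ci90_hi_pct = s[["hi"]],
               n_subjects = n_ok, seed = seed,
               verdict = be_verdict(s[["lo"]], s[["hi"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "subject_ratios") <- ratios
  attr(out, "conf_level") <- conf_level
  class(out) <- c("be_result", "data.frame")
  out
}

#' @export
print.be_result <- function(x, ...) {
  cat(sprintf("<be_result> %d subjects, seed %d, %.0f%% CI vs 80-125%%\n",
              x$n_subjects[1L], x$seed[1L],
              100 * (attr(x, "conf_level") %||% 0.9)))
  df <- as.data.frame(x)
  df$gmr_pct <- round(df$gmr_pct, 2)
  df$ci90_lo_pct <- round(df$ci90_lo_pct, 2)
  df$ci90_hi_pct <- round(df$ci90_hi_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Stability series assessment
#'
#' Pass when every percent-remaining value lies in `[lower, upper]`
#' (pharmacopeial 90-110\% by default; the regulatory floor for a
#' compounded suspension is 90\%).
#'
#' @param series A `stability_series` (see [stability_series()]) or a bare
#'   numeric vector of percent-remaining values.
#' @param lower,upper Acceptance band, percent.
#' @return A list: `verdict` (`"pass"`/`"fail"`), `min_pct`,
#'   `first_failing_week` (NA when passing).
#' @export
assess_stability <- function(series, lower = 90, upper = 110) {
  if (inherits(series, "stability_series")) {
    values <- series$pct_remaining
    weeks <- series$week
  } else {
    values <- as.numeric(series)
    weeks <- seq_along(values) - 1L
  }
  if (!length(values)) stop("empty stability series", call. = FALSE)
  stopifnot(all(values > 0))
  bad <- which(values < lower | values > upper)
  list(verdict = if (length(bad)) "fail" else "pass",
       min_pct = min(values),
       first_failing_week = if (length(bad)) weeks[bad[1L]] else NA)
}

#' Stability series container
#'
#' @param drug Drug name.
#' @param week Week labels (numeric, 0 = initial).
#' @param pct_remaining Percent of drug remaining at each week.
#' @return An object of class `stability_series`.
#' @export
stability_series <- function(drug, week, pct_remaining) {
  stopifnot(length(week) == length(pct_remaining), all(pct_remaining > 0))
  structure(list(drug = drug, week = week, pct_remaining = pct_remaining),
            class = "stability_series")
}

#' @export
print.stability_series <- function(x, ...) {
  cat(sprintf("<stability_series> %s\n", x$drug))
  print(data.frame(week = x$week, pct_remaining = x$pct_remaining))
  invisible(x)
}

#' Bundled four-week stability assay of the compounded suspension
#'
#' Weekly percent-remaining assays (initial through week 4, room
#' temperature) for both actives of the compounded 5/80 mg suspension.
#'
#' @param drug `"amlodipine"` or `"valsartan"`.
#' @return A [stability_series()].
#' @export
reference_stability <- function(drug = c("amlodipine", "valsartan")) {
  drug <- match.arg(drug)
  d <- utils::read.csv(system.file("extdata", "stability_suspension.csv",
                                   package = "suspeq", mustWork = TRUE))
  d <- d[d$drug == drug, ]
  stability_series(drug, d$week, d$pct_remaining)
}

#' Classify rheological behavior
#'
#' Trend of viscosity against shear rate: dilatant (shear-thickening) when
#' viscosity increases with shear rate by more than the relative tolerance,
#' pseudoplastic (shear-thinning) when it decreases, Newtonian otherwise.
#' With the handful of points a rheogram provides, the total relative
#' change is used rather than a formal trend test.
#'
#' @param shear_rates Strictly increasing shear rates, 1/s (>= 3 values).
#' @param viscosities Paired viscosities, cP.
#' @param tol Relative total-change tolerance (default 5\%).
#' @return `"dilatant"`, `"pseudoplastic"` or `"newtonian"`.
#' @export
classify_rheology <- function(shear_rates, viscosities, tol = 0.05) {
  if (length(shear_rates) < 3L || length(viscosities) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  stopifnot(length(shear_rates) == length(viscosities),
            all(diff(shear_rates) > 0), all(viscosities > 0))
  rel_change <- (viscosities[length(viscosities)] - viscosities[1L]) /
    viscosities[1L]
  if (rel_change > tol) "dilatant"
  else if (rel_change < -tol) "pseudoplastic"
  else "newtonian"
}
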