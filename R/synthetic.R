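## Synthetic-data generators: every file format and statistical structure
## the pipeline consumes can be produced in code, so the full chain is
## testable without any external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dissolution profile (Weibull release)
#'
#' Cumulative release `F(t) = f_max (1 - exp(-(t/t_d)^beta))` with
#' independent Gaussian measurement noise, clamped to [0, 110] (the assay
#' ceiling seen in practice).  The noise-free curve is strictly increasing
#' and the output is bit-reproducible per seed.
#'
#' @param f_max Plateau, percent (0 < f_max <= 110).
#' @param t_d Time scale at which 63.2\% of the plateau is released, min.
#' @param beta Weibull shape (> 0).
#' @param times_min Sampling times, min.
#' @param noise_sd Gaussian noise standard deviation, percent points.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param product,medium_ph Metadata for the resulting profile.
#' @return A [dissolution_profile()].
#' @export
gen_dissolution <- function(f_max = 100, t_d = 6, beta = 1,
                            times_min = c(5, 10, 15, 20, 30),
                            noise_sd = 0, seed = NULL,
                            product = "synthetic", medium_ph = 6.8) {
  stopifnot(f_max > 0, f_max <= 110, t_d > 0, beta > 0, noise_sd >= 0)
  f <- f_max * (1 - exp(-(times_min / t_d)^beta))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0",
                            call. = FALSE)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  f <- pmin(pmax(f, 0), 110)
  dissolution_profile(product, medium_ph, times_min, f)
}

#' Generate a synthetic oral plasma profile (Bateman kinetics)
#'
#' First-order absorption into a one-compartment model:
#' `C(t) = F D ka / (Vc (ka - ke)) (exp(-ke t) - exp(-ka t))` in ng/mL
#' (limit form when `ka == ke`), with multiplicative lognormal noise of the
#' given CV.  The noise-free curve is returned when `noise_cv = 0`.
#'
#' @param disposition A `disposition_params` (one-compartment; `ke` is
#'   `CL/Vc`).
#' @param ka_per_h First-order absorption rate constant, 1/h.
#' @param dose_mg Dose, mg.
#' @param f_abs Fraction of the dose absorbed.
#' @param times_h Sampling times, h.
#' @param noise_cv Coefficient of variation of the noise, percent.
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @param label Profile label.
#' @return A [plasma_profile()].
#' @export
gen_plasma <- function(disposition, ka_per_h, dose_mg, f_abs = 1,
                       times_h = seq(0, 72, by = 0.5), noise_cv = 0,
                       seed = NULL, label = "synthetic") {
  stopifnot(inherits(disposition, "disposition_params"),
            ka_per_h > 0, dose_mg >= 0, f_abs >= 0, f_abs <= 1,
            noise_cv >= 0)
  ke <- disposition$clearance_l_h / disposition$vc_l
  a0 <- f_abs * dose_mg / disposition$vc_l * 1000  # ng/mL
  conc <- if (abs(ka_per_h - ke) < 1e-12) {
    a0 * ke * times_h * exp(-ke * times_h)
  } else {
    a0 * ka_per_h / (ka_per_h - ke) *
      (exp(-ke * times_h) - exp(-ka_per_h * times_h))
  }
  if (noise_cv > 0) {
    if (is.null(seed)) stop("a seed is required when noise_cv > 0",
                            call. = FALSE)
    sdlog <- sqrt(log(1 + (noise_cv / 100)^2))
    conc <- with_seed(seed,
                      conc * exp(stats::rnorm(length(conc), 0, sdlog)))
  }
  plasma_profile(times_h, pmax(conc, 0), label = label)
}

#' Generate a synthetic stability series (first-order degradation)
#'
#' `A(t) = a0 exp(-k_deg t)` plus additive Gaussian assay noise,
#' reproducible per seed.
#'
#' @param a0 Initial assay, percent of label claim.
#' @param k_deg First-order degradation rate, 1/week.
#' @param weeks Assay weeks (0 = initial).
#' @param noise_sd Gaussian noise standard deviation, percent points.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param drug Drug name for the series.
#' @return A [stability_series()].
#' @export
gen_stability <- function(a0 = 100, k_deg = 0.012, weeks = 0:4,
                          noise_sd = 0, seed = NULL, drug = "synthetic") {
  stopifnot(a0 > 0, k_deg >= 0, noise_sd >= 0)
  v <- a0 * exp(-k_deg * weeks)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0",
                            call. = FALSE)
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
  }
  stability_series(drug, weeks, pmax(v, 1e-9))
}
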