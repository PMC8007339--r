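#' Derive a complete disposition parameter set
#'
#' Fills gaps among clearance, distribution volume and elimination
#' half-life using the relations `CL = ln2 * V / t_half` and
#' `t_half = ln2 * V / CL` (`V` being the drug's `vc_l_kg` volume scaled by
#' body weight).  When all three are supplied but mutually inconsistent,
#' clearance and volume are treated as primary and the discrepancy is
#' reported in the `"inconsistency"` attribute (a terminal half-life below
#' the `ln2 * V / CL` floor cannot be produced by any one- or
#' two-compartment model).  The model is one-compartmental unless the drug
#' carries distribution micro-constants `k12`/`k21`, in which case
#' `vc_l_kg` is read as the steady-state volume, the central volume comes
#' from `vc_central_l_kg`, and the half-life relation above is the
#' fast-distribution (well-stirred) limit.
#'
#' @param drug A [drug_substance()].
#' @return An object of class `disposition_params`: `clearance_l_h`,
#'   `vc_l`, `k12_per_h`, `k21_per_h`, `n_compartments`.
#' @export
derive_disposition <- function(drug) {
  stopifnot(inherits(drug, "drug_substance"))
  cl <- drug$clearance_l_h
  v <- if (is.na(drug$vc_l_kg)) NA_real_ else
    drug$vc_l_kg * drug$body_weight_kg
  t12 <- drug$half_life_h
  if (sum(!is.na(c(cl, v, t12))) < 2L)
    stop("insufficient parameters: need two of clearance, Vc, half-life",
         call. = FALSE)
  if (is.na(v))
    stop("a distribution volume is required (clearance/half-life alone ",
         "do not fix it here)", call. = FALSE)
  inconsistency <- NULL
  if (is.na(cl)) {
    cl <- log(2) * v / t12
  } else if (is.na(t12)) {
    t12 <- log(2) * v / cl
  } else {
    implied <- log(2) * v / cl
    if (abs(implied - t12) / t12 > 0.01)
      inconsistency <- sprintf(
        "printed half-life %.4g h differs from ln2*V/CL = %.4g h; CL and V taken as primary",
        t12, implied)
  }
  stopifnot(cl > 0, v > 0)
  two_cpt <- !is.na(drug$k12_per_h) && !is.na(drug$k21_per_h)
  if (two_cpt) stopifnot(drug$k12_per_h > 0, drug$k21_per_h > 0)
  vc <- if (two_cpt) drug$vc_central_l_kg * drug$body_weight_kg else v
  structure(
    list(clearance_l_h = cl, vc_l = vc,
         k12_per_h = if (two_cpt) drug$k12_per_h else 0,
         k21_per_h = if (two_cpt) drug$k21_per_h else 0,
         n_compartments = if (two_cpt) 2L else 1L,
         half_life_h = t12),
    class = "disposition_params", inconsistency = inconsistency
  )
}

#' Construct disposition parameters directly
#'
#' @param clearance_l_h Systemic clearance, L/h.
#' @param vc_l Central volume, L.
#' @param k12_per_h,k21_per_h Distribution micro-constants, 1/h (both 0 for
#'   a one-compartment model).
#' @return An object of class `disposition_params`.
#' @export
disposition_params <- function(clearance_l_h, vc_l, k12_per_h = 0,
                               k21_per_h = 0) {
  stopifnot(clearance_l_h > 0, vc_l > 0, k12_per_h >= 0, k21_per_h >= 0)
  two_cpt <- k12_per_h > 0 && k21_per_h > 0
  if (xor(k12_per_h > 0, k21_per_h > 0))
    stop("k12 and k21 must both be positive for a two-compartment model",
         call. = FALSE)
  structure(
    list(clearance_l_h = clearance_l_h, vc_l = vc_l,
         k12_per_h = k12_per_h, k21_per_h = k21_per_h,
         n_compartments = if (two_cpt) 2L else 1L,
         half_life_h = log(2) * vc_l / clearance_l_h),
    class = "disposition_params"
  )
}

#' @export
print.disposition_params <- function(x, ...) {
  cat(sprintf("<disposition_params> %d-compartment\n", x$n_compartments))
  cat(sprintf("  CL %.4g L/h | Vc %.4g L | ln2*Vc/CL = %.4g h\n",
              x$clearance_l_h, x$vc_l, log(2) * x$vc_l / x$clearance_l_h))
  if (x$n_compartments == 2L)
    cat(sprintf("  k12 %.4g /h | k21 %.4g /h\n", x$k12_per_h, x$k21_per_h))
  inc <- attr(x, "inconsistency")
  if (!is.null(inc)) cat("  note:", inc, "\n")
  invisible(x)
}

#' Plasma concentration-time profile
#'
#' @param times_h Sampling times, h, strictly increasing from 0.
#' @param conc_ng_ml Concentrations, ng/mL, non-negative.
#' @param label Profile label.
#' @return An object of class `plasma_profile`.
#' @export
plasma_profile <- function(times_h, conc_ng_ml, label = "") {
  times_h <- as.numeric(times_h); conc_ng_ml <- as.numeric(conc_ng_ml)
  if (length(times_h) != length(conc_ng_ml))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (length(times_h) && (times_h[1L] < 0 || any(diff(times_h) <= 0)))
    stop("times must be strictly increasing from 0", call. = FALSE)
  if (any(conc_ng_ml < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(times_h = times_h, conc_ng_ml = conc_ng_ml, label = label),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat(sprintf("<plasma_profile> %s: %d samples over %g h, Cmax %.4g ng/mL\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times_h), max(x$times_h), max(x$conc_ng_ml)))
  invisible(x)
}

#' @export
plot.plasma_profile <- function(x, ...) {
  graphics::plot(x$times_h, x$conc_ng_ml, type = "l",
                 xlab = "time (h)", ylab = "concentration (ng/mL)",
                 main = x$label, ...)
  invisible(x)
}

#' Simulate compartmental disposition from a systemic input rate
#'
#' Integrates `dAc/dt = input(t) - (CL/Vc) Ac - k12 Ac + k21 Ap` and
#' `dAp/dt = k12 Ac - k21 Ap` (one-compartment when k12 = k21 = 0) and
#' returns the central concentration in ng/mL.
#'
#' @param input Either an `absorption_sim`, a data frame with `times_h` and
#'   `input_rate_mg_h`, or a function of time (h) returning mg/h.
#' @param params A `disposition_params` object.
#' @param duration_h Simulated time, h (defaults to the input's extent).
#' @param step_h Output grid step, h.
#' @param rtol,atol Solver tolerances.
#' @return A [plasma_profile()].
#' @export
simulate_disposition <- function(input, params, duration_h = NULL,
                                 step_h = 0.05, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "disposition_params"))
  if (inherits(input, "absorption_sim")) {
    if (is.null(duration_h)) duration_h <- max(input$times_h)
    infun <- stats::approxfun(input$times_h, input$input_rate_mg_h,
                              yleft = 0, yright = 0)
    label <- paste0(input$drug$name, " (simulated)")
  } else if (is.data.frame(input)) {
    if (is.null(duration_h)) duration_h <- max(input$times_h)
    infun <- stats::approxfun(input$times_h, input$input_rate_mg_h,
                              yleft = 0, yright = 0)
    label <- "simulated"
  } else if (is.function(input)) {
    if (is.null(duration_h))
      stop("duration_h is required for a functional input", call. = FALSE)
    infun <- input
    label <- "simulated"
  } else stop("unsupported input type", call. = FALSE)

  ke <- params$clearance_l_h / params$vc_l
  k12 <- params$k12_per_h; k21 <- params$k21_per_h
  deriv <- function(t, y, p) {
    list(c(infun(t) - ke * y[1L] - k12 * y[1L] + k21 * y[2L],
           k12 * y[1L] - k21 * y[2L]))
  }
  times <- seq(0, duration_h, by = step_h)
  out <- deSolve::lsoda(c(0, 0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("disposition ODE solver failed", call. = FALSE)
  conc <- pmax(out[, 2L], 0) / params$vc_l * 1000  # mg/L -> ng/mL
  plasma_profile(out[, 1L], conc, label = label)
}

#' Non-compartmental analysis
#'
#' Cmax/Tmax from the observed maximum; AUC(0-t) by the linear trapezoid
#' rule; terminal slope `lambda_z` by unweighted log-linear regression over
#' the last `lambda_z_points` positive concentrations after Tmax (or the
#' window maximizing adjusted R-squared when
#' `lambda_z_method = "adjusted_r2"`); `AUC(0-inf) = AUC(0-t) +
#' C_last / lambda_z`; `t_half = ln2 / lambda_z`.
#'
#' @param profile A [plasma_profile()].
#' @param lambda_z_points Number of terminal points for the regression.
#' @param lambda_z_method `"last_n"` or `"adjusted_r2"`.
#' @return An object of class `pk_parameters`: `cmax_ng_ml`, `tmax_h`,
#'   `auc_0_t`, `auc_0_inf` (ng*h/mL), `lambda_z_per_h`, `t_half_h`.
#' @export
nca <- function(profile, lambda_z_points = 3,
                lambda_z_method = c("last_n", "adjusted_r2")) {
  stopifnot(inherits(profile, "plasma_profile"))
  lambda_z_method <- match.arg(lambda_z_method)
  t <- profile$times_h; c_ <- profile$conc_ng_ml
  if (length(t) < 2L)
    stop("profile has fewer than two samples; NCA is undefined",
         call. = FALSE)
  imax <- which.max(c_)
  cmax <- c_[imax]; tmax <- t[imax]
  auc_t <- sum(diff(t) * (utils::head(c_, -1L) + utils::tail(c_, -1L)) / 2)

  lambda_z <- NA_real_; auc_inf <- NA_real_; t_half <- NA_real_
  post <- which(t > tmax & c_ > 0)
  if (length(post) < 3L || cmax == 0) {
    warning("fewer than 3 positive post-Tmax concentrations; ",
            "AUC(0-inf) omitted", call. = FALSE)
  } else {
    fit_window <- function(idx, with_r2 = FALSE) {
      fit <- stats::lm(log(c_[idx]) ~ t[idx])
      list(slope = unname(stats::coef(fit)[2L]),
           ## a numerically perfect log-linear tail trips a harmless
           ## summary.lm precision warning
           adj_r2 = if (with_r2)
             suppressWarnings(summary(fit)$adj.r.squared) else NA_real_)
    }
    if (lambda_z_method == "last_n") {
      idx <- utils::tail(post, lambda_z_points)
      f <- fit_window(idx)
    } else {
      cand <- lapply(seq(3L, length(post)), function(k)
        fit_window(utils::tail(post, k), with_r2 = TRUE))
      f <- cand[[which.max(vapply(cand, `[[`, numeric(1L), "adj_r2"))]]
    }
    if (f$slope >= 0)
      stop("non-monotone terminal phase (regression slope >= 0): ",
           "lambda_z estimation error", call. = FALSE)
    lambda_z <- -f$slope
    t_half <- log(2) / lambda_z
    auc_inf <- auc_t + c_[length(c_)] / lambda_z
  }
  structure(
    list(cmax_ng_ml = cmax, tmax_h = tmax, auc_0_t = auc_t,
         auc_0_inf = auc_inf, lambda_z_per_h = lambda_z,
         t_half_h = t_half, label = profile$label),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> %s\n",
              if (nzchar(x$label)) x$label else ""))
  cat(sprintf("  Cmax %.4g ng/mL at Tmax %.3g h\n", x$cmax_ng_ml, x$tmax_h))
  cat(sprintf("  AUC(0-t) %.6g | AUC(0-inf) %.6g ng*h/mL\n",
              x$auc_0_t, x$auc_0_inf))
  cat(sprintf("  lambda_z %.4g /h | t1/2 %.4g h\n",
              x$lambda_z_per_h, x$t_half_h))
  invisible(x)
}

#' Read or write plasma profiles as CSV
#'
#' Columns `time_h`, `conc_ng_ml` and optional `label` (one profile per
#' label).
#'
#' @param path File path.
#' @return A [plasma_profile()], or a list of them when the file holds
#'   several labels.
#' @export
read_plasma_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_h", "conc_ng_ml")
  if (!all(req %in% names(d)))
    stop("plasma CSV must have columns time_h, conc_ng_ml", call. = FALSE)
  if (!("label" %in% names(d))) d$label <- ""
  out <- lapply(split(d, d$label), function(g) {
    g <- g[order(g$time_h), ]
    plasma_profile(g$time_h, g$conc_ng_ml, label = g$label[1L])
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname read_plasma_csv
#' @param profile A [plasma_profile()].
#' @export
write_plasma_csv <- function(profile, path) {
  stopifnot(inherits(profile, "plasma_profile"))
  utils::write.csv(data.frame(time_h = profile$times_h,
                              conc_ng_ml = profile$conc_ng_ml,
                              label = profile$label),
                   path, row.names = FALSE)
}
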