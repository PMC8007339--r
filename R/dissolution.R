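#' Dissolution profile
#'
#' A cumulative percent-dissolved time series for one product in one medium.
#' Timepoints are minutes, strictly increasing, first point after time zero;
#' the curve is implicitly anchored at (0, 0) (dissolution starts at dosing).
#' Percentages above 100 (assay variability) are accepted up to 110.
#'
#' @param product Product label (e.g. `"tablet"`, `"suspension"`).
#' @param medium_ph pH of the dissolution medium.
#' @param timepoints_min Sampling times, min.
#' @param pct_dissolved Cumulative percent dissolved at each time.
#' @param replicate_sd Optional per-timepoint standard deviations, percent.
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(product, medium_ph, timepoints_min,
                                pct_dissolved, replicate_sd = NULL) {
  timepoints_min <- as.numeric(timepoints_min)
  pct_dissolved <- as.numeric(pct_dissolved)
  if (length(timepoints_min) != length(pct_dissolved))
    stop("timepoints and percentages must have equal length", call. = FALSE)
  if (length(timepoints_min) < 1L)
    stop("a profile needs at least one timepoint", call. = FALSE)
  if (any(diff(timepoints_min) <= 0) || timepoints_min[1L] <= 0)
    stop("timepoints must be strictly increasing and positive",
         call. = FALSE)
  if (any(pct_dissolved < 0))
    stop("percent dissolved must be non-negative", call. = FALSE)
  if (!is.null(replicate_sd) &&
      length(replicate_sd) != length(timepoints_min))
    stop("replicate_sd must match the timepoints", call. = FALSE)
  structure(
    list(product = product, medium_ph = medium_ph,
         timepoints_min = timepoints_min, pct_dissolved = pct_dissolved,
         replicate_sd = replicate_sd),
    class = "dissolution_profile"
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> %s, medium pH %.1f\n",
              x$product, x$medium_ph))
  print(data.frame(time_min = x$timepoints_min,
                   pct_dissolved = x$pct_dissolved))
  invisible(x)
}

align_profiles <- function(reference, test) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(reference$timepoints_min) != length(test$timepoints_min) ||
      any(reference$timepoints_min != test$timepoints_min))
    stop("profiles are sampled at different timepoints; ",
         "interpolate onto a common grid first (interpolate_profile)",
         call. = FALSE)
  invisible(TRUE)
}

drop_after_85 <- function(reference, test) {
  ## Regulatory convention: keep points up to (and including) the first at
  ## which both profiles exceed 85% dissolved.
  both <- reference$pct_dissolved > 85 & test$pct_dissolved > 85
  if (!any(both)) return(seq_along(reference$timepoints_min))
  seq_len(which(both)[1L])
}

#' f1 difference factor
#'
#' `f1 = 100 * sum(|R_t - T_t|) / sum(R_t)` over the common timepoints.
#' Values above 15 conventionally indicate dissimilar profiles.
#'
#' @param reference,test [dissolution_profile()]s on identical timepoints
#'   (reference = comparator product, test = candidate product).
#' @param drop_after_both_85 Apply the regulatory rule that drops timepoints
#'   after both profiles exceed 85\% dissolved.  Off by default: the plain
#'   two-profile formula uses every common timepoint.
#' @return The f1 difference factor (dimensionless).
#' @export
f1_difference <- function(reference, test, drop_after_both_85 = FALSE) {
  align_profiles(reference, test)
  idx <- if (drop_after_both_85) drop_after_85(reference, test)
         else seq_along(reference$timepoints_min)
  r <- reference$pct_dissolved[idx]
  t_ <- test$pct_dissolved[idx]
  if (sum(r) <= 0)
    stop("f1 is undefined for an all-zero reference profile", call. = FALSE)
  100 * sum(abs(r - t_)) / sum(r)
}

#' f2 similarity factor
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R_t - T_t)^2)))` over the common
#' timepoints; 100 for identical profiles, above 50 conventionally indicates
#' similar profiles.
#'
#' @inheritParams f1_difference
#' @return The f2 similarity factor (dimensionless).
#' @export
f2_similarity <- function(reference, test, drop_after_both_85 = FALSE) {
  align_profiles(reference, test)
  idx <- if (drop_after_both_85) drop_after_85(reference, test)
         else seq_along(reference$timepoints_min)
  d <- reference$pct_dissolved[idx] - test$pct_dissolved[idx]
  50 * log10((1 + mean(d^2))^-0.5 * 100)
}

#' Similarity verdict from f1 and f2
#'
#' Similar when f2 > 50 and f1 <= 15; not similar when both criteria fail;
#' indeterminate when the two disagree (f2 > 50 but f1 > 15) — the
#' disagreement is flagged rather than silently resolved.
#'
#' @param f1,f2 The difference and similarity factors.
#' @return `"similar"`, `"not_similar"` or `"indeterminate"`.
#' @export
similarity_verdict <- function(f1, f2) {
  stopifnot(f1 >= 0)
  if (f2 > 50 && f1 <= 15) return("similar")
  if (f2 <= 50 && f1 > 15) return("not_similar")
  if (f2 > 50 && f1 > 15) return("indeterminate")
  "not_similar"  # f2 <= 50 and f1 <= 15: closeness criterion decisive
}

#' Classify release rapidity
#'
#' Biopharmaceutics-classification convention: very rapid when at least 85\%
#' is dissolved within 15 minutes; rapid when at least 85\% within
#' 30 minutes; otherwise not rapid.  Percentages at 15/30 min are obtained
#' by monotone interpolation when not sampled directly.
#'
#' @param profile A [dissolution_profile()] extending to 15 min or beyond.
#' @return `"very_rapid"`, `"rapid"` or `"not_rapid"`.
#' @export
classify_release <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (max(profile$timepoints_min) < 15)
    stop("profile ends before 15 min; cannot classify release",
         call. = FALSE)
  at <- interpolate_profile(profile, c(15, 30))
  if (at[1L] >= 85) return("very_rapid")
  if (at[2L] >= 85) return("rapid")
  "not_rapid"
}

#' Interpolate a dissolution profile
#'
#' Piecewise-linear interpolation through (0, 0) and the observed points;
#' beyond the last observation the last observed value is held constant (no
#' extrapolated increase).
#'
#' @param profile A [dissolution_profile()].
#' @param query_times_min Times (min, >= 0) at which percent dissolved is
#'   required.
#' @return Percent dissolved at each query time.
#' @export
interpolate_profile <- function(profile, query_times_min) {
  stopifnot(inherits(profile, "dissolution_profile"),
            all(query_times_min >= 0))
  stats::approx(x = c(0, profile$timepoints_min),
                y = c(0, profile$pct_dissolved),
                xout = query_times_min, method = "linear",
                rule = 2)$y
}

#' Convert a dissolution profile to a release-rate series
#'
#' Differentiates the interpolated cumulative curve (clamped at 100\%) into
#' a piecewise-constant release-rate function `r(t) = dose * d(F/100)/dt`
#' (mg/min).  The integral of the rate over the observed window equals
#' `dose * min(F_last, 100)/100`.  Small decreases in the cumulative curve
#' (within a 2 percentage-point tolerance) are clamped to flat; larger
#' decreases are a data-quality error.
#'
#' @param profile A [dissolution_profile()] with percentages <= 110.
#' @param dose_mg Dose represented by 100\%, mg.
#' @return A data frame with columns `t_start_min`, `t_end_min`,
#'   `rate_mg_min`, plus attribute `released_mg` (the integral).
#' @export
release_rate_series <- function(profile, dose_mg) {
  stopifnot(inherits(profile, "dissolution_profile"), dose_mg > 0)
  if (any(profile$pct_dissolved > 110))
    stop("percent dissolved exceeds the 110% assay tolerance",
         call. = FALSE)
  t <- c(0, profile$timepoints_min)
  f <- pmin(c(0, profile$pct_dissolved), 100)
  dec <- diff(f)
  if (any(dec < -2))
    stop("cumulative dissolution decreases by more than 2%: data-quality ",
         "error", call. = FALSE)
  f <- cummax(f)                       # clamp small decreases
  rate <- dose_mg * diff(f) / 100 / diff(t)
  out <- data.frame(t_start_min = t[-length(t)], t_end_min = t[-1L],
                    rate_mg_min = rate)
  attr(out, "released_mg") <- sum(rate * diff(t))
  out
}

## Hazard form of a tabulated profile: h(t) = F'(t) / (100 - F(t)) (1/min),
## with F the (0,0)-anchored, 100%-clamped cumulative curve capped at
## `cap_pct` so the hazard stays finite.  Applying dU/dt = -h(t) U to a
## static undissolved pool reproduces the profile exactly; the absorption
## simulator applies it per GI compartment.
profile_hazard_fun <- function(profile, cap_pct = 99.9) {
  t <- c(0, profile$timepoints_min)
  f <- cummax(pmin(c(0, profile$pct_dissolved), cap_pct))
  slopes <- diff(f) / diff(t)
  complete <- f[length(f)] >= cap_pct  # profile reached (clamped) 100%
  function(time_min) {
    i <- findInterval(time_min, t, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1L), length(slopes))
    beyond <- time_min >= t[length(t)]
    fval <- pmin(f[i] + slopes[i] * (time_min - t[i]), cap_pct)
    h <- slopes[i] / (100 - fval)
    ## a completed profile keeps dissolving any residual solid at the
    ## (caller-capped) maximum rate; an incomplete one stops releasing
    h[beyond] <- if (complete) Inf else 0
    pmax(h, 0)
  }
}

#' Read or write dissolution profiles as CSV
#'
#' The delimited schema has one row per timepoint with columns `product`,
#' `medium_ph`, `time_min`, `pct_dissolved` and optional `sd`.  A file may
#' hold any number of profiles (one per product x medium combination).
#'
#' @param path File path.
#' @return `read_dissolution_csv()` returns a list of
#'   [dissolution_profile()]s named `"product@pH"`.
#' @export
read_dissolution_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("product", "medium_ph", "time_min", "pct_dissolved")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("dissolution CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("medium_ph", "time_min", "pct_dissolved"))
    if (!is.numeric(d[[col]]))
      stop("non-numeric values in column ", col, call. = FALSE)
  key <- paste0(d$product, "@", format(d$medium_ph))
  out <- lapply(split(d, key), function(g) {
    g <- g[order(g$time_min), ]
    if (any(duplicated(g$time_min)))
      stop("duplicate timepoints for ", g$product[1L], " at pH ",
           g$medium_ph[1L], call. = FALSE)
    dissolution_profile(g$product[1L], g$medium_ph[1L], g$time_min,
                        g$pct_dissolved,
                        replicate_sd = if ("sd" %in% names(g)) g$sd)
  })
  out[order(names(out))]
}

#' @rdname read_dissolution_csv
#' @param profiles A list of (or a single) [dissolution_profile()].
#' @export
write_dissolution_csv <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(product = p$product, medium_ph = p$medium_ph,
               time_min = p$timepoints_min, pct_dissolved = p$pct_dissolved,
               sd = if (is.null(p$replicate_sd)) NA_real_ else p$replicate_sd)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Bundled two-timepoint dissolution data for the reference product
#'
#' The 15/30-min percent-dissolved values for amlodipine and valsartan from
#' the source tablet and the compounded suspension in the three compendial
#' media (pH 1.2, 4.5, 6.8), as published for the 5/80 mg combination
#' product.
#'
#' @param drug `"amlodipine"` or `"valsartan"`.
#' @return A list of [dissolution_profile()]s named `"product@pH"` with
#'   products `"tablet"` and `"suspension"`.
#' @export
reference_dissolution <- function(drug = c("amlodipine", "valsartan")) {
  drug <- match.arg(drug)
  all <- read_dissolution_csv(system.file("extdata",
                                          "dissolution_valzadepine.csv",
                                          package = "suspeq",
                                          mustWork = TRUE))
  drug_of <- vapply(all, function(p) sub("_.*$", "", p$product), "")
  out <- all[drug_of == drug]
  names(out) <- sub(paste0("^", drug, "_"), "", names(out))
  lapply(out, function(p) {
    p$product <- sub(paste0("^", drug, "_"), "", p$product)
    p
  })
}
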