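#' Batch specification for a compounded suspension
#'
#' @param components Data frame with columns `material`, `function_` (role)
#'   and `amount_g` (per batch).
#' @param n_bottles Number of bottles the batch is divided into.
#' @param bottle_volume_ml Reconstituted volume per bottle, mL.
#' @param dose_volume_ml Volume of one dose, mL.
#' @param tablets_per_dose Source tablets represented by one dose.
#' @param strength_label Label strength text (e.g. `"AML 5 mg / VAL 80 mg"`).
#' @return An object of class `batch_spec`.
#' @export
batch_spec <- function(components, n_bottles, bottle_volume_ml,
                       dose_volume_ml, tablets_per_dose = 1,
                       strength_label = "") {
  stopifnot(is.data.frame(components),
            all(c("material", "amount_g") %in% names(components)),
            nrow(components) >= 1,
            all(components$amount_g >= 0),
            n_bottles >= 1, bottle_volume_ml > 0, dose_volume_ml > 0)
  structure(
    list(components = components, n_bottles = n_bottles,
         bottle_volume_ml = bottle_volume_ml,
         dose_volume_ml = dose_volume_ml,
         tablets_per_dose = tablets_per_dose,
         strength_label = strength_label),
    class = "batch_spec"
  )
}

#' The published 20-bottle compounding batch
#'
#' Composition of the amlodipine/valsartan 5/80 mg per 5 mL suspension
#' batch: 200 crushed source tablets plus excipients, 320.40 g total,
#' divided into 20 x 50 mL bottles (16 g powder each), one 5 mL dose per
#' day and one tablet per dose.
#'
#' @return A [batch_spec()].
#' @export
reference_batch <- function() {
  comp <- utils::read.csv(system.file("extdata", "formula_suspension.csv",
                                      package = "suspeq", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  batch_spec(comp, n_bottles = 20, bottle_volume_ml = 50,
             dose_volume_ml = 5, tablets_per_dose = 1,
             strength_label = "AML 5 mg / VAL 80 mg per 5 mL")
}

#' Batch mass arithmetic
#'
#' @param spec A [batch_spec()].
#' @return A list: `total_g` (sum over components) and `per_bottle_g`.
#' @export
batch_total_mass <- function(spec) {
  stopifnot(inherits(spec, "batch_spec"))
  total <- sum(spec$components$amount_g)
  list(total_g = total, per_bottle_g = total / spec$n_bottles)
}

#' Scale a batch
#'
#' @param spec A [batch_spec()].
#' @param k Positive scale factor applied to all component amounts and the
#'   bottle count.
#' @return A scaled [batch_spec()].
#' @export
scale_batch <- function(spec, k) {
  stopifnot(inherits(spec, "batch_spec"), k > 0)
  spec$components$amount_g <- spec$components$amount_g * k
  spec$n_bottles <- spec$n_bottles * k
  spec
}

#' Doses obtainable from one bottle
#'
#' `floor(bottle_volume / dose_volume)`, with a warning when the division
#' is not exact.
#'
#' @param bottle_volume_ml,dose_volume_ml Volumes, mL.
#' @return Integer dose count.
#' @export
doses_per_bottle <- function(bottle_volume_ml, dose_volume_ml) {
  stopifnot(bottle_volume_ml > 0, dose_volume_ml > 0)
  if (dose_volume_ml > bottle_volume_ml) {
    warning("dose volume exceeds bottle volume: zero doses", call. = FALSE)
    return(0L)
  }
  n <- bottle_volume_ml / dose_volume_ml
  if (abs(n - round(n)) > 1e-9)
    warning(sprintf("bottle volume is not an exact multiple of the dose (%g / %g)",
                    bottle_volume_ml, dose_volume_ml), call. = FALSE)
  as.integer(floor(n + 1e-9))
}

#' Source tablets required for a batch
#'
#' @param n_bottles,doses_per_bottle,tablets_per_dose Counts (>= 1).
#' @return `n_bottles * doses_per_bottle * tablets_per_dose`.
#' @export
tablets_required <- function(n_bottles, doses_per_bottle, tablets_per_dose) {
  stopifnot(n_bottles >= 1, doses_per_bottle >= 1, tablets_per_dose >= 1)
  n_bottles * doses_per_bottle * tablets_per_dose
}

#' @export
print.batch_spec <- function(x, ...) {
  m <- batch_total_mass(x)
  cat(sprintf("<batch_spec> %s\n", x$strength_label))
  print(x$components, row.names = FALSE)
  cat(sprintf("  total %.2f g | %d bottles (%.2f g each, %g mL) | %g mL dose\n",
              m$total_g, x$n_bottles, m$per_bottle_g, x$bottle_volume_ml,
              x$dose_volume_ml))
  invisible(x)
}
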