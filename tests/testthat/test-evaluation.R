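test_that("percent prediction error reproduces the published verification cells", {
  # valsartan tablet Cmax
  expect_equal(percent_prediction_error(704.55, 747.30)$pe_abs_pct, 5.72,
               tolerance = 1e-3)
  # amlodipine suspension Cmax
  expect_equal(percent_prediction_error(3.027, 3.200)$pe_abs_pct, 5.406,
               tolerance = 1e-3)
  # valsartan suspension Cmax
  expect_equal(percent_prediction_error(707.22, 747.30)$pe_abs_pct, 5.36,
               tolerance = 1e-3)
  expect_equal(percent_prediction_error(123.4, 123.4)$pe_pct, 0)
  expect_error(percent_prediction_error(1, 0), "undefined")
})

test_that("prediction error is signed, with magnitude kept alongside", {
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    pe <- percent_prediction_error(a, b)
    expect_equal(pe$pe_abs_pct, abs(pe$pe_pct))
    # linearized antisymmetry: reflecting the prediction about the
    # observation flips the sign
    expect_equal(percent_prediction_error(2 * b - a, b)$pe_pct, -pe$pe_pct,
                 tolerance = 1e-12)
  }
})

test_that("bioequivalence verdict is the 80-125% containment rule", {
  expect_equal(be_verdict(81, 120), "pass")
  expect_equal(be_verdict(79.9, 110), "fail")
  expect_equal(be_verdict(95, 125.1), "fail")
  expect_equal(be_verdict(80, 125), "pass")
  expect_error(be_verdict(120, 100))
})

# fast bioequivalence fixture: solution-mode absorption, short horizon
fast_be_config <- function(drug = make_test_drug(peff = 1.5e-4, dose_mg = 10,
                                                 clearance_l_h = 5,
                                                 vc_l_kg = 0.5)) {
  list(drug = drug,
       config = solution_config(duration_h = 30, step = 0.1))
}

test_that("degenerate virtual bioequivalence gives a point interval at 100%", {
  be <- virtual_bioequivalence(fast_be_config(), fast_be_config(),
                               variability = c(clearance = 0, vc = 0),
                               n_subjects = 4, seed = 11)
  expect_equal(be$gmr_pct, c(100, 100), tolerance = 1e-9)
  expect_equal(be$ci90_lo_pct, c(100, 100), tolerance = 1e-9)
  expect_equal(be$ci90_hi_pct, c(100, 100), tolerance = 1e-9)
  expect_equal(be$verdict, c("pass", "pass"))
})

test_that("doubled test clearance halves the AUC ratio and fails", {
  test_cfg <- fast_be_config()
  test_cfg$disposition <- disposition_params(10, 35)
  ref_cfg <- fast_be_config()
  ref_cfg$disposition <- disposition_params(5, 35)
  be <- virtual_bioequivalence(test_cfg, ref_cfg,
                               variability = c(clearance = 0),
                               n_subjects = 3, seed = 2)
  auc_row <- be[be$metric == "auc_inf", ]
  expect_equal(auc_row$gmr_pct, 50, tolerance = 0.5)
  expect_equal(auc_row$verdict, "fail")
})

# two genuinely different formulations: the reference dissolves instantly,
# the test follows a slow Weibull release that stalls short of complete
slow_release_be_configs <- function() {
  drug <- make_test_drug(peff = 1.5e-4, dose_mg = 10,
                         clearance_l_h = 5, vc_l_kg = 0.5)
  slow <- gen_dissolution(f_max = 95, t_d = 25, beta = 1,
                          times_min = c(10, 20, 40, 60, 90), medium_ph = 6.5)
  list(
    test = list(drug = drug,
                config = simulation_config(30, output_step_h = 0.1,
                                           dissolution_mode = "tabulated",
                                           tabulated_profiles = list(slow),
                                           asf_model = "none")),
    reference = list(drug = drug, config = solution_config(30, 0.1)))
}

test_that("stochastic virtual BE is seed-reproducible and t-interval exact", {
  cfgs <- slow_release_be_configs()
  vary <- c(peff = 25, stomach_transit = 30)
  be1 <- virtual_bioequivalence(cfgs$test, cfgs$reference,
                                variability = vary,
                                n_subjects = 8, seed = 99)
  be2 <- virtual_bioequivalence(cfgs$test, cfgs$reference,
                                variability = vary,
                                n_subjects = 8, seed = 99)
  expect_identical(as.data.frame(be1), as.data.frame(be2))

  # the two formulations respond differently to the subject draws, so the
  # interval has positive width
  expect_true(all(be1$ci90_hi_pct > be1$ci90_lo_pct))

  # independent recomputation of the t interval from the subject ratios
  r <- attr(be1, "subject_ratios")
  for (m in colnames(r)) {
    lr <- log(r[, m])
    half <- stats::qt(0.95, length(lr) - 1) * stats::sd(lr) / sqrt(length(lr))
    row <- be1[be1$metric == m, ]
    expect_equal(row$gmr_pct, exp(mean(lr)) * 100, tolerance = 1e-9)
    expect_equal(row$ci90_lo_pct, exp(mean(lr) - half) * 100,
                 tolerance = 1e-9)
    expect_equal(row$ci90_hi_pct, exp(mean(lr) + half) * 100,
                 tolerance = 1e-9)
  }

  be3 <- virtual_bioequivalence(cfgs$test, cfgs$reference,
                                variability = vary,
                                n_subjects = 8, seed = 100)
  expect_false(identical(be1$gmr_pct, be3$gmr_pct))

  # the interval collapses to a point as the variability vanishes
  be0 <- virtual_bioequivalence(cfgs$test, cfgs$reference,
                                variability = c(peff = 0),
                                n_subjects = 4, seed = 1)
  expect_equal(be0$ci90_lo_pct, be0$ci90_hi_pct, tolerance = 1e-9)
})

test_that("identical formulations pass across seeds (coverage sanity)", {
  # with a paired crossover draw, identical formulations give unit ratios
  # whatever the subject variability, so every seeded run must pass
  cfg <- fast_be_config()
  verdicts <- vapply(1:5, function(s) {
    be <- virtual_bioequivalence(cfg, cfg,
                                 variability = c(clearance = 20, vc = 20),
                                 n_subjects = 4, seed = s)
    all(be$verdict == "pass")
  }, logical(1))
  expect_true(all(verdicts))
})

test_that("virtual bioequivalence enforces its preconditions", {
  cfg <- fast_be_config()
  expect_error(virtual_bioequivalence(cfg, cfg, n_subjects = 4),
               "seed")
  expect_error(virtual_bioequivalence(cfg, cfg,
                                      variability = c(foo = 10),
                                      n_subjects = 4, seed = 1),
               "unknown variability")
})

test_that("stability assessment applies the 90-110% band", {
  aml <- reference_stability("amlodipine")
  res <- assess_stability(aml)
  expect_equal(res$verdict, "pass")
  expect_equal(res$min_pct, 97.3)
  expect_true(is.na(res$first_failing_week))

  val <- reference_stability("valsartan")
  resv <- assess_stability(val)
  expect_equal(resv$verdict, "pass")
  expect_equal(resv$min_pct, 101.1)

  bad <- stability_series("x", 0:4, c(101, 99, 95, 91, 89))
  resb <- assess_stability(bad)
  expect_equal(resb$verdict, "fail")
  expect_equal(resb$first_failing_week, 4)

  # permutation changes only the first failing week, never pass/fail or min
  shuffled <- stability_series("x", 0:4, c(89, 101, 95, 99, 91))
  ress <- assess_stability(shuffled)
  expect_equal(ress$verdict, "fail")
  expect_equal(ress$min_pct, resb$min_pct)
  expect_equal(ress$first_failing_week, 0)
})

test_that("rheology classification detects the flow-curve trend", {
  expect_equal(classify_rheology(c(90, 95, 100), c(10, 12, 15)), "dilatant")
  expect_equal(classify_rheology(c(90, 95, 100), c(15, 12, 10)),
               "pseudoplastic")
  expect_equal(classify_rheology(c(90, 95, 100), c(10, 10.1, 10.05)),
               "newtonian")
  expect_error(classify_rheology(c(90, 95), c(10, 12)), "3 paired")
})
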