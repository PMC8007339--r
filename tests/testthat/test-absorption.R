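test_that("default fasted physiology matches its documented structure", {
  phys <- default_fasted_physiology()
  expect_equal(nrow(phys), 9)
  expect_equal(phys$name[1], "stomach")
  # small-intestinal transit (duodenum..ileum3) ~ 3.3 h
  expect_equal(sum(phys$transit_time_h[2:7]), 3.3, tolerance = 0.01)
  # stomach never absorbs
  expect_equal(phys$absorption_scale_factor[1], 0)
  expect_false(phys$absorbing[1])
})

test_that("Johnson dissolution rate matches hand evaluation and limits", {
  aml <- amlodipine()
  # saturated lumen and exhausted solid both give zero
  expect_equal(johnson_dissolution_rate(5, 25e-4, aml, 1, 1), 0)
  expect_equal(johnson_dissolution_rate(0, 25e-4, aml, 10, 0), 0)
  # hand-evaluated point: M 5 mg, r = h = 25 um, S 36.94 mg/mL, sink
  rate <- johnson_dissolution_rate(5, 25e-4, aml, 36.94, 0)
  expect_equal(rate / 3600, 3.10e-3, tolerance = 2e-3)   # mg/s
})

test_that("precipitation rate activates only above saturation", {
  expect_equal(precipitation_rate(1, 100, 0.1, 900), 0)   # C <= S
  # C = 2S hand evaluation, in mg/s
  r <- precipitation_rate(2 * 0.0168 * 100, 100, 0.0168, 900)
  expect_equal(r / 3600, 1.867e-3, tolerance = 1e-3)
  # the rate vanishes in the infinite-precipitation-time limit
  expect_lt(precipitation_rate(10, 100, 0.0168, 1e12), 1e-6)
  expect_error(precipitation_rate(1, 100, 0.1, 0), "positive")
})

test_that("absorption simulation conserves mass in all dissolution modes", {
  aml <- amlodipine()
  profs <- table3_profiles("amlodipine")
  tab <- profs[grep("tablet", names(profs))]
  for (cfg in list(
    simulation_config(24, output_step_h = 0.1,
                      dissolution_mode = "mechanistic_johnson"),
    simulation_config(24, output_step_h = 0.1,
                      dissolution_mode = "tabulated",
                      tabulated_profiles = tab),
    simulation_config(24, output_step_h = 0.1,
                      dissolution_mode = "solution"))) {
    sim <- simulate_absorption(aml, config = cfg)
    expect_lt(sim$mass_balance_error, 1e-6 * aml$dose_mg)
    # no state goes materially negative
    expect_gt(min(sim$state), -1e-6)
  }
})

test_that("no permeability means no absorption; no dose means no dynamics", {
  drug <- make_test_drug(peff = 0)
  sim <- simulate_absorption(drug, config = solution_config(150, 0.25))
  expect_equal(sim$fa, 0)
  expect_equal(max(sim$trajectory$absorbed_mg), 0)
  # everything eventually transits out
  expect_equal(utils::tail(sim$trajectory$transited_out_mg, 1),
               drug$dose_mg, tolerance = 0.02)

  z <- make_test_drug()
  z$dose_mg <- 0
  simz <- simulate_absorption(z, config = solution_config(6, 0.1))
  expect_equal(simz$fa, 0)
  expect_equal(max(abs(simz$state)), max(simz$state[, 19:27]))  # radii only
})

test_that("simulated Fa matches the closed-form transit-chain oracle", {
  # instant dissolution, 7 equal absorbing compartments, uniform ka
  for (ka in c(0.3, 1, 3)) {
    drug <- make_test_drug(peff = 2e-4)
    phys <- make_cat_physiology(drug$peff, ka_target = ka)
    sim <- simulate_absorption(drug, phys, solution_config(36, 0.05))
    expect_equal(sim$fa, oracle_cat_fa(ka, 3.3), tolerance = 0.01)
  }
})

test_that("fraction absorbed is monotone in permeability and solubility", {
  fa_p <- vapply(c(0.5e-4, 1e-4, 2e-4), function(p) {
    simulate_absorption(make_test_drug(peff = p),
                        config = solution_config(36, 0.1))$fa
  }, numeric(1))
  expect_true(all(diff(fa_p) > 0))

  # mechanistic mode: a poorly soluble drug dissolves (and absorbs) less
  fa_s <- vapply(c(0.001, 0.01, 0.1), function(s) {
    d <- make_test_drug(peff = 2e-4, solubility = s)
    cfg <- simulation_config(36, output_step_h = 0.1,
                             dissolution_mode = "mechanistic_johnson",
                             asf_model = "none")
    simulate_absorption(d, config = cfg)$fa
  }, numeric(1))
  expect_true(all(diff(fa_s) > 0))
})

test_that("a tabulated instant-release profile reproduces the solution limit", {
  drug <- make_test_drug(peff = 1e-4)
  inst <- dissolution_profile("inst", 6.5, c(0.01, 0.02), c(100, 100))
  cfg_tab <- simulation_config(36, output_step_h = 0.05,
                               dissolution_mode = "tabulated",
                               tabulated_profiles = list(inst),
                               asf_model = "none")
  fa_tab <- simulate_absorption(drug, config = cfg_tab)$fa
  fa_sol <- simulate_absorption(drug, config = solution_config(36, 0.05))$fa
  expect_equal(fa_tab, fa_sol, tolerance = 0.01)
})

test_that("tabulated dissolution reproduces the in vitro curve in a static vessel", {
  # a single non-transiting, non-absorbing compartment dissolving per the
  # profile hazard must re-trace the cumulative in vitro curve
  drug <- make_test_drug(peff = 0, dose_mg = 100)
  prof <- dissolution_profile("x", 6.5, c(5, 10, 15, 20, 30),
                              c(30, 55, 70, 82, 90))
  phys <- data.frame(name = "vessel", volume_ml = 900, ph = 6.5,
                     transit_time_h = 1e6, radius_cm = 1,
                     absorption_scale_factor = 0, absorbing = FALSE)
  cfg <- simulation_config(0.5, output_step_h = 1 / 120,
                           dissolution_mode = "tabulated",
                           tabulated_profiles = list(prof),
                           asf_model = "none")
  sim <- simulate_absorption(drug, phys, cfg)
  got <- sim$trajectory$dissolved_mg[round(sim$times_h * 60, 6) %in%
                                       prof$timepoints_min]
  expect_equal(got, prof$pct_dissolved, tolerance = 5e-3)
})

test_that("tabulated media map to the nearest compartment pH", {
  drug <- amlodipine()
  profs <- table3_profiles("amlodipine")
  tab <- profs[grep("tablet", names(profs))]
  media <- vapply(tab, `[[`, numeric(1), "medium_ph")
  idx <- suspeq:::nearest_profile_index(default_fasted_physiology()$ph, media)
  got <- media[idx]
  # stomach pH 1.3 -> 1.2; all small-intestinal pH >= 6.0 -> 6.8; caecum 6.4 -> 6.8
  expect_equal(unname(got),
               c(1.2, 6.8, 6.8, 6.8, 6.8, 6.8, 6.8, 6.8, 6.8))
  # a pH halfway toward acid maps to 4.5
  expect_equal(unname(media[suspeq:::nearest_profile_index(4.0, media)]), 4.5)
})

test_that("zero-order input delivers the dose at a flat rate", {
  zo <- zero_order_input(80, fa = 0.25, duration_h = 4, step_h = 0.5)
  expect_equal(unique(zo$input_rate_mg_h[zo$times_h < 4]), 80 * 0.25 / 4)
  expect_equal(sum(zo$input_rate_mg_h * 0.5) - utils::tail(zo$input_rate_mg_h, 1) * 0.5,
               20, tolerance = 1e-9)
})
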