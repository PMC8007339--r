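test_that("f1 and f2 reproduce hand-evaluated two-timepoint comparisons", {
  r45 <- dissolution_profile("tablet", 4.5, c(15, 30), c(49.6, 68.1))
  t45 <- dissolution_profile("susp", 4.5, c(15, 30), c(44.4, 67.9))
  expect_equal(f1_difference(r45, t45), 4.59, tolerance = 1e-3)
  expect_equal(f2_similarity(r45, t45), 70.94, tolerance = 1e-4)

  r12 <- dissolution_profile("tablet", 1.2, c(15, 30), c(17.7, 25.8))
  t12 <- dissolution_profile("susp", 1.2, c(15, 30), c(16.1, 23.5))
  expect_equal(f1_difference(r12, t12), 8.97, tolerance = 1e-3)

  a12r <- dissolution_profile("tablet", 1.2, c(15, 30), c(84.4, 90.3))
  a12t <- dissolution_profile("susp", 1.2, c(15, 30), c(85.6, 93.3))
  expect_equal(f2_similarity(a12r, a12t), 80.16, tolerance = 1e-4)

  # identical profiles
  expect_equal(f1_difference(r45, r45), 0)
  expect_equal(f2_similarity(r45, r45), 100)
})

test_that("f1/f2 match an independent brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    times <- sort(sample(seq(5, 60, by = 5), n))
    r <- sort(runif(n, 5, 105))
    t_ <- pmax(r + rnorm(n, 0, 8), 0.1)
    pr <- dissolution_profile("r", 6.8, times, r)
    pt <- dissolution_profile("t", 6.8, times, t_)
    expect_equal(f1_difference(pr, pt), oracle_f1(r, t_), tolerance = 1e-9)
    expect_equal(f2_similarity(pr, pt), oracle_f2(r, t_), tolerance = 1e-9)
    # symmetry of f2
    expect_equal(f2_similarity(pr, pt), f2_similarity(pt, pr))
  }
})

test_that("f2 decreases and f1 increases under a widening uniform offset", {
  r <- dissolution_profile("r", 6.8, c(5, 10, 15, 20, 30),
                           c(20, 45, 65, 75, 85))
  f1s <- f2s <- numeric(0)
  for (c_ in seq(0, 12, by = 2)) {
    t_ <- dissolution_profile("t", 6.8, r$timepoints_min,
                              r$pct_dissolved + c_)
    f1s <- c(f1s, f1_difference(r, t_))
    f2s <- c(f2s, f2_similarity(r, t_))
  }
  expect_true(all(diff(f1s) >= 0))
  expect_true(all(diff(f2s) <= 0))
})

test_that("profile comparison demands aligned timepoints and valid reference", {
  r <- dissolution_profile("r", 6.8, c(15, 30), c(50, 70))
  t_ <- dissolution_profile("t", 6.8, c(10, 30), c(45, 72))
  expect_error(f1_difference(r, t_), "interpolate")
  expect_error(f2_similarity(r, t_), "interpolate")
  z <- dissolution_profile("z", 6.8, c(15, 30), c(0, 0))
  expect_error(f1_difference(z, r), "all-zero")
})

test_that("similarity verdict applies both criteria and flags disagreement", {
  expect_equal(similarity_verdict(0, 100), "similar")
  expect_equal(similarity_verdict(3.83, 51.63), "similar")  # published pair
  expect_equal(similarity_verdict(20, 40), "not_similar")
  expect_equal(similarity_verdict(16, 55), "indeterminate")
  expect_equal(similarity_verdict(5, 45), "not_similar")
})

test_that("release classification matches the published verdicts", {
  p <- table3_profiles("amlodipine")
  expect_equal(classify_release(p[["tablet@4.5"]]), "very_rapid")
  expect_equal(classify_release(p[["tablet@6.8"]]), "very_rapid")
  expect_equal(classify_release(p[["tablet@1.2"]]), "rapid")
  v <- table3_profiles("valsartan")
  expect_equal(classify_release(v[["tablet@6.8"]]), "very_rapid")
  expect_equal(classify_release(v[["tablet@4.5"]]), "not_rapid")
  expect_equal(classify_release(v[["tablet@1.2"]]), "not_rapid")
  short <- dissolution_profile("x", 6.8, c(5, 10), c(20, 40))
  expect_error(classify_release(short), "15 min")
})

test_that("interpolation anchors at zero, reproduces knots, holds the tail", {
  p <- dissolution_profile("x", 1.2, c(15, 30), c(84.4, 90.3))
  expect_equal(interpolate_profile(p, c(15, 30)), c(84.4, 90.3))
  expect_equal(interpolate_profile(p, 22.5), 87.35)
  expect_equal(interpolate_profile(p, 0), 0)
  expect_equal(interpolate_profile(p, 120), 90.3)
})

test_that("release-rate series conserves mass and clamps above 100%", {
  # reaches 100% -> integral equals the dose
  p100 <- dissolution_profile("x", 6.8, c(5, 15), c(60, 100))
  rr <- release_rate_series(p100, dose_mg = 5)
  expect_equal(attr(rr, "released_mg"), 5, tolerance = 1e-9)

  # flat zero profile -> zero rate
  p0 <- dissolution_profile("x", 6.8, c(5, 15), c(0, 0))
  expect_equal(attr(release_rate_series(p0, 5), "released_mg"), 0)
  expect_true(all(release_rate_series(p0, 5)$rate_mg_min == 0))

  # valsartan suspension pH 6.8: 99.8 then 100.7 -> clamped at 100%
  pv <- dissolution_profile("susp", 6.8, c(15, 30), c(99.8, 100.7))
  expect_equal(attr(release_rate_series(pv, 80), "released_mg"), 80,
               tolerance = 1e-9)

  # random monotone profiles conserve dose * min(last, 100)/100
  set.seed(7)
  for (i in 1:20) {
    times <- sort(sample(5:60, 4))
    pct <- cumsum(runif(4, 0, 30))
    p <- dissolution_profile("x", 6.8, times, pct)
    rr <- release_rate_series(p, 7)
    expect_equal(attr(rr, "released_mg"),
                 7 * min(pct[4], 100) / 100, tolerance = 1e-9)
  }
  # strong decreases are a data-quality error
  bad <- dissolution_profile("x", 6.8, c(5, 15), c(50, 40))
  expect_error(release_rate_series(bad, 5), "data-quality")
  over <- dissolution_profile("x", 6.8, c(5, 15), c(50, 115))
  expect_error(release_rate_series(over, 5), "110")
})

test_that("dissolution CSV round-trips and validates its schema", {
  p1 <- dissolution_profile("tab", 4.5, c(5, 15, 30), c(20.5, 55.25, 88.125))
  p2 <- dissolution_profile("susp", 1.2, c(15, 30), c(17.123456789, 25.9))
  path <- tempfile(fileext = ".csv")
  write_dissolution_csv(list(p1, p2), path)
  back <- read_dissolution_csv(path)
  expect_length(back, 2)
  expect_equal(back[["tab@4.5"]]$pct_dissolved, p1$pct_dissolved,
               tolerance = 1e-12)
  expect_equal(back[["susp@1.2"]]$timepoints_min, p2$timepoints_min)

  bad <- tempfile(fileext = ".csv")
  writeLines("product,time_min,pct_dissolved\na,5,10", bad)
  expect_error(read_dissolution_csv(bad), "medium_ph")
})

test_that("the bundled two-timepoint dissolution table parses completely", {
  all <- read_dissolution_csv(system.file("extdata",
                                          "dissolution_valzadepine.csv",
                                          package = "suspeq"))
  expect_length(all, 12)  # 2 drugs x 2 products x 3 media
  aml <- table3_profiles("amlodipine")
  expect_setequal(names(aml),
                  c("tablet@1.2", "tablet@4.5", "tablet@6.8",
                    "suspension@1.2", "suspension@4.5", "suspension@6.8"))
  expect_equal(aml[["tablet@1.2"]]$pct_dissolved, c(84.4, 90.3))
})
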