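test_that("lift-off is found at the last zero-pressure sample", {
  cv <- make_step_curve(edge = 120, a_max = 150, a_min = 60, n = 301)
  # grid contains A = 120 exactly (spacing 0.3)
  expect_true(120 %in% cv$area)
  expect_equal(as.numeric(find_liftoff(cv)), 120, tolerance = 0.31)
})

test_that("lift-off is stable to Wilhelmy-plate noise across seeds", {
  errs <- vapply(1:100, function(s) {
    cv <- make_step_curve(edge = 120, n = 301, noise = 0.05, seed = s)
    as.numeric(find_liftoff(cv)) - 120
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})

test_that("a flat zero-pressure record raises a no-lift-off error", {
  cv <- isotherm_curve(seq(150, 100, length.out = 50), rep(0, 50))
  expect_error(find_liftoff(cv), class = "filmphase_no_liftoff")
})

test_that("a linear isotherm extrapolates to its own intercept", {
  # pi = 2 * (95 - A): A0 must be exactly 95
  cv <- make_linear_curve(slope = 2, a0 = 95, a_min = 50, a_max = 95)
  a0 <- find_limiting_area(cv)
  expect_equal(as.numeric(a0), 95, tolerance = 1e-6)
  expect_equal(attr(a0, "slope"), -2, tolerance = 1e-6)
  expect_gte(attr(a0, "n_points"), 10)
})

test_that("limiting area recovers the generator intercept", {
  cv <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                        max_cs_inverse = 120))
  expect_equal(as.numeric(find_limiting_area(cv)), 52, tolerance = 1)
})

test_that("gas-phase-only records raise a no-linear-region error", {
  cv <- isotherm_curve(seq(300, 200, length.out = 60),
                       seq(0, 0.9, length.out = 60))
  expect_error(find_limiting_area(cv), class = "filmphase_no_linear_region")
})

test_that("area at pressure is exact at sample points and on lines", {
  cv <- make_linear_curve(slope = 1, a0 = 100, a_min = 40, a_max = 100, n = 200)
  # a node: pick an existing sample
  i <- 57
  got <- area_at_pressure(cv, cv$pressure[i])
  expect_equal(as.numeric(got), cv$area[i], tolerance = 1e-9)
  # closed form pi = 100 - A: A(25) = 75
  expect_equal(as.numeric(area_at_pressure(cv, 25)), 75, tolerance = 1e-9)
  expect_equal(as.numeric(area_at_pressure(cv, c(10, 25, 40))),
               c(90, 75, 60), tolerance = 1e-9)
})

test_that("interpolation is restricted to the pre-collapse branch", {
  # engineered collapse: pi rises to 42 then falls while area keeps shrinking
  A <- seq(120, 20, length.out = 300)
  x <- pmax(100 - A, 0)
  p <- pmin(0.7 * x, 42 - 0.25 * pmax(x - 60, 0))
  cv <- isotherm_curve(A, p)
  # brute-force single-valued reference on the rising branch only
  rising <- seq_len(which.max(p))
  ref <- approx(p[rising], A[rising], xout = 20, ties = mean)$y
  expect_equal(as.numeric(area_at_pressure(cv, 20)), ref, tolerance = 1e-9)
  # a target only reachable after collapse is out of range
  expect_error(area_at_pressure(cv, max(p) + 1),
               class = "filmphase_out_of_range")
})

test_that("out-of-range targets name the offending pressure", {
  cv <- make_linear_curve()
  expect_error(area_at_pressure(cv, 75), "75",
               class = "filmphase_out_of_range")
})

test_that("analyze_isotherm composes all descriptors consistently", {
  cv <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                        max_cs_inverse = 186,
                                        meta = list(lipid = "DMPS-like")))
  ft <- analyze_isotherm(cv)
  expect_s3_class(ft, "isotherm_features")
  expect_equal(ft$phase$label, "LC")
  expect_gte(ft$lift_off_area, ft$limiting_area_A0)
  expect_true(all(ft$transitions$pressure > min(cv$pressure) &
                    ft$transitions$pressure < max(cv$pressure)))
  # defaults are applied identically whether implicit or explicit
  ft2 <- analyze_isotherm(cv, config = list(window = 11L, degree = 2L,
                                            prominence = 5, frac = 0.8))
  expect_equal(ft2$limiting_area_A0, ft$limiting_area_A0)
  expect_equal(ft2$phase$max_cs_inverse, ft$phase$max_cs_inverse)
  expect_equal(ft2$areas_at_pressure, ft$areas_at_pressure)
})

test_that("stage failures are tagged with the failing stage", {
  flat <- isotherm_curve(seq(150, 100, length.out = 60), rep(0, 60))
  err <- tryCatch(analyze_isotherm(flat), error = identity)
  expect_s3_class(err, "filmphase_stage_error")
  expect_match(conditionMessage(err), "stage '")
})

test_that("area descriptors scale with area while Cs-1 is unchanged", {
  cv <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                        max_cs_inverse = 77))
  ft <- analyze_isotherm(cv)
  for (s in c(0.5, 3)) {
    scaled <- isotherm_curve(cv$area * s, cv$pressure)
    fs <- analyze_isotherm(scaled)
    expect_equal(fs$lift_off_area, s * ft$lift_off_area, tolerance = 1e-6)
    expect_equal(fs$limiting_area_A0, s * ft$limiting_area_A0,
                 tolerance = 1e-6)
    expect_equal(unname(fs$areas_at_pressure),
                 s * unname(ft$areas_at_pressure), tolerance = 1e-6)
    expect_equal(fs$phase$max_cs_inverse, ft$phase$max_cs_inverse,
                 tolerance = 1e-6)
  }
})

test_that("features serialise to JSON with all fields", {
  ft <- analyze_isotherm(generate_isotherm(
    isotherm_spec(A0 = 52, lift_off = 110, max_cs_inverse = 186)))
  js <- jsonlite::fromJSON(features_to_json(ft))
  expect_equal(js$phase, "LC")
  expect_equal(js$limiting_area_A0_A2, ft$limiting_area_A0)
  expect_named(js$areas_at_pressure_A2, names(ft$areas_at_pressure))
})
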