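test_that("delta-A of a curve against itself is zero with zero SD", {
  cv <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                        max_cs_inverse = 77))
  da <- delta_area(cv, cv, pi_ref = 20)
  expect_equal(da$delta_A, 0)
  expect_equal(da$sd, 0)
})

test_that("a rigid area shift is returned exactly as delta-A", {
  cv <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                        max_cs_inverse = 77))
  for (shift in c(48.3, 14.9, -5.0)) {
    shifted <- isotherm_curve(cv$area + shift, cv$pressure)
    da <- delta_area(cv, shifted, pi_ref = 20)
    expect_equal(da$delta_A, shift, tolerance = 1e-9)
    expect_equal(da$sd, 0)
  }
})

test_that("replicate noise propagates into the delta-A uncertainty", {
  # 3 replicates per group, rigid offset 38.0, pressure noise 0.5 mN/m
  offset <- 38.0
  est <- vapply(1:50, function(s) {
    buf <- lapply(1:3, function(r) generate_isotherm(
      isotherm_spec(A0 = 52, lift_off = 110, max_cs_inverse = 186,
                    noise_sigma = 0.5, seed = 1000L * s + r)))
    drg <- lapply(1:3, function(r) generate_isotherm(
      isotherm_spec(A0 = 52, lift_off = 110, max_cs_inverse = 186,
                    drug_shift = offset, noise_sigma = 0.5,
                    seed = 2000L * s + r)))
    delta_area(buf, drg, pi_ref = 20)$delta_A
  }, numeric(1))
  expect_equal(mean(est), offset, tolerance = 0.25)
  expect_lt(max(abs(est - offset)), 1)
})

test_that("delta-A is antisymmetric and translation-consistent", {
  cv1 <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                         max_cs_inverse = 77, seed = 3L))
  cv2 <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                         max_cs_inverse = 186, seed = 4L))
  ab <- delta_area(cv1, cv2, pi_ref = 20)
  ba <- delta_area(cv2, cv1, pi_ref = 20)
  expect_equal(ab$delta_A, -ba$delta_A, tolerance = 1e-12)
  for (c_shift in c(7.5, -3.2)) {
    shifted <- isotherm_curve(cv2$area + c_shift, cv2$pressure)
    expect_equal(delta_area(cv1, shifted, 20)$delta_A,
                 ab$delta_A + c_shift, tolerance = 1e-9)
  }
})

test_that("unreachable reference pressures identify the offending curve", {
  cv <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                        max_cs_inverse = 77, pi_max = 30))
  expect_error(delta_area(cv, cv, pi_ref = 40), "buffer curve 1",
               class = "filmphase_out_of_range")
})

test_that("synergy excess reproduces hand arithmetic on tabulated values", {
  # zwitterionic film, acidic subphase: 48.3 - (1.7 + 41.8) = +4.8
  tab <- penetration_table(1.7, 41.8, 48.3, sd1 = 1.0, sd2 = 1.5,
                           sd_mix = 1.5)
  sx <- synergy_excess(tab)
  expect_equal(sx$excess, 4.8, tolerance = 1e-12)
  expect_equal(sx$sd, sqrt(1.0^2 + 1.5^2 + 1.5^2), tolerance = 1e-12)
  expect_equal(sx$flag, "synergistic")
  # anionic film, acidic subphase: 73.5 - (38.0 + 48.4) = -12.9
  sx2 <- synergy_excess(penetration_table(38.0, 48.4, 73.5, sd1 = 0.9,
                                          sd2 = 2.1, sd_mix = 1.7))
  expect_equal(sx2$excess, -12.9, tolerance = 1e-12)
  expect_equal(sx2$flag, "antagonistic")
  # all-zero table is additive
  sx0 <- synergy_excess(penetration_table(0, 0, 0))
  expect_equal(sx0$excess, 0)
  expect_equal(sx0$flag, "additive")
})

test_that("synergy excess is invariant under drug-label exchange", {
  tab12 <- penetration_table(1.7, 41.8, 48.3, sd1 = 1.0, sd2 = 1.5,
                             sd_mix = 1.5)
  tab21 <- penetration_table(41.8, 1.7, 48.3, sd1 = 1.5, sd2 = 1.0,
                             sd_mix = 1.5)
  expect_equal(synergy_excess(tab12)$excess, synergy_excess(tab21)$excess)
  expect_equal(synergy_excess(tab12)$sd, synergy_excess(tab21)$sd)
})

test_that("mismatched reference pressures are rejected", {
  d1 <- delta_area(make_linear_curve(), make_linear_curve(), pi_ref = 20)
  d2 <- delta_area(make_linear_curve(), make_linear_curve(), pi_ref = 25)
  expect_error(penetration_table(d1, d1, d2),
               class = "filmphase_inconsistency")
})

test_that("injection delta-pi handles constant and saturating traces", {
  # constant film: no rise after 4 h
  tr0 <- injection_trace(seq(0, 300, by = 1), rep(20, 301))
  expect_equal(injection_delta_pi(tr0, t_eval = 240)$delta_pi, 0)
  # closed form: dpi(t) = 6 (1 - exp(-t/60)); dpi(240) = 6 (1 - e^-4)
  t <- seq(0, 300, by = 0.5)
  tr <- injection_trace(t, 20 + 6 * (1 - exp(-t / 60)))
  got <- injection_delta_pi(tr, t_eval = 240)
  expect_equal(got$delta_pi, 6 * (1 - exp(-4)), tolerance = 1e-6)
  # dpi at t = 0 is zero whenever pi(0) = pi_initial
  expect_equal(injection_delta_pi(tr, t_eval = 0)$delta_pi, 0)
  expect_error(injection_delta_pi(tr, t_eval = 400),
               class = "filmphase_out_of_range")
})

test_that("plateau estimate recovers the generator asymptote across seeds", {
  est <- vapply(1:100, function(s) {
    tr <- generate_injection_trace(pi_initial = 20, delta_pi_inf = 10,
                                   tau = 30, noise_sigma = 0.1,
                                   duration = 240, seed = s)
    injection_delta_pi(tr, t_eval = 240)$delta_pi_plateau
  }, numeric(1))
  expect_lt(max(abs(est - 10)), 0.3)
})

test_that("the optional exponential fit recovers the kinetic parameters", {
  tr <- generate_injection_trace(pi_initial = 20, delta_pi_inf = 6, tau = 60,
                                 noise_sigma = 0.05, duration = 300, seed = 9L)
  fit <- injection_delta_pi(tr, t_eval = 240, fit_exponential = TRUE)$fit
  expect_equal(fit$delta_pi_inf, 6, tolerance = 0.1)
  expect_equal(fit$tau_min, 60, tolerance = 5)
})

test_that("injection traces validate timing and initial pressure", {
  expect_error(injection_trace(c(0, 1, 1), c(20, 21, 22)),
               class = "filmphase_validation_error")
  expect_error(injection_trace(c(0, 1, 2), c(22, 21, 22), pi_initial = 20),
               class = "filmphase_validation_error")
  # negative rises are reported, not clipped
  t <- 0:60
  tr <- injection_trace(t, 20 - 0.02 * t)
  expect_lt(injection_delta_pi(tr, t_eval = 60)$delta_pi, 0)
})

test_that("injection traces round-trip through delimited text", {
  tr <- generate_injection_trace(delta_pi_inf = 5, tau = 45, seed = 2L,
                                 meta = list(species = "drug-mix",
                                             concentration_M = 1e-6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_injection_trace(tr, path)
  back <- read_injection_trace(path)
  expect_equal(back$time, tr$time, tolerance = 1e-8)
  expect_equal(back$pressure, tr$pressure, tolerance = 1e-8)
  expect_equal(back$pi_initial, 20)
  expect_equal(back$meta$species, "drug-mix")
})
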