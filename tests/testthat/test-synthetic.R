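test_that("generators are deterministic in the seed and leave the RNG alone", {
  sp <- isotherm_spec(A0 = 52, lift_off = 110, max_cs_inverse = 186,
                      noise_sigma = 0.1, seed = 23L)
  set.seed(555)
  before <- .Random.seed
  c1 <- generate_isotherm(sp)
  expect_identical(.Random.seed, before)
  c2 <- generate_isotherm(sp)
  expect_identical(c1$area, c2$area)
  expect_identical(c1$pressure, c2$pressure)
  c3 <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                        max_cs_inverse = 186,
                                        noise_sigma = 0.1, seed = 24L))
  expect_false(identical(c1$pressure, c3$pressure))

  t1 <- generate_injection_trace(delta_pi_inf = 5, tau = 30,
                                 noise_sigma = 0.1, seed = 7L)
  t2 <- generate_injection_trace(delta_pi_inf = 5, tau = 30,
                                 noise_sigma = 0.1, seed = 7L)
  expect_identical(t1$pressure, t2$pressure)

  s1 <- generate_saxs(saxs_spec(noise_sigma = 0.01, seed = 7L))
  s2 <- generate_saxs(saxs_spec(noise_sigma = 0.01, seed = 7L))
  expect_identical(s1$intensity, s2$intensity)
})

test_that("noise-free closure: the analysis recovers every spec descriptor", {
  cases <- list(
    list(A0 = 66, lift_off = 112, max_cs_inverse = 77),
    list(A0 = 52, lift_off = 110, max_cs_inverse = 186),
    list(A0 = 38, lift_off = 44, max_cs_inverse = 400),
    list(A0 = 55, lift_off = 100, max_cs_inverse = 37),
    list(A0 = 60, lift_off = 115, max_cs_inverse = 120,
         transition_pi = 30, transition_depth = 30),
    list(A0 = 62, lift_off = 118, max_cs_inverse = 90,
         transition_pi = 22, transition_depth = 25)
  )
  for (cs in cases) {
    sp <- do.call(isotherm_spec, cs)
    ft <- analyze_isotherm(generate_isotherm(sp))
    expect_lt(abs(ft$limiting_area_A0 - cs$A0), 0.5)
    expect_lt(abs(ft$phase$max_cs_inverse / cs$max_cs_inverse - 1), 0.02)
    if (!is.null(cs$transition_pi)) {
      expect_gt(nrow(ft$transitions), 0)
      nearest <- ft$transitions$pressure[
        which.min(abs(ft$transitions$pressure - cs$transition_pi))]
      expect_lt(abs(nearest - cs$transition_pi), 0.5)
    }
  }
})

test_that("drug_shift closure: delta-A returns the shift to interpolation accuracy", {
  base <- isotherm_spec(A0 = 66, lift_off = 112, max_cs_inverse = 77)
  for (shift in c(48.3, 73.5, 14.9)) {
    shifted <- isotherm_spec(A0 = 66, lift_off = 112, max_cs_inverse = 77,
                             drug_shift = shift)
    da <- delta_area(generate_isotherm(base), generate_isotherm(shifted),
                     pi_ref = 20)
    expect_lt(abs(da$delta_A - shift), 0.1)
  }
})

test_that("cs_scale fluidises the generated film without moving delta-A targets", {
  base <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                          max_cs_inverse = 77))
  fluid <- generate_isotherm(isotherm_spec(A0 = 66, lift_off = 112,
                                           max_cs_inverse = 77,
                                           cs_scale = 37 / 77))
  expect_equal(analyze_isotherm(fluid)$phase$max_cs_inverse, 37,
               tolerance = 0.02)
  expect_equal(analyze_isotherm(fluid)$phase$label, "LE")
  expect_equal(analyze_isotherm(base)$phase$label, "LC")
})

test_that("collapse plateaus are generated above collapse_pi and detected", {
  cv <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                        max_cs_inverse = 186,
                                        collapse_pi = 38))
  expect_lt(max(cv$pressure), 38.01)
  # the pre-collapse rising branch is unchanged by the plateau
  ref <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                         max_cs_inverse = 186, pi_max = 38))
  a20 <- area_at_pressure(cv, 20)
  expect_equal(as.numeric(a20), as.numeric(area_at_pressure(ref, 20)),
               tolerance = 1e-3)
})

test_that("invalid isotherm specs are rejected", {
  expect_error(isotherm_spec(A0 = 100, lift_off = 60, max_cs_inverse = 77),
               class = "filmphase_spec_error")
  expect_error(isotherm_spec(A0 = 50, lift_off = 100, max_cs_inverse = -5),
               class = "filmphase_spec_error")
  expect_error(isotherm_spec(A0 = 50, lift_off = 100, max_cs_inverse = 77,
                             n_points = 20),
               class = "filmphase_spec_error")
  expect_error(isotherm_spec(A0 = 50, lift_off = 100, max_cs_inverse = 77,
                             transition_pi = 0.5),
               class = "filmphase_spec_error")
  expect_error(isotherm_spec(A0 = 50, lift_off = 100, max_cs_inverse = 77,
                             collapse_pi = 30, transition_pi = 35),
               class = "filmphase_spec_error")
  expect_error(generate_injection_trace(tau = -1),
               class = "filmphase_spec_error")
})

test_that("injection generator matches its closed form", {
  tr <- generate_injection_trace(pi_initial = 20, delta_pi_inf = 6, tau = 60,
                                 duration = 240, n_points = 241L)
  expect_equal(tr$pressure[tr$time == 240], 20 + 6 * (1 - exp(-4)),
               tolerance = 1e-9)
  flat <- generate_injection_trace(delta_pi_inf = 0, tau = 30)
  expect_equal(flat$pressure, rep(20, length(flat$time)))
})

test_that("SAXS generator places peaks at library positions and scales with a", {
  pat <- generate_saxs(saxs_spec(space_group = "Pn3m", a = 10.3))
  expect_equal(attr(pat, "peak_positions"),
               pn3m_positions(10.3)[pn3m_positions(10.3) <= 2.5])
  half <- generate_saxs(saxs_spec(space_group = "Pn3m", a = 20.6,
                                  q_range = c(0.25, 2.5)))
  expect_equal(attr(half, "peak_positions")[1:3],
               pn3m_positions(10.3)[1:3] / 2, tolerance = 1e-12)
  expect_error(saxs_spec(a = 10.3, q_range = c(1.5, 2.0)),
               class = "filmphase_spec_error")
  expect_error(saxs_spec(space_group = "Fd3m"),
               class = "filmphase_spec_error")
})

test_that("the standard fixture suite has the designed phase progression", {
  fx <- fixture_suite()
  labels <- vapply(c("F1", "F2", "F3", "F4"), function(nm)
    analyze_isotherm(fx[[nm]])$phase$label, character(1))
  expect_equal(unname(labels), c("LC", "LC", "LC", "S"))
  expect_s3_class(fx$F5, "saxs_pattern")
  expect_equal(index_cubic(detect_peaks(fx$F5))$space_group, "Pn3m")
})

test_that("the oracle fixture's curve matches its prescribed Cs-1 profile", {
  fx <- fixture_suite()
  csf <- attr(fx$F2, "cs_profile")
  prof <- compute_compressibility(fx$F2)
  sel <- prof$pressure_grid >= quantile(prof$pressure_grid, 0.1) &
    prof$pressure_grid <= quantile(prof$pressure_grid, 0.9)
  rel <- abs(prof$cs_inverse[sel] / csf(prof$pressure_grid[sel]) - 1)
  expect_lt(max(rel), 0.02)
})

test_that("fixtures materialise as readable delimited files", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  back <- read_isotherm(paths[["F3"]])
  expect_equal(back$meta$lipid, "DMPS-like")
  expect_s3_class(read_saxs(paths[["F5"]]), "saxs_pattern")
})

test_that("spec configs load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("iso1:", "  A0: 52", "  lift_off: 110",
               "  max_cs_inverse: 186",
               "sax1:", "  kind: saxs", "  a: 10.3"), yml)
  specs <- read_spec_config(yml)
  expect_s3_class(specs$iso1, "isotherm_spec")
  expect_s3_class(specs$sax1, "saxs_spec")
  expect_equal(specs$sax1$a, 10.3)
})
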