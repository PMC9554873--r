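#' Specification of a synthetic compression isotherm
#'
#' Defines the ground truth for a generated isotherm. The curve is built by
#' prescribing a compressibility-modulus profile \eqn{C_s^{-1}(\pi)} — a
#' smooth bump peaking at `max_cs_inverse`, optionally carved by a
#' transition dip — and integrating the defining relation
#' \eqn{dA/d\pi = -A / C_s^{-1}(\pi)} from the lift-off point
#' \eqn{(A_{lift\mbox{-}off},\, \pi = 0)}. Every descriptor the analysis
#' pipeline extracts is therefore known by construction. The low-pressure
#' baseline of the profile is solved internally so that the linear
#' extrapolation of the condensed branch (the definition of the limiting
#' area) hits `A0`.
#'
#' @param A0 limiting area, Angstrom^2/molecule (extrapolation of the
#'   condensed branch to pi = 0)
#' @param lift_off lift-off area, Angstrom^2/molecule; must exceed `A0`
#' @param max_cs_inverse peak compressibility modulus, mN/m
#' @param transition_pi optional pressure of a phase-transition dip, mN/m
#' @param transition_depth depth of the dip in Cs-1, mN/m
#' @param transition_width Gaussian sigma of the dip, mN/m; the default
#'   emulates the sharp plateau-type minima seen in compression isotherms
#' @param collapse_pi optional collapse pressure; above it the curve shows
#'   a plateau
#' @param drug_shift rigid rightward area offset, Angstrom^2/molecule,
#'   emulating drug incorporation at all pressures
#' @param cs_scale multiplicative rescale of the whole Cs-1 profile,
#'   emulating drug-induced fluidisation (default 1, no rescale)
#' @param noise_sigma Gaussian noise on pressure, mN/m
#' @param n_points number of samples (>= 50)
#' @param pi_max maximum recorded pressure (before any collapse), mN/m
#' @param pi_peak pressure at which Cs-1 peaks; default 90% of the top of
#'   the recorded range
#' @param seed RNG seed for the noise (default 17)
#' @param meta metadata list forwarded to the generated curve
#' @return object of class `isotherm_spec`
#' @export
isotherm_spec <- function(A0, lift_off, max_cs_inverse,
                          transition_pi = NULL, transition_depth = 0,
                          transition_width = 2,
                          collapse_pi = NULL, drug_shift = 0, cs_scale = 1,
                          noise_sigma = 0, n_points = 400L,
                          pi_max = 45, pi_peak = NULL, seed = 17L,
                          meta = list()) {
  if (!(lift_off > A0 && A0 > 0))
    fp_stop("spec_error", "require lift_off > A0 > 0 (got %g, %g)",
            lift_off, A0)
  if (max_cs_inverse <= 0) fp_stop("spec_error", "max_cs_inverse must be > 0")
  if (n_points < 50L) fp_stop("spec_error", "n_points must be >= 50")
  pi_top <- collapse_pi %||% pi_max
  if (!is.null(transition_pi) &&
      (transition_pi <= 1 || transition_pi >= pi_top))
    fp_stop("spec_error",
            "transition_pi must lie in (1, %g), got %g", pi_top, transition_pi)
  pi_peak <- pi_peak %||% (0.9 * pi_top)
  structure(list(A0 = A0, lift_off = lift_off,
                 max_cs_inverse = max_cs_inverse,
                 transition_pi = transition_pi,
                 transition_depth = transition_depth,
                 transition_width = transition_width,
                 collapse_pi = collapse_pi,
                 drug_shift = drug_shift, cs_scale = cs_scale,
                 noise_sigma = noise_sigma, n_points = as.integer(n_points),
                 pi_max = pi_max, pi_peak = pi_peak,
                 seed = as.integer(seed), meta = meta),
            class = "isotherm_spec")
}

# the prescribed Cs-1(pi) profile for a spec, as a function of pi,
# given the solved low-pressure baseline c0. The transition dip centre is
# offset so the *composite* profile attains its local minimum exactly at
# transition_pi: a symmetric dip on the sloping flank of the bump would
# otherwise bottom out slightly downslope of its own centre.
spec_cs_profile <- function(spec, c0) {
  M <- spec$max_cs_inverse * spec$cs_scale
  w <- 0.45 * spec$pi_peak
  bump <- function(p) c0 + (M - c0) * exp(-((p - spec$pi_peak) / w)^2)
  has_dip <- !is.null(spec$transition_pi) && spec$transition_depth > 0
  centre <- spec$transition_pi
  if (has_dip) {
    tp <- spec$transition_pi; wt <- spec$transition_width
    slope <- (M - c0) * (-2 * (tp - spec$pi_peak) / w^2) *
      exp(-((tp - spec$pi_peak) / w)^2)
    # stationarity at tp: depth * 2u/wt^2 * exp(-u^2/wt^2) = -slope, u = tp - centre
    g <- function(u) spec$transition_depth * 2 * u / wt^2 *
      exp(-(u / wt)^2) + slope
    lim <- wt / sqrt(2) * 0.999
    if (g(-lim) * g(lim) < 0)
      centre <- tp - stats::uniroot(g, c(-lim, lim), tol = 1e-10)$root
  }
  function(p) {
    cs <- bump(p)
    if (has_dip)
      cs <- cs - spec$transition_depth *
        exp(-((p - centre) / spec$transition_width)^2)
    cs
  }
}

# limiting area implied by the analytic profile: integrate the isotherm on a
# fine grid, resample uniformly in area (the measure of a constant-rate
# compression record) and extrapolate the Cs-1 >= 0.8 max branch to pi = 0
implied_A0 <- function(spec, c0, n_fine = 4000L) {
  csf <- spec_cs_profile(spec, c0)
  pi_top <- spec$collapse_pi %||% spec$pi_max
  pg <- seq(0, pi_top, length.out = n_fine)
  cs <- csf(pg)
  if (any(cs <= 0.5)) return(NA_real_)
  A <- spec$lift_off * exp(-as.numeric(pracma::cumtrapz(pg, 1 / cs)))
  A_u <- seq(spec$lift_off, min(A), length.out = n_fine)
  p_u <- stats::approx(rev(A), rev(pg), xout = A_u)$y
  cs_u <- csf(p_u)
  qual <- cs_u >= 0.8 * max(cs_u)
  imax <- which.max(cs_u)
  lo <- imax; while (lo > 1L && qual[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < n_fine && qual[hi + 1L]) hi <- hi + 1L
  b <- stats::lm.fit(cbind(1, A_u[lo:hi]), p_u[lo:hi])$coefficients
  as.numeric(-b[1] / b[2])
}

.calib_cache <- new.env(parent = emptyenv())

#' Generate a synthetic compression isotherm
#'
#' Realises an [isotherm_spec]: solves the profile baseline so the
#' condensed-branch extrapolation hits the requested `A0`, integrates
#' \eqn{dA/d\pi = -A/C_s^{-1}(\pi)} on a fine pressure grid, prepends a
#' zero-pressure gas segment above the lift-off area, optionally appends a
#' collapse plateau, samples the curve uniformly in area (constant-rate
#' compression), applies the rigid drug shift and adds seeded Gaussian
#' pressure noise. The generator is a pure function of the spec; the
#' caller's RNG state is untouched.
#'
#' @param spec an [isotherm_spec]
#' @return an [isotherm_curve]; the generating profile is attached as
#'   attribute `cs_profile` (a function of pi) and the spec as attribute
#'   `spec`
#' @export
generate_isotherm <- function(spec) {
  stopifnot(inherits(spec, "isotherm_spec"))
  M <- spec$max_cs_inverse * spec$cs_scale
  # the baseline solve depends only on the deterministic profile fields;
  # cache it so replicate seeds of one spec do not repeat the root-find
  key <- paste(spec$A0, spec$lift_off, M,
               spec$transition_pi %||% "none", spec$transition_depth,
               spec$transition_width, spec$collapse_pi %||% "none",
               spec$pi_max, spec$pi_peak, sep = "|")
  f <- function(c0) implied_A0(spec, c0) - spec$A0
  if (!is.null(.calib_cache[[key]])) {
    c0 <- .calib_cache[[key]]
  } else {
    # implied A0 grows monotonically with the baseline; scan for a finite
    # bracket before root-finding (very low baselines collapse the film)
    grid <- exp(seq(log(max(0.6, spec$transition_depth / 10)),
                    log(0.95 * M), length.out = 25))
    fg <- vapply(grid, function(c0) tryCatch(f(c0),
                                             error = function(e) NA_real_),
                 numeric(1))
    okv <- which(is.finite(fg))
    brk <- okv[which(diff(sign(fg[okv])) > 0)]
    if (!length(brk))
      fp_stop("spec_error",
              "A0/lift_off ratio %.3f not attainable with max Cs-1 = %g",
              spec$A0 / spec$lift_off, spec$max_cs_inverse)
    i <- brk[1L]
    j <- okv[match(i, okv) + 1L]
    c0 <- stats::uniroot(f, c(grid[i], grid[j]), tol = 1e-8)$root
    .calib_cache[[key]] <- c0
  }
  csf <- spec_cs_profile(spec, c0)
  pi_top <- spec$collapse_pi %||% spec$pi_max
  n_fine <- 4000L
  pg <- seq(0, pi_top, length.out = n_fine)
  cs <- csf(pg)
  if (any(cs <= 0.5))
    fp_stop("spec_error", "transition dip drives Cs-1 profile below 0.5 mN/m")
  Af <- spec$lift_off * exp(-as.numeric(pracma::cumtrapz(pg, 1 / cs)))
  # gas segment: flat pi = 0 from 15% above lift-off down to lift-off
  gas_frac <- 0.15
  A_start <- spec$lift_off * (1 + gas_frac)
  # optional collapse plateau: area keeps decreasing, pi nearly constant
  A_plateau <- if (!is.null(spec$collapse_pi)) 0.08 * min(Af) else 0
  A_end <- min(Af) - A_plateau
  A_s <- seq(A_start, A_end, length.out = spec$n_points)
  p_s <- numeric(spec$n_points)
  gas <- A_s >= spec$lift_off
  branch <- !gas & A_s >= min(Af)
  p_s[branch] <- stats::approx(rev(Af), rev(pg), xout = A_s[branch])$y
  plat <- A_s < min(Af)
  if (any(plat)) {
    # gentle decline keeps |dpi/dA| well below the plateau detector's bound
    p_s[plat] <- pi_top - 0.1 * (min(Af) - A_s[plat]) / max(A_plateau, 1e-9)
  }
  A_s <- A_s + spec$drug_shift
  if (spec$noise_sigma > 0)
    p_s <- with_seed(spec$seed,
                     pmax(p_s + stats::rnorm(spec$n_points, 0, spec$noise_sigma),
                          -0.9))
  curve <- isotherm_curve(A_s, p_s, meta = spec$meta)
  attr(curve, "cs_profile") <- csf
  attr(curve, "spec") <- spec
  curve
}

#' Generate a constant-area injection trace
#'
#' Emulates the drug-injection experiment: a monolayer preformed at
#' `pi_initial` responds to a drug injected into the subphase with a
#' saturating-exponential pressure rise
#' \eqn{\pi(t) = \pi_0 + \Delta\pi_\infty (1 - e^{-t/\tau})} plus seeded
#' Gaussian noise.
#'
#' @param pi_initial film pressure before injection, mN/m (default 20)
#' @param delta_pi_inf asymptotic pressure rise, mN/m
#' @param tau rise time constant, minutes (> 0)
#' @param noise_sigma Gaussian noise on pressure, mN/m
#' @param duration recorded span, minutes (default 240, i.e. 4 h)
#' @param n_points number of samples
#' @param seed RNG seed
#' @param meta metadata list (species, concentration_M, ...)
#' @return an [injection_trace]
#' @export
generate_injection_trace <- function(pi_initial = 20, delta_pi_inf = 5,
                                     tau = 60, noise_sigma = 0,
                                     duration = 240, n_points = 241L,
                                     seed = 17L, meta = list()) {
  if (tau <= 0) fp_stop("spec_error", "tau must be > 0")
  t <- seq(0, duration, length.out = n_points)
  p <- pi_initial + delta_pi_inf * (1 - exp(-t / tau))
  if (noise_sigma > 0)
    p <- with_seed(seed, p + stats::rnorm(n_points, 0, noise_sigma))
  p[1] <- pi_initial   # anchor the pre-injection reading
  injection_trace(t, p, pi_initial = pi_initial, meta = meta)
}

#' Specification of a synthetic SAXS pattern
#'
#' @param space_group one of `names(cubic_libraries)`
#' @param a lattice parameter, nm (> 0)
#' @param peak_width Gaussian sigma of the Bragg peaks, nm^-1
#' @param background_level background amplitude relative to the first peak
#' @param noise_sigma Gaussian noise amplitude (same relative scale)
#' @param n_points number of q samples
#' @param q_range c(min, max) scattering-vector window, nm^-1; must contain
#'   at least the first three allowed reflections
#' @param seed RNG seed
#' @param meta metadata list
#' @return object of class `saxs_spec`
#' @export
saxs_spec <- function(space_group = "Pn3m", a = 10.3, peak_width = 0.015,
                      background_level = 0.05, noise_sigma = 0,
                      n_points = 1200L, q_range = c(0.5, 2.5), seed = 17L,
                      meta = list()) {
  if (!space_group %in% names(cubic_libraries))
    fp_stop("spec_error", "unknown space group '%s'", space_group)
  if (a <= 0) fp_stop("spec_error", "lattice parameter must be > 0")
  qN <- 2 * pi * sqrt(cubic_libraries[[space_group]]$N) / a
  if (qN[1] < q_range[1] || qN[3] > q_range[2])
    fp_stop("spec_error",
            "q_range [%g, %g] must cover the first three reflections (%.3g-%.3g nm^-1)",
            q_range[1], q_range[2], qN[1], qN[3])
  structure(list(space_group = space_group, a = a, peak_width = peak_width,
                 background_level = background_level,
                 noise_sigma = noise_sigma, n_points = as.integer(n_points),
                 q_range = q_range, seed = as.integer(seed), meta = meta),
            class = "saxs_spec")
}

#' Generate a synthetic 1D SAXS pattern
#'
#' Places Gaussian Bragg peaks at \eqn{q = (2\pi/a)\sqrt N} for the
#' space group's allowed reflections (heights decaying with order, as in
#' powder patterns of lyotropic cubic phases), on a smooth decaying
#' background, with seeded Gaussian noise.
#'
#' @param spec a [saxs_spec]
#' @return a [saxs_pattern]; generating peak positions attached as
#'   attribute `peak_positions`
#' @export
generate_saxs <- function(spec) {
  stopifnot(inherits(spec, "saxs_spec"))
  lib <- cubic_libraries[[spec$space_group]]
  qN <- 2 * pi * sqrt(lib$N) / spec$a
  inside <- qN >= spec$q_range[1] & qN <= spec$q_range[2]
  q <- seq(spec$q_range[1], spec$q_range[2], length.out = spec$n_points)
  heights <- exp(-0.35 * (seq_along(qN) - 1))
  y <- spec$background_level * exp(-2 * (q - q[1]) / diff(spec$q_range))
  for (j in which(inside))
    y <- y + heights[j] * exp(-((q - qN[j])^2) / (2 * spec$peak_width^2))
  if (spec$noise_sigma > 0)
    y <- with_seed(spec$seed,
                   pmax(y + stats::rnorm(spec$n_points, 0, spec$noise_sigma), 0))
  pat <- saxs_pattern(q, y, meta = spec$meta)
  attr(pat, "peak_positions") <- qN[inside]
  pat
}

#' Standard synthetic fixture suite
#'
#' Builds the five reference fixtures used throughout the tests and the
#' analysis scripts:
#' \describe{
#'   \item{F1}{POPC-like zwitterionic-lipid film on buffer: liquid-condensed,
#'     peak Cs-1 77 mN/m, A0 66, lift-off 112 Angstrom^2.}
#'   \item{F2}{oracle fixture: curve generated from a prescribed Cs-1
#'     profile (attached as attribute) for derivative-recovery checks.}
#'   \item{F3}{DMPS-like anionic-lipid film: liquid-condensed, peak Cs-1
#'     186 mN/m, A0 52, lift-off 110 Angstrom^2.}
#'   \item{F4}{cholesterol-like film: solid, peak Cs-1 400 mN/m, A0 38,
#'     lift-off 44 Angstrom^2.}
#'   \item{F5}{Pn3m SAXS pattern at a = 10.3 nm.}
#' }
#'
#' @param seed base RNG seed; fixture i uses `seed + i`
#' @param noise_sigma pressure noise for the isotherm fixtures, mN/m
#' @return named list of fixtures (`isotherm_curve` / `saxs_pattern`), each
#'   carrying its generating spec as attribute `spec`
#' @export
fixture_suite <- function(seed = 17L, noise_sigma = 0) {
  list(
    F1 = generate_isotherm(isotherm_spec(
      A0 = 66, lift_off = 112, max_cs_inverse = 77,
      noise_sigma = noise_sigma, seed = seed + 1L,
      meta = list(lipid = "POPC-like", subphase = "buffer", pH = 5.5))),
    F2 = generate_isotherm(isotherm_spec(
      A0 = 55, lift_off = 100, max_cs_inverse = 120,
      noise_sigma = noise_sigma, seed = seed + 2L,
      meta = list(lipid = "oracle", subphase = "buffer", pH = 7.0))),
    F3 = generate_isotherm(isotherm_spec(
      A0 = 52, lift_off = 110, max_cs_inverse = 186,
      noise_sigma = noise_sigma, seed = seed + 3L,
      meta = list(lipid = "DMPS-like", subphase = "buffer", pH = 5.5))),
    F4 = generate_isotherm(isotherm_spec(
      A0 = 38, lift_off = 44, max_cs_inverse = 400,
      noise_sigma = noise_sigma, seed = seed + 4L,
      meta = list(lipid = "cholesterol-like", subphase = "buffer", pH = 5.5))),
    F5 = generate_saxs(saxs_spec(
      space_group = "Pn3m", a = 10.3, seed = seed + 5L,
      meta = list(sample = "cubosome-like")))
  )
}

#' Materialise the fixture suite as delimited-text files
#'
#' @param dir output directory (created if missing)
#' @param seed base seed passed to [fixture_suite]
#' @param noise_sigma pressure noise, mN/m
#' @return invisibly, the named vector of written paths
#' @export
write_fixtures <- function(dir, seed = 17L, noise_sigma = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- fixture_suite(seed = seed, noise_sigma = noise_sigma)
  paths <- character(0)
  for (nm in names(fx)) {
    obj <- fx[[nm]]
    path <- file.path(dir, paste0(
      nm, if (inherits(obj, "saxs_pattern")) "_saxs.csv" else "_isotherm.csv"))
    if (inherits(obj, "saxs_pattern")) write_saxs(obj, path)
    else write_isotherm(obj, path)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Read isotherm specs from a YAML/JSON config file
#'
#' Each top-level entry names a fixture and provides [isotherm_spec]
#' arguments (or [saxs_spec] arguments when `kind: saxs`).
#'
#' @param path YAML or JSON file
#' @return named list of `isotherm_spec` / `saxs_spec` objects
#' @export
read_spec_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  lapply(cfg, function(entry) {
    kind <- entry$kind %||% "isotherm"
    entry$kind <- NULL
    if (identical(kind, "saxs")) do.call(saxs_spec, entry)
    else do.call(isotherm_spec, entry)
  })
}
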