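#' Lift-off area of a compression isotherm
#'
#' The lift-off area marks the onset of the gas-to-expanded transition: the
#' area at which the surface pressure first begins to rise from its baseline
#' on compression. The baseline is estimated from the largest-area 10% of
#' samples; the detection threshold is the baseline mean plus
#' `max(3 * sigma_baseline, 0.2)` mN/m, and the rise must be sustained (pi
#' stays above threshold at all smaller areas). The reported lift-off is the
#' last sample at or below threshold before the sustained rise.
#'
#' @param curve an [isotherm_curve]
#' @param min_threshold absolute floor of the detection threshold, mN/m
#' @return lift-off area, Angstrom^2/molecule, with attributes `threshold`
#'   and `baseline_sd`
#' @export
find_liftoff <- function(curve, min_threshold = 0.2) {
  stopifnot(inherits(curve, "isotherm_curve"))
  a <- curve$area; p <- curve$pressure          # a decreasing
  n <- length(a)
  nb <- max(3L, ceiling(0.1 * n))
  base <- p[seq_len(nb)]
  sd_b <- stats::sd(base)
  thr <- mean(base) + max(3 * sd_b, min_threshold)
  above <- p > thr
  if (!any(above))
    fp_stop("no_liftoff", "surface pressure never exceeds %.3g mN/m", thr)
  # first index from which pi stays above threshold through the end
  k <- if (all(above)) 1L else max(which(!above)) + 1L
  if (k > n)
    fp_stop("no_liftoff", "no sustained rise above %.3g mN/m", thr)
  out <- if (k == 1L) a[1L] else a[k - 1L]
  attr(out, "threshold") <- thr
  attr(out, "baseline_sd") <- sd_b
  out
}

#' Limiting area by extrapolation of the condensed branch
#'
#' The limiting area \eqn{A_0} estimates the close-packed molecular
#' footprint: a straight line is least-squares fitted (pi on A) over the
#' steepest part of the isotherm and extrapolated to zero surface pressure.
#' The fit window is the contiguous run of samples whose compressibility
#' modulus is at least `frac` of its maximum (which also keeps the window
#' below any transition dip or collapse plateau, where Cs-1 drops).
#'
#' @param curve an [isotherm_curve]
#' @param profile optional precomputed `compressibility_profile`
#' @param frac fraction of max Cs-1 defining the linear window
#' @param min_points minimum number of samples the window must contain
#' @param ... passed to [compute_compressibility] when `profile` is NULL
#' @return \eqn{A_0} in Angstrom^2/molecule, with attributes `slope`
#'   (mN/m per Angstrom^2), `window` (area range used) and `n_points`
#' @export
find_limiting_area <- function(curve, profile = NULL, frac = 0.8,
                               min_points = 10L, ...) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (is.null(profile)) {
    profile <- tryCatch(compute_compressibility(curve, ...),
                        error = function(e)
                          fp_stop("no_linear_region",
                                  "cannot locate condensed branch: %s",
                                  conditionMessage(e)))
  }
  cs <- profile$cs_inverse
  qual <- cs >= frac * max(cs)
  imax <- which.max(cs)
  # contiguous qualifying run containing the maximum
  lo <- imax; while (lo > 1L && qual[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(cs) && qual[hi + 1L]) hi <- hi + 1L
  if (hi - lo + 1L < min_points)
    fp_stop("no_linear_region",
            "condensed linear region has %d points (minimum %d)",
            hi - lo + 1L, min_points)
  A <- profile$area_grid[lo:hi]
  P <- profile$pressure_grid[lo:hi]
  fit <- stats::lm.fit(cbind(1, A), P)
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] >= 0)
    fp_stop("no_linear_region", "condensed branch is not compressive")
  a0 <- as.numeric(-b[1] / b[2])
  attr(a0, "slope") <- as.numeric(b[2])
  attr(a0, "window") <- range(A)
  attr(a0, "n_points") <- hi - lo + 1L
  a0
}

# index (in decreasing-area order) of the first collapse event, or n if none:
# a local pressure maximum followed by a drop >= drop_min, or a sustained
# plateau with |dpi/dA| below slope_min after the film has formed
locate_collapse <- function(curve, drop_min = 1, slope_min = 0.05,
                            plateau_run = 10L, plateau_pi_min = 15) {
  p_raw <- curve$pressure; a <- curve$area; n <- length(p_raw)
  # median-smooth so single-sample noise spikes cannot mimic a collapse drop
  p <- if (n >= 9L) stats::runmed(p_raw, 9L, endrule = "median") else p_raw
  run_max <- cummax(p)
  # a drop only signals collapse once a coherent film exists; baseline
  # noise around pi = 0 cannot produce a collapse event
  drop_idx <- which(run_max - p >= drop_min & run_max > 10)
  i_drop <- if (length(drop_idx)) {
    j <- drop_idx[1]
    max(which(p[1:j] == run_max[j]))   # the maximum preceding the drop
  } else n
  # plateau: sustained near-zero dpi/dA once the film is well formed;
  # the slope comes from the local-polynomial fit, not pointwise diffs
  i_plat <- n
  if (n >= plateau_run + 1L) {
    win <- min(11L, n - 1L + n %% 2L)
    lp <- localpoly_deriv(a, p_raw, window = win)
    ok <- abs(lp$deriv) < slope_min & lp$fitted > plateau_pi_min
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= plateau_run)
    if (length(hit)) i_plat <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  }
  min(i_drop, i_plat)
}

#' Area per molecule at target surface pressures
#'
#' Interpolates \eqn{A(\pi)} along the compression branch of the isotherm,
#' restricted to the pre-collapse region (before the first pressure maximum
#' followed by a drop of at least 1 mN/m, or the first sustained plateau
#' with \eqn{|d\pi/dA|} below 0.05 mN/m per Angstrom^2). Interpolation is
#' piecewise linear and exact at sample points; where noise makes pi locally
#' non-monotone the upper envelope of the branch is used so that
#' \eqn{A(\pi)} stays single-valued.
#'
#' @param curve an [isotherm_curve]
#' @param pi_targets numeric vector of target pressures, mN/m
#' @return named numeric vector of areas, Angstrom^2/molecule
#' @export
area_at_pressure <- function(curve, pi_targets) {
  stopifnot(inherits(curve, "isotherm_curve"))
  cut <- locate_collapse(curve)
  a <- curve$area[seq_len(cut)]
  p <- curve$pressure[seq_len(cut)]
  # monotone rising branch: keep strict running maxima of pi
  keep <- p > c(-Inf, cummax(p)[-length(p)])
  a <- a[keep]; p <- p[keep]
  bad <- pi_targets > max(p) | pi_targets < min(p)
  if (any(bad))
    fp_stop("out_of_range",
            "target pi = %s mN/m outside the recorded rising branch [%.3g, %.3g]",
            paste(pi_targets[bad], collapse = ", "), min(p), max(p))
  out <- stats::approx(p, a, xout = pi_targets, ties = "ordered")$y
  names(out) <- format(pi_targets, trim = TRUE)
  out
}

#' Full descriptor extraction for one isotherm
#'
#' Composes the per-curve analyses: compressibility profile and its maximum
#' (Davies-Rideal phase label), phase-transition minima, lift-off area,
#' limiting area and areas at the requested pressures. Deterministic given
#' the configuration; any stage failure is re-raised tagged with the stage
#' name.
#'
#' @param curve an [isotherm_curve]
#' @param config named list overriding defaults: `window`, `degree`
#'   (local-fit controls), `prominence` (transition depth, mN/m),
#'   `pi_targets` (pressures for A(pi); defaults to 10-45 mN/m in steps of
#'   5, silently restricted to the recorded range), `frac` (limiting-area
#'   window fraction)
#' @return an object of class `isotherm_features` with fields
#'   `lift_off_area`, `limiting_area_A0`, `areas_at_pressure`,
#'   `transitions`, `phase`, `profile`
#' @export
analyze_isotherm <- function(curve, config = list()) {
  stopifnot(inherits(curve, "isotherm_curve"))
  cfg <- utils::modifyList(
    list(window = 11L, degree = 2L, prominence = 5, frac = 0.8,
         pi_targets = NULL), config)
  stage <- function(name, expr) {
    tryCatch(expr, filmphase_error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("filmphase_stage_error", class(e))))
    })
  }
  profile <- stage("compressibility",
                   compute_compressibility(curve, window = cfg$window,
                                           degree = cfg$degree))
  phase <- stage("phase", classify_phase(profile$max_cs_inverse))
  transitions <- stage("transitions",
                       detect_transitions(profile, prominence = cfg$prominence))
  liftoff <- stage("liftoff", find_liftoff(curve))
  a0 <- stage("limiting_area",
              find_limiting_area(curve, profile = profile, frac = cfg$frac))
  targets <- cfg$pi_targets
  default_targets <- is.null(targets)
  if (default_targets) targets <- seq(10, 45, by = 5)
  areas <- stage("area_at_pressure", {
    if (default_targets) {
      cut <- locate_collapse(curve)
      targets <- targets[targets <= max(curve$pressure[seq_len(cut)]) &
                           targets >= min(curve$pressure)]
    }
    if (length(targets)) area_at_pressure(curve, targets) else numeric(0)
  })
  structure(list(lift_off_area = as.numeric(liftoff),
                 limiting_area_A0 = as.numeric(a0),
                 a0_diagnostics = attributes(a0),
                 areas_at_pressure = areas,
                 transitions = transitions,
                 phase = phase,
                 profile = profile,
                 config = cfg,
                 meta = curve$meta),
            class = "isotherm_features")
}

#' @export
print.isotherm_features <- function(x, ...) {
  cat(sprintf("<isotherm_features> phase %s (max Cs-1 %.1f mN/m), A_lift-off %.1f, A0 %.1f A2\n",
              x$phase$label, x$phase$max_cs_inverse,
              x$lift_off_area, x$limiting_area_A0))
  if (nrow(x$transitions))
    cat(sprintf("  transitions at pi = %s mN/m\n",
                paste(sprintf("%.1f", x$transitions$pressure), collapse = ", ")))
  if (length(x$areas_at_pressure))
    cat("  A(pi):", paste(sprintf("%s->%.1f", names(x$areas_at_pressure),
                                  x$areas_at_pressure), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise features to JSON
#'
#' @param features an `isotherm_features` object
#' @param path optional output path; when NULL the JSON string is returned
#' @export
features_to_json <- function(features, path = NULL) {
  x <- list(
    phase = features$phase$label,
    max_cs_inverse_mN_per_m = features$phase$max_cs_inverse,
    lift_off_area_A2 = features$lift_off_area,
    limiting_area_A0_A2 = features$limiting_area_A0,
    areas_at_pressure_A2 = as.list(features$areas_at_pressure),
    transitions = features$transitions,
    meta = features$meta
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
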