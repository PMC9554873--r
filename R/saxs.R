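#' Allowed-reflection libraries for bicontinuous cubic space groups
#'
#' For a cubic lattice the Bragg peaks fall at
#' \eqn{q = (2\pi/a)\sqrt{h^2+k^2+l^2}}; each space group permits a
#' characteristic sequence of \eqn{N = h^2+k^2+l^2}. The double-diamond
#' Pn3m phase shows spacing ratios \eqn{\sqrt2:\sqrt3:\sqrt4:\sqrt6:\sqrt8:\sqrt9},
#' the primitive Im3m \eqn{\sqrt2:\sqrt4:\sqrt6:\sqrt8:\sqrt{10}:\sqrt{12}}
#' and the gyroid Ia3d \eqn{\sqrt6:\sqrt8:\sqrt{14}:\sqrt{16}:\sqrt{20}:\sqrt{22}}.
#'
#' @format named list; each element has `N` (integer vector) and `hkl`
#'   (character vector of Miller indices)
#' @export
cubic_libraries <- list(
  Pn3m = list(N = c(2L, 3L, 4L, 6L, 8L, 9L),
              hkl = c("110", "111", "200", "211", "220", "221")),
  Im3m = list(N = c(2L, 4L, 6L, 8L, 10L, 12L),
              hkl = c("110", "200", "211", "220", "310", "222")),
  Ia3d = list(N = c(6L, 8L, 14L, 16L, 20L, 22L),
              hkl = c("211", "220", "321", "400", "420", "332"))
)

#' Construct a 1D SAXS pattern
#'
#' @param q scattering vector, nm^-1, strictly increasing and positive
#' @param intensity arbitrary units, same length, finite
#' @param meta named list (sample label, temperature, ...)
#' @return object of class `saxs_pattern`
#' @export
saxs_pattern <- function(q, intensity, meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    fp_stop("validation_error", "q and intensity differ in length")
  if (!all(is.finite(q)) || !all(is.finite(intensity)))
    fp_stop("validation_error", "non-finite values in SAXS pattern")
  if (any(q <= 0) || any(diff(q) <= 0))
    fp_stop("validation_error", "q must be positive and strictly increasing")
  structure(list(q = q, intensity = intensity, meta = meta),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat(sprintf("<saxs_pattern> %d points, q in [%.3g, %.3g] nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Read a 1D SAXS profile from delimited text
#'
#' Two numeric columns `q_nm_inv, intensity` with optional `# key: value`
#' metadata lines.
#' @param path file path
#' @param sep separator; NULL auto-detects
#' @return a [saxs_pattern]
#' @export
read_saxs <- function(path, sep = NULL) {
  raw <- read_delimited_xy(path, c("q", "intensity"), sep = sep)
  saxs_pattern(raw$x, raw$y, meta = raw$meta)
}

#' Write a SAXS pattern to delimited text
#' @param pattern a [saxs_pattern]
#' @param path output path
#' @param sep field separator
#' @export
write_saxs <- function(pattern, path, sep = ",") {
  write_delimited_xy(pattern$q, pattern$intensity, c("q_nm_inv", "intensity"),
                     path, meta = pattern$meta, sep = sep)
}

#' Detect Bragg peaks in a 1D SAXS profile
#'
#' Subtracts a rolling-median background (window 5% of the q range) and
#' reports local maxima exceeding `min_height_rel` of the maximum recorded
#' intensity, separated by at least `min_separation`. Peak centres are
#' refined to sub-grid precision by fitting a parabola to the logarithm of
#' the background-subtracted intensity at the three samples around each
#' maximum (exact for Gaussian peaks); the parabola curvature also yields a
#' Gaussian-sigma width estimate.
#'
#' @param pattern a [saxs_pattern] with at least 50 samples
#' @param min_height_rel detection threshold as a fraction of the maximum
#'   intensity
#' @param min_separation minimum distance between reported peaks, nm^-1
#' @return object of class `peak_set`: data frame with columns `position`
#'   (nm^-1), `height` (background-subtracted) and `width` (Gaussian sigma,
#'   nm^-1); zero rows when nothing qualifies
#' @export
detect_peaks <- function(pattern, min_height_rel = 0.02, min_separation = 0.05) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  q <- pattern$q; y <- pattern$intensity
  n <- length(q)
  if (n < 50L)
    fp_stop("insufficient_data", "pattern has %d points (minimum 50)", n)
  win <- ceiling(0.05 * n)
  if (win %% 2L == 0L) win <- win + 1L
  bg <- stats::runmed(y, k = max(3L, win), endrule = "median")
  r <- y - bg
  thr <- min_height_rel * max(y)
  cand <- which(r[-c(1L, n)] > pmax(r[-c(n - 1L, n)], thr) &
                  r[-c(1L, n)] >= r[-c(1L, 2L)]) + 1L
  # enforce separation, keeping the taller peak
  cand <- cand[order(r[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(q[i] - q[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  pos <- hgt <- wid <- numeric(length(kept))
  for (j in seq_along(kept)) {
    i <- kept[j]
    tri <- pmax(r[(i - 1L):(i + 1L)], 1e-12)
    ly <- log(tri)
    x3 <- q[(i - 1L):(i + 1L)]
    # parabola through three points: vertex and curvature
    d1 <- (ly[2] - ly[1]) / (x3[2] - x3[1])
    d2 <- ((ly[3] - ly[2]) / (x3[3] - x3[2]) - d1) / (x3[3] - x3[1])
    if (is.finite(d2) && d2 < 0) {
      vx <- (x3[1] + x3[2]) / 2 - d1 / (2 * d2)
      pos[j] <- min(max(vx, x3[1]), x3[3])
      wid[j] <- sqrt(-1 / (2 * d2))
    } else {
      pos[j] <- q[i]
      wid[j] <- NA_real_
    }
    hgt[j] <- r[i]
  }
  structure(data.frame(position = pos, height = hgt, width = wid),
            class = c("peak_set", "data.frame"))
}

#' Fit the cubic lattice parameter from indexed reflections
#'
#' Least-squares fit of observed peak positions against
#' \eqn{\sqrt{h^2+k^2+l^2}} through the origin:
#' \eqn{q_{obs} = (2\pi/a)\sqrt N}. Requires at least three distinct
#' reflections.
#'
#' @param q_obs observed peak positions, nm^-1
#' @param N integer vector of \eqn{h^2+k^2+l^2} for each peak (alternatively
#'   pass `hkl`, a character vector like "110", from which N is computed)
#' @param hkl optional Miller-index strings used when `N` is missing
#' @return list with `a` (lattice parameter, nm), `residual` (RMS relative
#'   deviation of the matched peaks) and `n` (number of reflections)
#' @export
fit_lattice_parameter <- function(q_obs, N = NULL, hkl = NULL) {
  if (is.null(N)) {
    if (is.null(hkl)) fp_stop("config_error", "provide N or hkl")
    N <- vapply(strsplit(hkl, ""), function(d) sum(as.integer(d)^2), numeric(1))
  }
  if (length(q_obs) != length(N))
    fp_stop("validation_error", "q_obs and N differ in length")
  if (length(q_obs) < 3L)
    fp_stop("degenerate_fit", "need >= 3 matched reflections, got %d",
            length(q_obs))
  s <- sqrt(N)
  if (length(unique(N)) < 2L)
    fp_stop("degenerate_fit", "all reflections share the same h^2+k^2+l^2")
  slope <- sum(q_obs * s) / sum(s^2)
  pred <- slope * s
  list(a = 2 * pi / slope,
       residual = sqrt(mean(((q_obs - pred) / pred)^2)),
       n = length(q_obs))
}

#' Index a peak set against cubic space-group libraries
#'
#' Matches the detected peak positions against the allowed-reflection
#' sequences of candidate cubic space groups. For each candidate the first
#' (lowest-q) peak is anchored on the group's lowest allowed reflection;
#' remaining peaks are matched greedily in increasing q to library entries,
#' a library entry may be skipped (unobserved reflection) without penalty,
#' and peaks matching no entry within `rel_tol` add a fixed per-peak
#' penalty to the selection score. The candidate minimising
#' (RMS relative residual + penalty) with at least three matched peaks
#' wins; ties are broken by the larger number of matched peaks, then by
#' library order. The lattice parameter is then refined with
#' [fit_lattice_parameter].
#'
#' @param peaks a `peak_set` (or data frame with a `position` column, or a
#'   numeric vector of positions), nm^-1
#' @param candidates character vector of space groups to try (subset of
#'   `names(cubic_libraries)`)
#' @param rel_tol relative tolerance on peak-position ratios
#' @param unmatched_penalty score penalty per unmatched observed peak
#' @return object of class `cubic_phase_assignment`: list with
#'   `space_group`, `miller_indices` (character), `lattice_parameter_a`
#'   (nm), `residual`, `n_matched`, `matched` (data frame q_obs, N, hkl)
#' @export
index_cubic <- function(peaks, candidates = names(cubic_libraries),
                        rel_tol = 0.015, unmatched_penalty = 0.02) {
  pos <- if (is.numeric(peaks)) sort(peaks) else sort(peaks$position)
  if (length(pos) < 3L)
    fp_stop("insufficient_peaks", "need >= 3 peaks to index, got %d",
            length(pos))
  if (!length(candidates))
    fp_stop("config_error", "no candidate space groups supplied")
  unknown <- setdiff(candidates, names(cubic_libraries))
  if (length(unknown))
    fp_stop("config_error", "unknown space group(s): %s",
            paste(unknown, collapse = ", "))
  best <- NULL
  for (gi in seq_along(candidates)) {
    lib <- cubic_libraries[[candidates[gi]]]
    ratios_exp <- sqrt(lib$N / lib$N[1L])
    ratios_obs <- pos / pos[1L]
    ptr <- 1L
    m_idx <- integer(0); m_lib <- integer(0); dev <- numeric(0)
    for (i in seq_along(pos)) {
      if (ptr > length(ratios_exp)) break
      # nearest not-yet-used library entry, in increasing order
      rel <- abs(ratios_obs[i] / ratios_exp[ptr:length(ratios_exp)] - 1)
      jrel <- which.min(rel)
      if (rel[jrel] <= rel_tol) {
        m_idx <- c(m_idx, i)
        m_lib <- c(m_lib, ptr + jrel - 1L)
        dev <- c(dev, rel[jrel])
        ptr <- ptr + jrel
      }
    }
    if (length(m_idx) < 3L) next
    score <- sqrt(mean(dev^2)) +
      unmatched_penalty * (length(pos) - length(m_idx))
    cand <- list(group = candidates[gi], order = gi,
                 m_idx = m_idx, m_lib = m_lib, score = score,
                 n_matched = length(m_idx))
    if (is.null(best) ||
        score < best$score - 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (cand$n_matched > best$n_matched ||
          (cand$n_matched == best$n_matched && gi < best$order))))
      best <- cand
  }
  if (is.null(best))
    fp_stop("no_assignment",
            "no candidate matches >= 3 peaks within rel_tol = %g", rel_tol)
  lib <- cubic_libraries[[best$group]]
  matched <- data.frame(q_obs = pos[best$m_idx],
                        N = lib$N[best$m_lib],
                        hkl = lib$hkl[best$m_lib])
  fit <- fit_lattice_parameter(matched$q_obs, N = matched$N)
  structure(list(space_group = best$group,
                 miller_indices = matched$hkl,
                 lattice_parameter_a = fit$a,
                 residual = fit$residual,
                 n_matched = best$n_matched,
                 matched = matched),
            class = "cubic_phase_assignment")
}

#' @export
print.cubic_phase_assignment <- function(x, ...) {
  cat(sprintf("<cubic_phase_assignment> %s, a = %.3f nm, %d reflections, RMS rel. residual %.2e\n",
              x$space_group, x$lattice_parameter_a, x$n_matched, x$residual))
  cat("  [hkl]:", paste0("[", x$miller_indices, "]", collapse = " "), "\n")
  invisible(x)
}

#' Serialise a cubic-phase assignment to JSON
#' @param assignment a `cubic_phase_assignment`
#' @param path optional output path; when NULL the JSON string is returned
#' @export
assignment_to_json <- function(assignment, path = NULL) {
  x <- list(space_group = assignment$space_group,
            lattice_parameter_a_nm = assignment$lattice_parameter_a,
            miller_indices = assignment$miller_indices,
            residual = assignment$residual,
            n_matched = assignment$n_matched,
            peaks = assignment$matched)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
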