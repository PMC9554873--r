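#' Construct a compression isotherm
#'
#' An `isotherm_curve` holds one Langmuir-trough compression run: area per
#' molecule (\eqn{\mathring{A}^2}/molecule) against surface pressure \eqn{\pi}
#' (mN/m), stored in order of decreasing area, plus free-form metadata
#' (lipid, subphase, pH, temperature, compression rate, replicate id).
#'
#' Rows are canonicalised on construction: samples are ordered by decreasing
#' area and duplicate-area rows are averaged. The raw record must be monotone
#' in area in acquisition order (either direction, small reversals up to
#' `reversal_tol` of the area range are tolerated as trough noise); a mixed
#' compression/expansion record is rejected.
#'
#' @param area numeric vector, area per molecule in square Angstrom
#' @param pressure numeric vector, surface pressure in mN/m, same length
#' @param meta named list of metadata (lipid, subphase, pH, temperature_C,
#'   rate_mm_per_min, replicate, ...)
#' @param reversal_tol tolerated non-monotonicity in acquisition order,
#'   as a fraction of the recorded area range
#' @return an object of class `isotherm_curve` with fields `area`, `pressure`,
#'   `meta`
#' @export
isotherm_curve <- function(area, pressure, meta = list(), reversal_tol = 0.005) {
  area <- as.numeric(area); pressure <- as.numeric(pressure)
  if (length(area) != length(pressure))
    fp_stop("validation_error", "area and pressure differ in length (%d vs %d)",
            length(area), length(pressure))
  if (!all(is.finite(area)) || !all(is.finite(pressure)))
    fp_stop("validation_error", "non-finite values in isotherm record")
  if (any(pressure < -1))
    fp_stop("validation_error", "surface pressure below -1 mN/m (min %.3g)",
            min(pressure))
  rng <- diff(range(area))
  if (rng <= 0) fp_stop("validation_error", "area has zero range")
  d <- diff(area)
  dominant <- if (sum(d < 0) >= sum(d > 0)) -1 else 1
  if (any(dominant * d < -reversal_tol * rng))
    fp_stop("validation_error",
            "area is not monotone in acquisition order beyond tolerance")
  ord <- order(area, decreasing = TRUE)
  area <- area[ord]; pressure <- pressure[ord]
  if (anyDuplicated(area)) {
    # tapply on a numeric grouping sorts levels in increasing order
    pressure <- rev(as.numeric(tapply(pressure, area, mean)))
    area <- sort(unique(area), decreasing = TRUE)
  }
  if (length(area) < 10L)
    fp_stop("insufficient_data", "isotherm has %d usable rows (minimum 10)",
            length(area))
  structure(list(area = area, pressure = pressure, meta = meta),
            class = "isotherm_curve")
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf("<isotherm_curve> %d samples, A %.1f-%.1f A2/molecule, pi %.2f-%.2f mN/m\n",
              length(x$area), min(x$area), max(x$area),
              min(x$pressure), max(x$pressure)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.isotherm_curve <- function(x, ...) {
  data.frame(area_A2_per_molecule = x$area,
             surface_pressure_mN_per_m = x$pressure)
}

#' Read a surface pressure--area isotherm from delimited text
#'
#' Expects two numeric columns (area, surface pressure), comma-, tab- or
#' whitespace-separated, with an optional header row and optional
#' `# key: value` metadata comment lines. Rows are re-ordered to decreasing
#' area if the trough exported the run in reverse, and duplicate-area rows
#' are averaged. When the header names the area column in nm^2
#' (e.g. `area_nm2_per_molecule`) areas are converted to Angstrom^2.
#'
#' @param path file path
#' @param sep field separator; `NULL` (default) auto-detects
#' @return an [isotherm_curve]
#' @export
read_isotherm <- function(path, sep = NULL) {
  raw <- read_delimited_xy(path, c("area", "pressure"), sep = sep)
  area <- raw$x
  if (!is.null(raw$header) && grepl("nm2|nm\\^2", raw$header[1], ignore.case = TRUE))
    area <- area * 100   # nm^2 -> A^2
  isotherm_curve(area, raw$y, meta = raw$meta)
}

#' Write an isotherm to delimited text
#'
#' Mirrors the input dialect of [read_isotherm]: `# key: value` metadata
#' lines, a header, then `area, pressure` rows.
#'
#' @param curve an [isotherm_curve]
#' @param path output file path
#' @param sep field separator
#' @export
write_isotherm <- function(curve, path, sep = ",") {
  write_delimited_xy(curve$area, curve$pressure,
                     c("area_A2_per_molecule", "surface_pressure_mN_per_m"),
                     path, meta = curve$meta, sep = sep)
}
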