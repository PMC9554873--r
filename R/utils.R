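#' @keywords internal
"_PACKAGE"

# classed condition helper: every user-facing error carries a
# filmphase_<class> condition class so callers can branch on failure mode
fp_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("filmphase_", class), "filmphase_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Local-polynomial smoothing with analytic derivative
#'
#' Fits a least-squares polynomial of the given degree over a sliding window
#' centred (where possible) on each sample and returns the fitted value and
#' the analytic first derivative of the local fit. Unlike convolution-type
#' Savitzky-Golay filters this handles non-uniform abscissae, which compression
#' isotherms sampled uniformly in time generally have in pressure.
#'
#' @param x numeric abscissa (any monotone order, need not be uniform)
#' @param y numeric ordinate, same length
#' @param window odd integer window length in samples (>= degree + 2)
#' @param degree polynomial degree of the local fit
#' @return list with `fitted` and `deriv`, both aligned with `x`
#' @keywords internal
localpoly_deriv <- function(x, y, window = 11L, degree = 2L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (window %% 2L == 0L) window <- window + 1L
  if (window < degree + 2L || window > n)
    fp_stop("config_error", "smoothing window %d invalid for %d samples", window, n)
  h <- (window - 1L) %/% 2L
  fitted <- deriv <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (hi - lo + 1L < window) {        # one-sided near the edges
      if (lo == 1L) hi <- min(n, window) else lo <- max(1L, n - window + 1L)
    }
    xi <- x[lo:hi] - x[i]
    X <- outer(xi, 0:degree, `^`)
    beta <- tryCatch(qr.coef(qr(X), y[lo:hi]),
                     error = function(e) rep(NA_real_, degree + 1L))
    beta[is.na(beta)] <- 0
    fitted[i] <- beta[1L]
    deriv[i] <- beta[2L]
  }
  list(fitted = fitted, deriv = deriv)
}

# shared delimited-text reader: '#'-prefixed "key: value" metadata lines,
# optional header, comma/tab/whitespace separated numeric columns
read_delimited_xy <- function(path, col_names, sep = NULL) {
  if (!file.exists(path)) fp_stop("io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  body_idx <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
      if (length(m) == 3L) {
        key <- trimws(m[2]); val <- trimws(m[3])
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      }
      next
    }
    body_idx <- c(body_idx, i)
  }
  if (length(body_idx) == 0L)
    fp_stop("insufficient_data", "no data rows in %s", path)
  if (is.null(sep)) {
    probe <- lines[body_idx[1]]
    sep <- if (grepl(",", probe)) "," else if (grepl("\t", probe)) "\t" else ""
  }
  split_row <- function(ln) {
    if (sep == "") strsplit(trimws(ln), "\\s+")[[1]]
    else trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
  }
  first <- split_row(lines[body_idx[1]])
  header <- NULL
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    header <- first
    body_idx <- body_idx[-1]
  }
  vals <- matrix(NA_real_, nrow = length(body_idx), ncol = 2L)
  for (r in seq_along(body_idx)) {
    fields <- split_row(lines[body_idx[r]])
    if (length(fields) < 2L)
      fp_stop("parse_error", "line %d of %s: expected 2 columns, found %d",
              body_idx[r], path, length(fields))
    num <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(num)))
      fp_stop("parse_error", "line %d of %s: non-numeric value '%s'",
              body_idx[r], path, fields[1:2][is.na(num)][1])
    vals[r, ] <- num
  }
  list(x = vals[, 1], y = vals[, 2], meta = meta, header = header)
}

write_delimited_xy <- function(x, y, col_names, path, meta = list(), sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    v <- meta[[key]]
    if (is.atomic(v) && length(v) == 1L)
      writeLines(sprintf("# %s: %s", key, format(v)), con)
  }
  writeLines(paste(col_names, collapse = sep), con)
  writeLines(paste(format(x, trim = TRUE, digits = 10),
                   format(y, trim = TRUE, digits = 10), sep = sep), con)
  invisible(path)
}
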