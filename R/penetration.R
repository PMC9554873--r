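#' Drug-induced area expansion at fixed surface pressure
#'
#' Quantifies drug incorporation into a monolayer as the increase in area
#' per molecule at a reference surface pressure when the drug is present in
#' the subphase:
#' \deqn{\Delta A = \bar A_{drug}(\pi_{ref}) - \bar A_{buffer}(\pi_{ref})}
#' where each group mean is taken over replicate curves. Negative values
#' (film condensation) are preserved. The uncertainty is propagated from
#' the replicate standard deviations of the two independent groups as
#' \eqn{\sqrt{SD_{buffer}^2 + SD_{drug}^2}}.
#'
#' @param buffer_curves an [isotherm_curve] or list of replicate curves on
#'   pure buffer
#' @param drug_curves an [isotherm_curve] or list of replicate curves with
#'   the drug in the subphase
#' @param pi_ref reference surface pressure, mN/m (default 20)
#' @return object of class `delta_area` with fields `delta_A`
#'   (Angstrom^2/molecule), `sd`, `pi_ref`, `n_buffer`, `n_drug`,
#'   `mean_buffer`, `mean_drug`
#' @export
delta_area <- function(buffer_curves, drug_curves, pi_ref = 20) {
  as_list <- function(x) if (inherits(x, "isotherm_curve")) list(x) else x
  bc <- as_list(buffer_curves); dc <- as_list(drug_curves)
  if (!length(bc) || !length(dc))
    fp_stop("validation_error", "each group needs at least one curve")
  eval_group <- function(curves, label) {
    vapply(seq_along(curves), function(i) {
      tryCatch(as.numeric(area_at_pressure(curves[[i]], pi_ref)),
               filmphase_out_of_range = function(e)
                 fp_stop("out_of_range",
                         "pi_ref = %g mN/m unreachable in %s curve %d: %s",
                         pi_ref, label, i, conditionMessage(e)))
    }, numeric(1))
  }
  ab <- eval_group(bc, "buffer")
  ad <- eval_group(dc, "drug")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(delta_A = mean(ad) - mean(ab),
                 sd = sqrt(sd0(ab)^2 + sd0(ad)^2),
                 pi_ref = pi_ref,
                 n_buffer = length(ab), n_drug = length(ad),
                 mean_buffer = mean(ab), mean_drug = mean(ad)),
            class = "delta_area")
}

#' @export
print.delta_area <- function(x, ...) {
  cat(sprintf("<delta_area> dA(pi = %g) = %.2f +/- %.2f A2/molecule (n = %d vs %d)\n",
              x$pi_ref, x$delta_A, x$sd, x$n_buffer, x$n_drug))
  invisible(x)
}

#' Assemble a penetration table for a two-drug comparison
#'
#' Collects the single-drug and combination Delta-A readings at a common
#' reference pressure into one record, the unit on which synergy is
#' assessed.
#'
#' @param drug1,drug2,mix `delta_area` results (or numeric Delta-A values)
#'   for the first drug, the second drug and their combination
#' @param sd1,sd2,sd_mix standard deviations, required when the entries are
#'   plain numerics (ignored otherwise)
#' @param pi_ref reference pressure when entries are plain numerics
#' @param labels optional character vector of length 3 naming the entries
#' @param condition optional named list (lipid, subphase, pH)
#' @return object of class `penetration_table`
#' @export
penetration_table <- function(drug1, drug2, mix, sd1 = 0, sd2 = 0, sd_mix = 0,
                              pi_ref = 20,
                              labels = c("drug1", "drug2", "mix"),
                              condition = list()) {
  grab <- function(x, s) {
    if (inherits(x, "delta_area")) c(x$delta_A, x$sd, x$pi_ref) else c(x, s, pi_ref)
  }
  g1 <- grab(drug1, sd1); g2 <- grab(drug2, sd2); gm <- grab(mix, sd_mix)
  prefs <- c(g1[3], g2[3], gm[3])
  if (diff(range(prefs)) > 1e-9)
    fp_stop("inconsistency", "entries evaluated at different pi_ref: %s",
            paste(format(prefs), collapse = ", "))
  if (any(c(g1[2], g2[2], gm[2]) < 0))
    fp_stop("validation_error", "negative standard deviation")
  structure(list(pi_ref = prefs[1],
                 delta_A = c(drug1 = g1[1], drug2 = g2[1], mix = gm[1]),
                 sd = c(drug1 = g1[2], drug2 = g2[2], mix = gm[2]),
                 labels = labels, condition = condition),
            class = "penetration_table")
}

#' @export
print.penetration_table <- function(x, ...) {
  cat(sprintf("<penetration_table> pi_ref = %g mN/m\n", x$pi_ref))
  for (i in 1:3)
    cat(sprintf("  dA_%s = %.1f +/- %.1f A2/molecule\n",
                x$labels[i], x$delta_A[i], x$sd[i]))
  invisible(x)
}

#' Excess-over-additivity synergy score
#'
#' Compares the combination reading with the sum of the single-drug
#' readings at the same reference pressure:
#' \deqn{excess = \Delta A_{mix} - (\Delta A_{drug1} + \Delta A_{drug2})}
#' A positive excess beyond its propagated uncertainty indicates synergy
#' (the drugs incorporate better together), a negative excess beyond
#' uncertainty antagonism; otherwise the interaction is scored additive.
#' This is a derived comparison metric, not a thermodynamic mixing model.
#'
#' @param table a [penetration_table]
#' @return object of class `synergy_excess` with fields `excess`
#'   (Angstrom^2/molecule), `sd`, `flag` (one of "synergistic",
#'   "antagonistic", "additive") and `pi_ref`
#' @export
synergy_excess <- function(table) {
  stopifnot(inherits(table, "penetration_table"))
  excess <- unname(table$delta_A["mix"] -
                     (table$delta_A["drug1"] + table$delta_A["drug2"]))
  sd <- unname(sqrt(sum(table$sd^2)))
  flag <- if (excess - sd > 0) "synergistic"
          else if (excess + sd < 0) "antagonistic"
          else "additive"
  structure(list(excess = excess, sd = sd, flag = flag,
                 pi_ref = table$pi_ref),
            class = "synergy_excess")
}

#' @export
print.synergy_excess <- function(x, ...) {
  cat(sprintf("<synergy_excess> %.2f +/- %.2f A2/molecule at pi = %g mN/m: %s\n",
              x$excess, x$sd, x$pi_ref, x$flag))
  invisible(x)
}

#' Construct a constant-area injection trace
#'
#' Records the surface-pressure response of a preformed monolayer after a
#' drug solution is injected into the subphase at fixed trough area. Time
#' must be strictly increasing; the stated initial pressure must agree with
#' the first recorded pressure within 0.5 mN/m.
#'
#' @param time minutes, strictly increasing
#' @param pressure surface pressure, mN/m
#' @param pi_initial film pressure before injection, mN/m; defaults to the
#'   first recorded pressure
#' @param meta named list (species, concentration_M, ...)
#' @return object of class `injection_trace`
#' @export
injection_trace <- function(time, pressure, pi_initial = NULL, meta = list()) {
  time <- as.numeric(time); pressure <- as.numeric(pressure)
  if (length(time) != length(pressure) || length(time) < 2L)
    fp_stop("validation_error", "time and pressure must match, length >= 2")
  if (!all(is.finite(time)) || !all(is.finite(pressure)))
    fp_stop("validation_error", "non-finite values in injection trace")
  if (any(diff(time) <= 0))
    fp_stop("validation_error", "time must be strictly increasing")
  pi_initial <- pi_initial %||% pressure[1L]
  if (abs(pressure[1L] - pi_initial) > 0.5)
    fp_stop("validation_error",
            "pi at t = 0 (%.2f) disagrees with pi_initial (%.2f) by > 0.5 mN/m",
            pressure[1L], pi_initial)
  structure(list(time = time, pressure = pressure, pi_initial = pi_initial,
                 meta = meta),
            class = "injection_trace")
}

#' Read an injection trace from delimited text
#'
#' Two numeric columns `time_min, surface_pressure_mN_per_m`, with optional
#' `# key: value` metadata lines (species, concentration_M, pi_initial).
#'
#' @param path file path
#' @param sep separator; NULL auto-detects
#' @return an [injection_trace]
#' @export
read_injection_trace <- function(path, sep = NULL) {
  raw <- read_delimited_xy(path, c("time", "pressure"), sep = sep)
  injection_trace(raw$x, raw$y,
                  pi_initial = raw$meta$pi_initial, meta = raw$meta)
}

#' Write an injection trace to delimited text
#' @param trace an [injection_trace]
#' @param path output path
#' @param sep field separator
#' @export
write_injection_trace <- function(trace, path, sep = ",") {
  meta <- trace$meta
  meta$pi_initial <- trace$pi_initial
  write_delimited_xy(trace$time, trace$pressure,
                     c("time_min", "surface_pressure_mN_per_m"),
                     path, meta = meta, sep = sep)
}

#' Surface-pressure rise after subphase injection
#'
#' Evaluates \eqn{\Delta\pi(t) = \pi(t) - \pi_{initial}} at the requested
#' time (linear interpolation between samples) and additionally estimates
#' the plateau rise \eqn{\Delta\pi_\infty} as the mean of the final 10% of
#' samples minus the initial pressure. Optionally fits the saturating
#' exponential \eqn{\Delta\pi(t) = \Delta\pi_\infty (1 - e^{-t/\tau})}.
#' Negative rises (film loss) are reported, not clipped.
#'
#' @param trace an [injection_trace]
#' @param t_eval evaluation time, minutes (default 240, i.e. 4 h)
#' @param fit_exponential also fit the saturating-exponential model
#' @return list with `delta_pi` (at `t_eval`), `delta_pi_plateau`, and when
#'   requested `fit` (list with `delta_pi_inf`, `tau_min`, or NULL if the
#'   fit fails to converge)
#' @export
injection_delta_pi <- function(trace, t_eval = 240, fit_exponential = FALSE) {
  stopifnot(inherits(trace, "injection_trace"))
  if (t_eval < min(trace$time) || t_eval > max(trace$time))
    fp_stop("out_of_range",
            "t_eval = %g min outside recorded span [%g, %g]",
            t_eval, min(trace$time), max(trace$time))
  p_t <- stats::approx(trace$time, trace$pressure, xout = t_eval)$y
  n <- length(trace$time)
  tail_idx <- seq.int(max(1L, n - ceiling(0.1 * n) + 1L), n)
  out <- list(delta_pi = p_t - trace$pi_initial,
              delta_pi_plateau = mean(trace$pressure[tail_idx]) - trace$pi_initial)
  if (fit_exponential) {
    df <- data.frame(t = trace$time, dp = trace$pressure - trace$pi_initial)
    out$fit <- tryCatch({
      fit <- stats::nls(dp ~ dpi * (1 - exp(-t / tau)), data = df,
                        start = list(dpi = max(out$delta_pi_plateau, 0.1),
                                     tau = max(trace$time) / 4))
      as.list(stats::coef(fit))[c("dpi", "tau")] |>
        stats::setNames(c("delta_pi_inf", "tau_min"))
    }, error = function(e) NULL)
  }
  out
}
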