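#' Build and validate a batch run configuration
#'
#' The manifest lists every input file with its experimental condition; the
#' options control the per-curve analyses. Validation happens up front so a
#' bad manifest fails before any computation.
#'
#' @param manifest data frame with columns `path`, `kind` (one of
#'   "isotherm", "saxs", "injection"), `lipid`, `subphase`, `pH`, `drug`
#'   (`"buffer"` for drug-free controls; combination drugs contain `":"`),
#'   and optionally `concentration_M`, `replicate`
#' @param options named list of analysis options: `window`, `degree`,
#'   `prominence`, `pi_ref` (vector of reference pressures for delta-A,
#'   default 20), `rel_tol` (SAXS indexing tolerance)
#' @param out_dir output directory for the results bundle
#' @param seed integer seed recorded in the bundle
#' @param log_level "quiet", "info" or "debug"
#' @return object of class `run_config`
#' @export
run_config <- function(manifest, options = list(), out_dir = tempdir(),
                       seed = 17L, log_level = "info") {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    fp_stop("config_error", "manifest is empty")
  need <- c("path", "kind", "lipid", "subphase", "pH", "drug")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    fp_stop("config_error", "manifest lacks column(s): %s",
            paste(miss, collapse = ", "))
  bad_kind <- setdiff(unique(manifest$kind), c("isotherm", "saxs", "injection"))
  if (length(bad_kind))
    fp_stop("config_error", "unknown kind(s): %s", paste(bad_kind, collapse = ", "))
  gone <- !file.exists(manifest$path)
  if (any(gone))
    fp_stop("config_error", "missing input file(s): %s",
            paste(manifest$path[gone], collapse = ", "))
  lab <- c("lipid", "subphase", "drug")
  if (any(vapply(lab, function(cl) any(!nzchar(manifest[[cl]])), logical(1))))
    fp_stop("config_error", "empty condition labels in manifest")
  # a condition label must map to a single pH
  key <- paste(manifest$lipid, manifest$subphase, manifest$drug, sep = "|")
  for (k in unique(key)) {
    ph <- unique(manifest$pH[key == k])
    if (length(ph) > 1L)
      fp_stop("config_error",
              "condition '%s' maps to multiple pH values: %s", k,
              paste(ph, collapse = ", "))
  }
  opts <- utils::modifyList(
    list(window = 11L, degree = 2L, prominence = 5, pi_ref = 20,
         rel_tol = 0.015), options)
  structure(list(manifest = manifest, options = opts, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

fp_log <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$log_level %||% "info"]] >= levels[[level]])
    message(sprintf("[filmphase] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline over a manifest
#'
#' Reads every input, extracts per-curve isotherm descriptors, groups
#' isotherms by lipid and pH to compute drug-penetration delta-A tables
#' (with a synergy score whenever two single drugs and their combination
#' are present against a buffer control), indexes SAXS patterns, and
#' evaluates injection traces. Results are returned as a bundle and, when
#' `write = TRUE`, written under `config$out_dir` as JSON plus delimited
#' tables. Re-running with the same config and seed reproduces the same
#' bundle.
#'
#' @param config a [run_config]
#' @param write write the results bundle to `config$out_dir`
#' @return object of class `results_bundle`: list with `features` (one
#'   `isotherm_features` per isotherm row), `penetration` (per lipid/pH/
#'   pi_ref: `delta_area` per drug plus optional `synergy`), `saxs`
#'   (`cubic_phase_assignment` per pattern), `injection` (delta-pi records),
#'   `errors` (per-file failures), and the config
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  mf <- config$manifest
  opts <- config$options
  bundle <- list(features = list(), penetration = list(), saxs = list(),
                 injection = list(), errors = list(), config = config)
  curves <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    res <- tryCatch({
      switch(row$kind,
        isotherm = {
          cv <- read_isotherm(row$path)
          fp_log(config, "info", "op=analyze file=%s window=%d prominence=%g",
                 basename(row$path), opts$window, opts$prominence)
          curves[[i]] <- cv
          ft <- analyze_isotherm(cv, config = opts[c("window", "degree",
                                                     "prominence")])
          bundle$features[[basename(row$path)]] <-
            c(list(condition = row[c("lipid", "subphase", "pH", "drug")]),
              list(features = ft))
          NULL
        },
        saxs = {
          pat <- read_saxs(row$path)
          pk <- detect_peaks(pat)
          asg <- index_cubic(pk, rel_tol = opts$rel_tol)
          fp_log(config, "info", "op=saxs file=%s group=%s a=%.3f",
                 basename(row$path), asg$space_group, asg$lattice_parameter_a)
          bundle$saxs[[basename(row$path)]] <- asg
          NULL
        },
        injection = {
          tr <- read_injection_trace(row$path)
          dp <- injection_delta_pi(tr, t_eval = min(240, max(tr$time)))
          fp_log(config, "info", "op=injection file=%s dpi=%.2f",
                 basename(row$path), dp$delta_pi)
          bundle$injection[[basename(row$path)]] <-
            c(dp, list(condition = row[c("lipid", "subphase", "pH", "drug")]))
          NULL
        })
    }, filmphase_error = function(e) conditionMessage(e))
    if (!is.null(res)) bundle$errors[[basename(row$path)]] <- res
  }
  # penetration tables: per lipid x pH group with a buffer control
  iso <- which(mf$kind == "isotherm" & !vapply(curves, is.null, logical(1)))
  if (length(iso)) {
    grp <- paste(mf$lipid[iso], mf$pH[iso], sep = "|")
    for (g in unique(grp)) {
      rows <- iso[grp == g]
      drugs <- mf$drug[rows]
      buf <- rows[drugs == "buffer"]
      if (!length(buf) || all(drugs == "buffer")) next
      for (pref in opts$pi_ref) {
        ent <- list(lipid = mf$lipid[rows[1]], pH = mf$pH[rows[1]],
                    pi_ref = pref, delta_A = list())
        for (d in setdiff(unique(drugs), "buffer")) {
          dr <- rows[drugs == d]
          ent$delta_A[[d]] <- tryCatch(
            delta_area(curves[buf], curves[dr], pi_ref = pref),
            filmphase_error = function(e) conditionMessage(e))
          if (inherits(ent$delta_A[[d]], "delta_area"))
            fp_log(config, "info", "op=delta_area group=%s drug=%s pi=%g dA=%.2f",
                   g, d, pref, ent$delta_A[[d]]$delta_A)
        }
        singles <- names(ent$delta_A)[!grepl(":", names(ent$delta_A))]
        mixes <- names(ent$delta_A)[grepl(":", names(ent$delta_A))]
        ok <- function(x) inherits(x, "delta_area")
        if (length(singles) == 2L && length(mixes) == 1L &&
            all(vapply(ent$delta_A, ok, logical(1)))) {
          tab <- penetration_table(ent$delta_A[[singles[1]]],
                                   ent$delta_A[[singles[2]]],
                                   ent$delta_A[[mixes]],
                                   labels = c(singles, mixes))
          ent$synergy <- synergy_excess(tab)
        }
        bundle$penetration[[paste(g, pref, sep = "|")]] <- ent
      }
    }
  }
  class(bundle) <- "results_bundle"
  if (write) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summarise_features <- function(x) {
    ft <- x$features
    list(condition = as.list(x$condition),
         phase = ft$phase$label,
         max_cs_inverse = ft$phase$max_cs_inverse,
         lift_off_area = ft$lift_off_area,
         limiting_area_A0 = ft$limiting_area_A0,
         areas_at_pressure = as.list(ft$areas_at_pressure),
         transitions = ft$transitions)
  }
  out <- list(
    features = lapply(bundle$features, summarise_features),
    penetration = lapply(bundle$penetration, function(ent) {
      ent$delta_A <- lapply(ent$delta_A, function(d)
        if (inherits(d, "delta_area")) d[c("delta_A", "sd", "pi_ref")] else d)
      if (!is.null(ent$synergy))
        ent$synergy <- ent$synergy[c("excess", "sd", "flag")]
      ent
    }),
    saxs = lapply(bundle$saxs, function(a)
      a[c("space_group", "lattice_parameter_a", "miller_indices",
          "residual", "n_matched")]),
    injection = lapply(bundle$injection, function(x)
      x[c("delta_pi", "delta_pi_plateau")]),
    errors = bundle$errors,
    seed = bundle$config$seed
  )
  jsonlite::write_json(out, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  render_tables(bundle, out_dir)
  invisible(out_dir)
}

#' Render penetration report tables
#'
#' Writes one delimited table per monolayer lipid: one row per drug
#' (single drugs then the combination), one column per subphase pH, cells
#' formatted `mean +/- SD` to one decimal, `NA` where a condition is
#' missing.
#'
#' @param bundle a `results_bundle` from [run_pipeline]
#' @param out_dir output directory
#' @param sep field separator (default tab)
#' @return invisibly, the written file paths
#' @export
render_tables <- function(bundle, out_dir, sep = "\t") {
  if (!length(bundle$penetration)) return(invisible(character(0)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ent_lipid <- vapply(bundle$penetration, function(e) e$lipid, character(1))
  paths <- character(0)
  for (lp in unique(ent_lipid)) {
    ents <- bundle$penetration[ent_lipid == lp]
    phs <- sort(unique(vapply(ents, function(e) as.numeric(e$pH), numeric(1))))
    drugs <- unique(unlist(lapply(ents, function(e) names(e$delta_A))))
    drugs <- c(sort(drugs[!grepl(":", drugs)]), sort(drugs[grepl(":", drugs)]))
    prefs <- sort(unique(vapply(ents, function(e) e$pi_ref, numeric(1))))
    lines <- character(0)
    for (pref in prefs) {
      header <- paste(c(sprintf("delta_A_at_pi_%g", pref),
                        sprintf("pH_%g", phs)), collapse = sep)
      lines <- c(lines, header)
      for (d in drugs) {
        cells <- vapply(phs, function(ph) {
          hit <- Filter(function(e) as.numeric(e$pH) == ph &&
                          e$pi_ref == pref && !is.null(e$delta_A[[d]]) &&
                          inherits(e$delta_A[[d]], "delta_area"), ents)
          if (!length(hit)) return("NA")
          da <- hit[[1]]$delta_A[[d]]
          sprintf("%.1f \u00b1 %.1f", da$delta_A, da$sd)
        }, character(1))
        lines <- c(lines, paste(c(d, cells), collapse = sep))
      }
      lines <- c(lines, "")
    }
    path <- file.path(out_dir, sprintf("penetration_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", lp)))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
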