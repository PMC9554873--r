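#!/usr/bin/env Rscript
# Materialise the standard synthetic study set.
#
# No raw trough or SAXS data accompany the study conditions, so every
# downstream analysis runs on synthetic records with known ground truth:
# four compression isotherms (a POPC-like condensed film, an oracle film
# with a prescribed compressibility profile, a DMPS-like anionic film, a
# cholesterol-like solid film), drug-shifted variants of the POPC- and
# DMPS-like films carrying the published area expansions at 20 mN/m, a
# plateau-transition film, three injection traces starting at 20 mN/m and
# a Pn3m scattering pattern at a = 10.3 nm.

suppressPackageStartupMessages(library(filmphase))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 17L

paths <- write_fixtures(out, seed = seed, noise_sigma = 0.05)
cat("base fixtures:\n"); print(unname(paths))

# drug-shifted families: rigid offsets equal to the tabulated delta-A
# readings for the 1:1 drug combination on acidic buffer
shifts <- list(
  F1_mix = list(A0 = 66, lift_off = 112, max_cs_inverse = 77, shift = 48.3,
                lipid = "POPC-like"),
  F3_dox = list(A0 = 52, lift_off = 110, max_cs_inverse = 186, shift = 38.0,
                lipid = "DMPS-like"),
  F3_mix = list(A0 = 52, lift_off = 110, max_cs_inverse = 186, shift = 73.5,
                lipid = "DMPS-like"))
for (nm in names(shifts)) {
  s <- shifts[[nm]]
  cv <- generate_isotherm(isotherm_spec(
    A0 = s$A0, lift_off = s$lift_off, max_cs_inverse = s$max_cs_inverse,
    drug_shift = s$shift, noise_sigma = 0.05, seed = seed + 10L,
    meta = list(lipid = s$lipid, subphase = "drugged", pH = 5.5)))
  write_isotherm(cv, file.path(out, paste0(nm, "_isotherm.csv")))
  cat(sprintf("%s: +%.1f A2/molecule shift\n", nm, s$shift))
}

# plateau-type transition at 30 mN/m (drug squeeze-out signature)
cv_tr <- generate_isotherm(isotherm_spec(
  A0 = 60, lift_off = 115, max_cs_inverse = 120,
  transition_pi = 30, transition_depth = 60, noise_sigma = 0.05,
  seed = seed + 20L, meta = list(lipid = "plateau-demo", pH = 5.5)))
write_isotherm(cv_tr, file.path(out, "F6_transition_isotherm.csv"))

# injection traces: film preformed at 20 mN/m, drug injected underneath
inj <- list(weak = c(dpi = 1.5, tau = 45), medium = c(dpi = 6, tau = 60),
            strong = c(dpi = 10, tau = 30))
for (nm in names(inj)) {
  tr <- generate_injection_trace(pi_initial = 20,
                                 delta_pi_inf = inj[[nm]][["dpi"]],
                                 tau = inj[[nm]][["tau"]],
                                 noise_sigma = 0.1, duration = 240,
                                 seed = seed + 30L + match(nm, names(inj)),
                                 meta = list(species = nm))
  write_injection_trace(tr, file.path(out, paste0("inject_", nm, ".csv")))
}
cat("injection traces: ", paste(names(inj), collapse = ", "), "\n")
cat("done; fixtures under", out, "\n")
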