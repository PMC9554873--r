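# filmphase

Analysis of drug–membrane interactions at the air–water interface:
Langmuir-monolayer compression isotherms, drug-penetration metrics and
SAXS identification of cubic lipid mesophases.

## The problem

When a drug dissolved in the subphase inserts into a lipid monolayer,
the π–A compression isotherm shifts and the film's mechanical state
changes. Membrane biophysicists quantify this with a small set of
descriptors:

* the **compressibility modulus**
  `Cs⁻¹ = −A (∂π/∂A)_T` (mN/m), whose maximum classifies the film by
  the Davies–Rideal bands — liquid-expanded (12.5–50 mN/m),
  liquid-condensed (50–250), solid (> 250) — and whose minima against π
  mark phase transitions such as drug squeeze-out;
* the **lift-off area** (where π first rises on compression) and the
  **limiting area** `A₀` (extrapolation of the steep branch to π = 0);
* the **area expansion at fixed pressure**,
  `ΔA = A_drug(π_ref) − A_buffer(π_ref)`, read for single drugs and
  drug combinations (reference pressure 20 mN/m), from which an
  excess-over-additivity synergy score is derived;
* the **pressure rise Δπ(t)** after injecting a drug beneath a film
  preformed at 20 mN/m;
* for drug-carrier nanoparticles (cubosomes), the **cubic mesophase**
  identified from 1D SAXS patterns: Bragg peaks at
  `q = (2π/a)·√(h²+k²+l²)` whose spacing ratios
  (√2:√3:√4:√6:√8:√9 for Pn3m) fix the space group and lattice
  parameter `a`.

`filmphase` implements all of these as composable functions plus a
manifest-driven batch pipeline, and ships a seeded synthetic-data
generator that builds isotherms by integrating prescribed Cs⁻¹
profiles — so every descriptor has a known ground truth and the whole
pipeline is testable without laboratory data.

## Worked example

```r
library(filmphase)

# a condensed anionic-lipid film on acidic buffer, ground truth known
buf <- generate_isotherm(isotherm_spec(A0 = 52, lift_off = 110,
                                       max_cs_inverse = 186,
                                       meta = list(lipid = "DMPS-like", pH = 5.5)))
analyze_isotherm(buf)
#> <isotherm_features> phase LC (max Cs-1 183.9 mN/m), A_lift-off 108.8, A0 52.0 A2
#>   A(pi): 10->65.1, 15->55.4, 20->50.0, 25->47.0, 30->45.0, 35->43.6, 40->42.4, 45->41.2

# drug in the subphase shifts the isotherm rigidly by 73.5 A2/molecule;
# the penetration metric reads the shift back at 20 mN/m
drug <- isotherm_curve(buf$area + 73.5, buf$pressure)
delta_area(buf, drug, pi_ref = 20)
#> <delta_area> dA(pi = 20) = 73.50 +/- 0.00 A2/molecule (n = 1 vs 1)

# cubosome SAXS pattern: detect peaks, index the cubic phase, fit a
pat <- generate_saxs(saxs_spec(space_group = "Pn3m", a = 10.3))
index_cubic(detect_peaks(pat))
#> <cubic_phase_assignment> Pn3m, a = 10.300 nm, 6 reflections, RMS rel. residual 5.68e-07
#>   [hkl]: [110] [111] [200] [211] [220] [221]
```

The recovered maximum modulus (183.9 mN/m, within 2% of the prescribed
186) classifies the film liquid-condensed; the limiting area comes back
at 52.0 Å²; the ΔA fixture returns its construction offset exactly; and
the six Pn3m reflections index to the generating lattice parameter.

## Analysis workflow

The `analysis/` scripts run the package as a narrative workflow,
writing tables under `results/`:

```sh
Rscript analysis/01_fixtures.R     # materialise the synthetic study set
Rscript analysis/02_isotherms.R    # per-curve descriptors -> isotherm_features.csv
Rscript analysis/03_penetration.R  # delta-A, synergy, injection kinetics
Rscript analysis/04_saxs.R         # peak detection + cubic indexing
Rscript analysis/05_report.R       # batch pipeline + per-lipid report tables
```

`run_pipeline()` / `render_tables()` provide the same batch analysis
programmatically from a manifest data frame.

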