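---
title: "Methods: monolayer isotherm descriptors, drug penetration and cubic-phase indexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monolayer isotherm descriptors, drug penetration and cubic-phase indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmphase)
```

## What the package computes

`filmphase` analyses three kinds of records from drug--membrane
interaction studies at the air--water interface:

1. **Compression isotherms** of Langmuir monolayers: surface pressure
   $\pi$ (mN/m) against area per molecule $A$ (Å²/molecule), from which
   it extracts the compressibility modulus profile, the monolayer phase
   state, phase-transition minima, the lift-off area, the limiting area
   and areas at target pressures.
2. **Constant-area injection traces**: the pressure rise $\Delta\pi(t)$
   of a film preformed at $\pi_0$ (typically 20 mN/m) after a drug is
   injected into the subphase.
3. **1D SAXS profiles** $I(q)$ of lipid mesophases, from which it
   identifies bicontinuous cubic space groups and fits the lattice
   parameter.

A seeded synthetic-data generator produces all three kinds of records
with known ground truth, so the full pipeline is testable without any
measured data.

## Isotherm descriptors

### Compressibility modulus

The central quantity is the in-plane compressibility modulus

$$C_s^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T,$$

evaluated along the isotherm (`compute_compressibility()`). High values
mean a rigid, condensed film; minima against $\pi$ mark phase
transitions or molecular reorganisations such as drug squeeze-out.

The derivative is estimated by fitting a local polynomial (degree 2,
window 11 samples by default) to $\pi(A)$ and differentiating the fit
analytically. This is the Savitzky--Golay idea generalised to the
non-uniform abscissae that constant-rate compression produces; it is
robust to Wilhelmy-plate noise and exact for locally quadratic signals.
Both window and degree are exposed: widen the window for noisier
records at the cost of smearing narrow transitions. The profile is
reported only where $\pi \ge 1$ mN/m, below which no coherent film
exists and the ratio $A\,\mathrm{d}\pi/\mathrm{d}A$ is dominated by
noise.

### Phase classification

`classify_phase()` applies the Davies--Rideal criterion to the maximum
of the profile: max $C_s^{-1}$ in 12.5--50 mN/m indicates a
liquid-expanded (LE) film, 50--250 mN/m liquid-condensed (LC), above
250 mN/m solid (S); below 12.5 mN/m the film is treated as gaseous (G,
a band the criterion itself does not name). Boundaries are
lower-inclusive, so 50 mN/m classifies as LC. The classification is a
deterministic step function; no interpolation between bands is
attempted.

### Transitions

`detect_transitions()` reports local minima of $C_s^{-1}$ versus $\pi$
ranked by topographic prominence (the depth below the lower of the two
enclosing maxima). The default prominence floor is 5 mN/m; minima in
the first and last two grid points are suppressed because one-sided
derivative estimates there are unreliable. For noisy records the floor
should be raised above the modulus noise level (pressure noise
$\sigma_\pi$ maps to modulus noise of roughly
$A\,\sigma_\pi\,c/\Delta A$ with $c \approx 0.3$ for the default
window, i.e. a few mN/m for $\sigma_\pi = 0.05$ mN/m); the analysis
scripts use 15 mN/m. When a single "principal" transition must be
named, the package's own analyses take the deepest minimum at
$\pi \ge 5$ mN/m — below that the film is still forming and minima are
not interpretable as phase transitions.

### Lift-off and limiting area

The lift-off area is where $\pi$ first rises from baseline on
compression. The baseline is the largest-area 10% of samples; the
detection threshold is the baseline mean plus
$\max(3\sigma_{\text{baseline}}, 0.2\ \text{mN/m})$, the rise must
persist at all smaller areas, and the value reported is the last
sample at or below threshold. The 0.2 mN/m floor reflects typical
Wilhelmy-plate resolution; without it a noise-free record would have a
zero threshold and any numerical ripple would trigger detection.

The limiting area $A_0$ extrapolates the steep, linear part of the
isotherm to $\pi = 0$. "Linear part" is operationalised as the
contiguous run of samples whose $C_s^{-1}$ is at least 80% of its
maximum (at least 10 points); this automatically stops below transition
dips and collapse plateaus, where the modulus drops. A straight line is
least-squares fitted ($\pi$ on $A$) and $A_0$ is its $\pi = 0$
intercept; slope and window are kept as diagnostics.

### Areas at pressure, collapse handling

$A(\pi)$ is evaluated by piecewise-linear interpolation along the
compression branch (`area_at_pressure()`), exact at sample points. The
branch is truncated at the first collapse event: a (median-smoothed)
pressure maximum followed by a drop of at least 1 mN/m once a film
exists ($\pi > 10$ mN/m), or a sustained plateau with
$|\mathrm{d}\pi/\mathrm{d}A| < 0.05$ mN·m⁻¹/Å² over at least 10
samples at $\pi > 15$ mN/m. Where noise makes $\pi$ locally
non-monotone, the upper envelope is used so $A(\pi)$ stays
single-valued. Note that $A(\pi)$ on the real curve lies below the
$A_0$ extrapolation line — the isotherm is convex — so e.g.
$A(20) < A_0$ is expected, not an error.

## Drug penetration

### The ΔA metric

Incorporation of a drug into the film is quantified at a reference
pressure (default 20 mN/m) as

$$\Delta A = \bar A_{\text{drug}}(\pi_{\text{ref}}) -
             \bar A_{\text{buffer}}(\pi_{\text{ref}}),$$

with each group mean taken over replicate curves
(`delta_area()`). Replicates are aggregated per curve first (one
$A(\pi_{\text{ref}})$ per experiment) rather than by averaging curves
pointwise, matching how such tables are built from repeated runs; the
uncertainty is
$\sqrt{SD_{\text{buffer}}^2 + SD_{\text{drug}}^2}$ assuming the two
groups are independent. Negative values (condensation) are reported
unchanged.

### Synergy

When two drugs and their combination are measured against the same
buffer control, `synergy_excess()` scores the interaction as the
excess over additivity,
$\Delta A_{\text{mix}} - (\Delta A_{1} + \Delta A_{2})$, with
propagated SD, flagged synergistic/antagonistic only when the excess
exceeds its uncertainty. No formula for this comparison is standard in
the monolayer literature — tables are usually inspected by eye — so the
excess is explicitly labelled a derived metric. It is symmetric in the
two drugs by construction.

### Injection kinetics

`injection_delta_pi()` reports $\Delta\pi(t) = \pi(t) - \pi_0$ at a
requested time (default 240 min, i.e. the 4 h reading) by linear
interpolation, plus a model-free plateau estimate (mean of the final
10% of samples minus $\pi_0$). A saturating-exponential fit
$\Delta\pi_\infty(1 - e^{-t/\tau})$ is available but optional, since
adsorption kinetics frequently deviate from single-exponential
behaviour; no mechanistic adsorption model is fitted.

## SAXS cubic-phase identification

Bragg peaks of a cubic lattice fall at
$q = (2\pi/a)\sqrt{h^2 + k^2 + l^2}$. The libraries cover the three
bicontinuous cubic groups seen in lipid mesophases — Pn3m
($\sqrt2:\sqrt3:\sqrt4:\sqrt6:\sqrt8:\sqrt9$; [110], [111], [200],
[211], [220], [221]), Im3m ($\sqrt2:\sqrt4:\sqrt6:\sqrt8:\sqrt{10}:
\sqrt{12}$) and Ia3d ($\sqrt6:\sqrt8:\sqrt{14}:\sqrt{16}:\sqrt{20}:
\sqrt{22}$).

`detect_peaks()` subtracts a rolling-median background (window 5% of
the $q$ range), keeps local maxima above a relative height threshold
with a minimum separation, and refines each centre by fitting a
parabola to the log of the background-subtracted intensity at the
three samples around the maximum — exact for Gaussian peaks. The
rolling median is deliberately short so it tracks smooth scattering
backgrounds; it partially absorbs peak tails, which biases width
estimates but not positions (the quantity indexing uses).

`index_cubic()` anchors the lowest-$q$ peak on the group's lowest
allowed reflection and matches the remaining peaks greedily, in
increasing $q$, within a relative tolerance (default 1.5%). Library
entries may be skipped without penalty (unobserved reflections — the
indexer succeeds whether five or six reflections are present), while
observed peaks matching nothing add a fixed penalty (default 0.02) to
the selection score. The candidate with the lowest
RMS-residual-plus-penalty and at least three matches wins; ties go to
more matches, then library order. `fit_lattice_parameter()` then
refines $a$ by a least-squares fit of $q_{\text{obs}}$ against
$\sqrt{N}$ through the origin; fewer than three distinct reflections
is a degenerate fit and an error.

## The synthetic-data generator

### Isotherms

Rather than adopting a named 2D equation of state, `generate_isotherm()`
prescribes the compressibility profile itself and integrates the
defining relation

$$\frac{\mathrm{d}A}{\mathrm{d}\pi} = -\frac{A}{C_s^{-1}(\pi)},
  \qquad A(0) = A_{\text{lift-off}},$$

so every descriptor the pipeline extracts is known by construction.
The profile is a smooth Gaussian bump peaking at the requested
`max_cs_inverse` (by default at 90% of the recorded pressure range,
width 45% of the peak position), sitting on a low-pressure baseline.
That baseline is not a free knob: it is solved by root-finding so that
the straight-line extrapolation of the $C_s^{-1} \ge 0.8\,\max$ branch
— the definition of $A_0$ — hits the requested limiting area. The
solve is performed on an area-uniform resampling of the analytic
curve, the sampling measure of a constant-rate compression record.

Optional features:

* a **transition dip** (Gaussian, default width 2 mN/m) carved into
  the profile; its centre is offset analytically so the composite
  profile bottoms out exactly at `transition_pi` despite the sloping
  bump underneath. The default width and the deep dips used in the
  package's own study fixtures emulate the sharp plateau-type minima
  compression isotherms show when drugs are squeezed out of the film,
  where the modulus falls to a few tens of mN/m;
* a **collapse plateau** above `collapse_pi` (area keeps decreasing at
  near-constant pressure);
* a **rigid area shift** (`drug_shift`) encoding a drug-induced ΔA
  reading, and an independent **profile rescale** (`cs_scale`)
  encoding fluidisation. The two are deliberately separate: a rigid
  shift alone raises the apparent modulus in proportion to
  $(A + \text{shift})/A$, so shift fixtures are read only at the
  reference pressure;
* seeded Gaussian pressure noise (floored at $-0.9$ mN/m, the
  validity limit of a pressure record). Generators are pure functions
  of their spec and never disturb the caller's RNG state.

A 15% zero-pressure gas segment above the lift-off area precedes the
film, giving the lift-off detector a baseline.

### What the generator does and does not emulate

It reproduces the features the descriptors respond to: monotone
compression, phase-dependent stiffness, plateau transitions, collapse,
rigid drug shifts, uncorrelated pressure noise. It does not model
drift, correlated (1/f) trough noise, leakage, hysteresis,
impurity-induced lift-off tails, or any physical insertion mechanism —
passing round-trip tests therefore demonstrates correctness of the
numerics, not validity of any physical model of drug insertion.

### Injection traces and SAXS patterns

Injection traces are saturating exponentials with seeded noise and the
$t = 0$ sample anchored at $\pi_0$. SAXS patterns place Gaussian peaks
with geometrically decaying heights at the library positions on a
smooth decaying background. Neither emulates detector artefacts,
smearing or form-factor modulation.

## Problem sizes and determinism

The package's own analyses use 400-sample isotherms, 241-sample
injection traces and 1200-point SAXS patterns; property suites run 100
randomised closed-form isotherms for the derivative oracle and 100
noise seeds for parameter recovery, with all seeds fixed (default 17).
Identical configurations reproduce byte-identical result bundles;
timestamps appear only in logs.

## Known limitations

* The derivative window trades noise against resolution; transitions
  narrower than the window's pressure span are attenuated, and their
  measured prominence understates the prescribed dip depth.
* The transition detector reports *all* prominent minima; naming one
  of them "the" transition requires the depth-and-floor convention
  described above, which a sufficiently pathological profile could
  defeat.
* $A_0$ extrapolation assumes the condensed branch is approximately
  linear over the fit window; strongly curved condensed branches (very
  low moduli) carry a few tenths of Å² of systematic bias.
* The SAXS indexer assumes the first detected peak is a true
  reflection; a spurious low-$q$ peak (e.g. residual beam-stop tail)
  would mis-anchor the ratio sequence.
* Synergy is a descriptive excess-over-additivity score, not a
  thermodynamic mixing analysis.
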