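---
title: "Classifying protein conformational states from solution biophysics"
author: "moltenscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein conformational states from solution biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltenscope)
```

# The problem

A flexible, partially disordered protein defeats any single structural
probe. Size-exclusion chromatography calibrated with globular standards
reads its mass high, because disordered parts occupy more volume per
dalton than a globule does. A SAXS radius of gyration on its own does not
say whether the chain is collapsed or expanded. Circular-dichroism
unfolding curves lose their sigmoid when tertiary contacts are weak.
The decision between the canonical states — native globule, molten
globule (compact, native-like secondary structure, fluctuating tertiary
contacts), pre-molten globule (partially collapsed, little persistent
structure), and extended coil — therefore rests on the *pattern of
agreement* across probes. This package implements each probe's analysis
and the integration step, with every stage testable against synthetic
data generated from the analytic models the analyses assume.

# Sequence indicators

`compositionProfile()` computes residue-class statistics from a sequence
(FASTA input via `readProteinFasta()`, which validates against the 20
canonical residues; strict mode errors at the offending position, lenient
mode drops with a warning).

* **Residue classes.** The order-promoting set {I, C, L, V, W, Y, F} —
  the bulky residues that build hydrophobic cores — and the complementary
  13-residue disorder-promoting set partition the alphabet, so the two
  fractions always sum to one; this is asserted as a package invariant.
* **Mass.** Average (not monoisotopic) residue masses with one water,
  matching the convention of standard protein-parameter calculators.
* **Charge–hydropathy placement.** The abscissa ⟨H⟩ is the Kyte–Doolittle
  scale rescaled to [0, 1] by (v − min)/(max − min), averaged in sliding
  windows of 5 residues and then across windows — the canonical recipe
  for the folded/unfolded phase boundary. The ordinate ⟨R⟩ at pH 7 is the
  plain counting convention |#(K,R) − #(D,E)|/N, ignoring histidine and
  termini, because that is the convention under which the boundary
  ⟨R⟩_b = 2.785⟨H⟩ − 1.151 was derived. At any other pH a
  Henderson–Hasselbalch per-residue model with the EMBOSS pKa table is
  used instead (side chains C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
  Y 10.1; termini 8.6/3.6). Points exactly on the boundary are assigned
  to the native side so the classification is total; the signed
  perpendicular distance is returned so borderline calls are visible.

# Hydrodynamics

`partitionCoefficient()` is the textbook K_av; elution outside [V₀, V_t]
is returned (outside [0, 1]) with a warning rather than clipped, because
a flagged impossible value is more informative than a silently repaired
one. `calibrateSEC()` fits ordinary least squares of K_av against
log₁₀(R_h) and log₁₀(M); no robust fitting is offered since SEC
calibrations have few points and outliers should be inspected, not
down-weighted. `secEstimate()` inverts the lines, warning on
extrapolation.

`siegelMonteMass()` evaluates M = s·N₀·6πηR_h/(1 − ν₂ρ) with all unit
conversions centralised (1 S = 10⁻¹³ s, radii in nm, result in Da).
Defaults η = 0.001 Pa·s and ν₂ρ = 0.73 encode water viscosity and the
standard protein partial specific volume ν₂ = 0.73 cm³/g in a ρ = 1 g/cm³
solvent. The relation is exactly linear in s and in R_h, which the tests
assert directly.

`conformerRh()` evaluates the empirical per-state compaction laws
log₁₀ R_h[Å] = a·log₁₀ M[Da] + b with the coefficient set

| state | a | b |
|---|---|---|
| native | 0.369 | −0.254 |
| molten globule | 0.334 | −0.053 |
| pre-molten globule | 0.392 | −0.188 |
| urea-unfolded | 0.493 | −0.649 |
| GdmCl-unfolded | 0.526 | −0.691 |

The literature carries more than one published set, so the table lives in
`scalingLaws()` and can be replaced wholesale. The adopted set was chosen
because it reproduces the standard anchor points — about 3.1 nm for a
55.1 kDa native globule and about 3.4 nm for a molten-globule dimer of
the same mass — and its exponents increase from native to unfolded, so
more expanded states grow faster with mass (asserted as an invariant).

`qFactor()` is R_g/R_h with quadrature error propagation. `qClassify()`
reports *all* bands containing Q — sphere 0.775 ± 0.01, globular
0.76–0.86, molten globule 0.70–0.93, pre-molten globule 0.93–1.15, coil
≥ 1.35 — plus bands whose edge lies within 0.1 of Q as "adjacent". The
overlaps are intentional: Q alone cannot separate a molten globule from
a pre-molten globule near their shared edge, and the classifier resolves
that with the Kratky shape. `idealCoilQFactor()` provides the coil
reference from first principles: for an N-bead Gaussian chain,
R_g = b√(N/6) and the Kirkwood inverse hydrodynamic radius
1/R_h = N⁻²·Σ_{i≠j}√(6/π)/(b√|i−j|). The sum converges from below
(≈ 1.488 at N = 10⁴, ≈ 1.499 at N = 10⁵) toward the commonly quoted 1.51.

# SAXS

`guinierFit()` fits ln I = ln I₀ − q²R_g²/3 by least squares, weighted by
(I/σ)² when errors are present (the correct weights for a log-transformed
ordinate). The window is found by fixed-point iteration: the first fit
uses the lowest-q decade, the point set is then recomputed as
qR_g ∈ [0.759, 1.294] with the current R_g, and the fit repeats until the
set is stable (cap 50 iterations; on an oscillating cycle the smaller
window is kept and the result flagged unconverged). A window with fewer
than 5 points is an error, as is a non-negative slope (no Guinier
region).

**Known bias.** The Guinier law is exact only as q → 0. Expanding the
hard-sphere form factor gives ln P = −(qR)²/5 − 0.00286(qR)⁴ + …, so a
least-squares line over the conventional window overestimates R_g by
about +2.6% for a sphere; for a Gaussian coil the deviation has the
opposite sign and is larger (about −11%), which is why coil Guinier
ranges are normally restricted to qR_g < 1. The package does not attempt
to correct this: the fixed-window estimator is the field's canonical
procedure and the bias is a property of the estimator, not a bug. The
test suite freezes both biased values against the analytic oracles, and
asserts exact (< 0.1%) recovery for curves that obey the Guinier law at
all q, which isolates the bias from implementation error.

`dimensionlessKratky()` plots y = (qR_g)²·I/I₀ against x = qR_g. Peak
detection runs on a Savitzky–Golay-smoothed copy (window 11, order 3 —
wide enough to suppress grid noise, narrow enough to keep the ~0.5-wide
physical maximum); the interior global maximum qualifies as a peak when
its prominence (height above the lowest smoothed level between the peak
and the high-x end) exceeds 5% of the curve maximum. For a Guinier-limit
curve the peak sits at x = √3 with height 3/e, a closed form the tests
check. The tail level is the mean y over x ∈ [2.5, 4]; a curve not
reaching x = 4 is classified `inconclusive`.

`kratkyClassify()` applies the qualitative pattern rules: peak with a low
tail → `globular_compact`; peak with tail ≥ `peakFraction` × peak height
→ `compact_plus_flexible`; no qualifying peak → `extended`. The
`peakFraction` default is 0.5. This threshold separates the two analytic
anchors cleanly: a pure sphere has tail/peak ≈ 0.13, while a 60/40
sphere+coil intensity mixture — the model of a compact domain linked to a
disordered one — has tail/peak ≈ 0.68 (the Debye coil's dimensionless
Kratky ordinate plateaus at 2, holding the mixture's tail up). A higher
threshold such as 0.8 would misread that canonical hybrid as a plain
globule, so 0.5, the midpoint separator between the two anchors, is the
shipped default; it is configurable because the pattern scheme is
qualitative by nature.

# Titrations

`sternVolmerFit()` fixes the intercept at 1 because F₀/F = 1 at [Q] = 0
by construction (a free intercept is available for diagnostics). The
linearity verdict tests the quadratic term of an unconstrained fit at
α = 0.01; downward curvature is the signature of fluorophore populations
with unequal accessibility. Ratios below 1 beyond a 2% tolerance warn.

`unfoldedFraction()` uses the linear-baseline construction
f_d = (y − y_N)/(y_D − y_N); baselines may be supplied or fitted from
flanking x-ranges. Values outside [0, 1] are flagged, not clipped —
clipping would bias subsequent fits.

`fitUnfolding()` operationalises "low cooperativity": it fits both a
two-state model with linear baselines (chemical:
ΔG = ΔG₀ − m[D], RT = 0.5925 kcal/mol at 298 K; thermal: van 't Hoff in
ΔH_vH and T_m) and a straight line, compares them by AICc, and calls the
transition `cooperative` only when the two-state model wins by more than
ΔAICc = 4 (the conventional "considerably less support" cutoff), its
steepness parameter is positive, and the fitted midpoint is interior to
the sampled range — otherwise `weakly_cooperative_or_linear`. Start
values come from the signal ends and the half-signal crossing, with a
small ladder of fallback m-values; a non-converging two-state fit falls
back to the linear verdict with a flag, and a constant signal returns a
`degenerate` flag and no verdict. With fewer points than the two-state
parameter count allows (n ≤ 8), the AICc correction is infinite and the
model cannot win — a deliberate property, not a failure mode.

`lambdaMaxSeries()` extracts emission maxima by parabolic interpolation
through the grid maximum and its neighbours (±0.1 nm on a 1-nm grid);
edge maxima cannot be interpolated and flag the series.

# Evidence integration

`classifyState()` uses linear additive voting: each populated channel
splits one (weighted, default equal) vote over the states it supports —
charge–hydropathy native side → {native, MG}; Q-band membership → the
bands' states; minimal R_h-law deviation → that state; Kratky
`globular_compact` → native, `compact_plus_flexible` → MG, `extended` →
{pre-MG, coil}; cooperative unfolding → native, non-cooperative →
{MG, pre-MG, coil}; high ANS affinity → MG; λ_max ≤ 330 nm → native,
330–350 nm → MG, ≥ 350 nm → {pre-MG, coil}. Scores are normalised to sum
to 1. A probabilistic model was deliberately avoided: the underlying
reasoning is qualitative rule accumulation, and additive votes keep every
score traceable to its channels (each channel also emits a rationale
sentence). Ties break by channel priority — Kratky > R_h deviation > Q >
unfolding > charge–hydropathy > ANS/λ_max — because the Kratky shape is
the probe that actually separates MG from pre-MG when Q sits between
their bands. Confidence: `strong` when the top score is ≥ 0.5 with a
margin ≥ 0.15, `weak` when the margin is < 0.1 or fewer than two channels
voted, else `moderate`. The equal default weighting is a package choice,
exposed in `defaultSettings()` so sensitivity can be tested.

# The synthetic-data module

Generators produce exactly the structures the analyses assume: sphere
form factor, Debye coil, and their intensity mixtures on a
0.05–4.0 nm⁻¹, 400-point grid (a typical beamline range); SEC runs from a
linear K_av–log R_h law; gradient migration linear in s; Stern–Volmer
lines; two-state or linear unfolding titrations (20 points over 0–5 M by
default); and composition-targeted random sequences. Noise is additive
Gaussian, relative or absolute, and each generator derives its own
pseudorandom stream from (seed, generator name), so fixtures are
independent and byte-reproducible, and the global random stream is left
untouched.

What this validates — and what it does not: passing round-trip tests
shows the estimators are correct for data that obey the generating
models with uncorrelated Gaussian noise. Real measurements add
background-subtraction residuals, inter-particle interference and
concentration effects in SAXS, column non-ideality in SEC, and baseline
drift in titrations; none of these are emulated, so performance on real
data is bounded by how well those upstream corrections were done.

# Problem sizes and run times

All analyses here are desk-scale. The shipped tests use 400-point
scattering curves, 100-seed recovery ensembles for Guinier and unfolding
fits, 50-seed ensembles for calibration noise, and a 10⁵-bead Kirkwood
sum; the whole suite and the acceptance script each run in well under a
minute on a single core.

# Known limitations

* Fixed-window Guinier estimates carry the shape-dependent biases
  described above; quantitative R_g comparisons across shapes should use
  matched windows.
* No indirect-transform P(r) analysis, ab initio shape reconstruction,
  DLS autocorrelation fitting, or CD spectral deconvolution is included;
  those belong to their dedicated tools upstream of this package.
* The apparent-mass route through SEC assumes the standards' conformation
  and is reported as evidence *against* globularity when it disagrees
  with the Siegel–Monte mass — it is not a mass measurement for
  non-globular analytes.
* Thermal unfolding uses an equilibrium two-state form; irreversible
  thermal transitions violate its assumptions and should be interpreted
  qualitatively.
* The classifier's weights and bands are transparent configuration, not
  fitted parameters; its output is a structured summary of evidence, not
  a posterior probability.
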