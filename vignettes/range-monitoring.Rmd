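---
title: "Range monitoring with charged secondaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range monitoring with charged secondaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmon)
```

`fragmon` models the chain that turns secondary charged fragments emitted by
a therapeutic ion beam into an estimate of the Bragg-peak position: ion
transport, fragment emission, escape through the patient/phantom, tracking,
vertexing, profile fitting and absorption unfolding. This vignette is the
package's own account of each model, its assumptions, the defaults, and what
the simulation does *not* capture.

## Ion transport

Stopping power is the relativistic Bethe–Bloch formula without density-effect
or shell corrections. At the energies of interest here (protons up to
250 MeV, carbon at 80–400 MeV/u) those corrections shift the stopping power
by under ~2 %, which is well inside the ±0.30 cm tolerance we attach to
range predictions; omitting them keeps the formula hand-checkable (the test
suite pins three reference points evaluated term by term). Mean excitation
energies are I(water) = 75 eV and I(PMMA) = 74 eV; PMMA is C₅H₈O₂ at
1.19 g/cm³.

The CSDA range integrates `dE/S(E)` by adaptive quadrature (relative
tolerance 1e-8) from a 1 MeV/u cutoff: below that the residual range is under
0.3 mm, irrelevant at the millimetre scale of range monitoring. Forward and
inverse slab transport use range algebra — the exit energy is the energy
whose residual range equals `R(E0) − t` — with bracketed root-finding to
1e-9 MeV, which makes `invert_energy_loss(transport_energy(E0, t), t) = E0`
a sub-µeV round trip by construction. The depth–dose curve is pure CSDA:
`dose(z) ∝ S(E(z))` up to the range, with no nuclear attenuation of the
primary, no fragmentation tail beyond the peak, and no lateral spreading.
Its purpose is to furnish the Bragg depth `Δ_beam` and a visual reference,
not dosimetry.

Water-equivalent thickness (WET) uses one multiplicative factor per
material: `path × (ρ/ρ_water) × rsp_mass`, with `rsp_mass(PMMA)` set to
1.16/1.19 so that bulk PMMA has the conventional 1.16 length equivalence.
Inside a phantom the Bragg position is found by marching the beam axis
through the region sequence and stopping where the accumulated WET equals
the beam's CSDA range in water.

## Phantoms and ray tracing

Phantoms are ordered lists of analytic solids (sphere, box, cylinder), each
with a material and optional density override; later regions take precedence
inside earlier ones, which is sufficient for nested-sphere and slab
geometries without full constructive solid geometry. Chord lengths are exact
quadratic/slab intersections; rays tangent to a surface (discriminant below
1e-12) count as misses, a deliberate tie-break that avoids zero-length
slivers. The test suite checks the analytic tracer against a brute-force ray
marcher at 1e-3–1e-4 cm steps and verifies rigid-motion invariance.

## The emission model — what it emulates and what it does not

The generator is a *calibration*, not microscopic nuclear physics. Its
defaults define the study conditions:

* **Longitudinal shape**: double-logistic with the rising midpoint at the
  phantom entrance (width 0.4 cm) and the falling midpoint at 0.65 of the
  Bragg depth beyond the entrance (width 1.7 cm). The falling width comes
  from the closed-form identity `p2 = 3(δ₄₀ − Δ₄₀)/5` applied to the
  reference profile means (6.60 and 9.40 cm for the 220 MeV/u, 90°
  configuration); with these defaults the generated profile's fitted Δ₄₀ is
  ≈ 6.9 cm, within 10 % of the 6.60 cm reference. The flat background
  (5 % of the plateau) is treated as *ambient* — present from the upstream
  display margin through the phantom exit — because measured profiles show
  background on both sides of the entrance; the signal component still dies
  out before the Bragg depth. Hard support cutoffs inside the fit window
  would otherwise bias the background estimate through structurally empty
  bins.
* **Energy spectrum**: shifted exponential, mean 90 MeV, truncated to
  7–250 MeV. The lower edge is the detection threshold of the reference
  measurement; the mean encodes that only protons above ~50–60 MeV escape
  deep tissue in useful numbers. This is a documented calibration choice.
* **Angular yields**: a per-primary per-steradian table, default
  12.59×10⁻³ sr⁻¹ at 60° and 2.74×10⁻³ sr⁻¹ at 90°, linearly interpolated
  and never extrapolated. Rate queries are pure arithmetic
  (`count = N_primaries × yield × ΔΩ`), with the exact pyramid solid angle
  for rectangular apertures.
* **Escape**: survival = (range cut) × exp(−x/λ_nuc) with λ_nuc = 80 cm WET
  (the proton nuclear interaction length scale in water). The range cut —
  the emission energy must exceed the energy whose water range equals the
  exit WET — dominates the attenuation; with the default spectrum the mean
  survival drops by roughly an order of magnitude between shallow
  (~2.5 cm) and very deep (~20–30 cm) exit paths.
* **Multiple scattering**: Highland width
  `θ₀ = 13.6 MeV/(βcp) √t (1 + 0.038 ln t)` with `t` the exit path in
  water radiation lengths and `βcp` at the mean of emission and exit
  energies. The smeared direction is pivoted at the *geometric phantom exit
  point*: scattering happens inside the phantom, so the measured line keeps
  its physical lever arm; pivoting at the vertex would leave the vertex
  estimate artificially unbiased.
* **Importance sampling**: directions are drawn uniformly in solid angle
  inside a 25° cone around the detector direction, so desk-scale runs need
  10⁴–10⁵ tracks instead of the ~10⁸ primaries a full 4π simulation would
  take; absolute rates are handled analytically by the yield table.

Not emulated: species other than protons in the defaults (deuterons/tritons
ride the same machinery with their own yield tables), z-dependence of the
emission spectrum, the projectile-fragment forward tail beyond the Bragg
peak, prompt photons, and detector hardware effects (quenching, saturation,
hit-level reconstruction). Passing tests therefore demonstrate the *method*
— fitting, observables, unfolding — under controlled conditions, not the
fidelity of any particular beam model to real data.

## Reconstruction

The emission-point estimate is the point **on the known beam line** closest
to the measured track line (POCA): with pencil-beam scanning the transverse
beam position is delivery-system knowledge, so the beam-line point is the
better-constrained estimate, and the line–line distance is exported as a
quality metric. Parallel geometries (|sin| < 1e-9) raise an error rather
than returning an arbitrary midpoint. The longitudinal coordinate is the
projection on the nominal beam axis, in cm relative to the phantom centre.
Profiles use half-open 0.2 cm bins by default, with under/overflow kept
separate and per-bin errors from summed squared weights.

The beam-spot projection term `σ = σ_beam·|cot θ|` (exactly zero at 90°, by
`cospi`/`sinpi` arithmetic) can be folded into the fit model as a Gaussian
convolution, evaluated by a trapezoidal kernel over ±5σ on a grid ten times
finer than the narrowest model scale.

## Profile fitting and the range observables

Both fit models (erfc fall-off and double-logistic) are weighted least
squares on bin centres via Levenberg–Marquardt. The first pass uses
empirical Poisson variances `max(count, 1)`; a second pass reweights with
model variances `max(fitted, 1)`. The second (Pearson) pass matters: with
purely empirical weights, downward-fluctuating low-count bins are
over-weighted and the pull distribution of the edge parameters at the
kilotrack statistic widens to σ ≈ 1.3 instead of 1. Initialisation is
automatic — plateau from the 90th-percentile bin, background from the outer
bins, edge midpoints from the 40 % crossings, and edge widths from the
80 % → 40 % crossing separation (a logistic drops from 0.8 to 0.4 of its
plateau over 1.79 widths). A deterministic ladder of jittered restarts keeps
fits reproducible without consuming RNG state; the best-χ² valid fit wins,
which protects against the local minimum in which one wide logistic absorbs
both the plateau tilt and the background.

The observables interpret "40 % of maximum" as 40 % of (max − background)
*above* background, making Δ₄₀ invariant under background shifts (the
drawn definition coincides with this when the background is zero). X_left
and X_right are the outermost level crossings by bracketed root-finding at
1e-10 tolerance; δ₄₀ takes the tangent at X_right to its intersection with
the background level. In the well-separated-edge limit these reduce to
`X_right = p1 + p2 ln 1.5`, `X_left = p3 − p4 ln 1.5`,
`δ₄₀ = Δ₄₀ + (5/3)p2`, which the tests verify to 1e-6 cm alongside a dense
brute-force scan to 1e-4 cm. Uncertainties propagate the full fit
covariance through a numerical Jacobian — parameter correlations (notably
p1–p2–p5) are substantial, and diagonal-only errors would overstate them.

Dispersions at fixed statistics use disjoint subsets by default (matching
how fixed-size samples are carved out of a measured dataset), bootstrap
optionally; a single sample reports `NA`, never zero. The acceptance suite
runs 30 disjoint kilotrack samples plus 12 samples of 4 000 tracks to check
both the millimetre scale of the dispersions and their 1/√n statistical
scaling.

## Absorption unfolding

For each thickness `x_j` on a grid (default 2.5–10 cm WET in 1.5 cm steps;
the reference `x0` is the grid minimum), the simulator produces a
constant-thickness detected profile, fits it, and the six fitted parameters
are modelled as degree-2 polynomials in `x` (the trends are smooth and
low-order; degree is configurable 1–3). The LUT thickness axis is
water-equivalent, so one table serves mixed-density geometries through the
per-track exit WET. Amplitudes are stored per generated track (per-primary
normalisation), making tables comparable across node statistics.

Each detected track is then re-weighted by `w(z, x) = f(z, x0)/f(z, x)` — a
*multiplicative restoring* weight, equal to 1 at the reference thickness and
greater than 1 wherever more material suppressed the counts. The denominator
is floored at 1e-3 of the reference-curve maximum and weights are capped at
20, with the capped fraction reported: in the far tails the ratio of two
fitted curves is ill-conditioned and a logged cap is preferable to a silent
near-infinity. Out-of-span thicknesses are refused by default and clamped
(with bookkeeping) inside the pipeline, where thin slivers of geometry
routinely graze the span ends.

In the nested-sphere demonstration (10 cm PMMA sphere at 1.2 g/cm³ with a
3 cm, 0.6 g/cm³ core), the exit thickness varies strongly with emission
depth, the raw reconstructed profile is statistically incompatible with the
generated one (two-sample KS), and the re-weighted profile is compatible at
the 2×10⁴-generated-track scale the packaged configuration uses. A known
limitation: the tracker's geometric acceptance also varies (by a few
percent) with emission depth — a solid-angle effect, not absorption — and
the weighting deliberately does not correct it, so at much larger samples
the KS test would eventually resolve this residual tilt.

## Determinism and problem sizes

Every stochastic stage draws from its own RNG stream derived from one master
seed by fixed affine hashing, so changing, say, the detector smearing never
perturbs the emission sample. All sampling is wrapped so the caller's RNG
state is untouched. The default problem sizes — 2×10⁴ generated tracks per
run, 2×10⁴ per LUT node, 200 replicas in the pull and coverage studies,
78 000 tracks in the dispersion study — were chosen as the smallest samples
at which the statistical checks are comfortably resolved.

## Known limitations

* The transport is uncorrected Bethe–Bloch/CSDA: no straggling, no nuclear
  attenuation of the primary, no fragmentation tail; range predictions
  carry a ~1–3 % model uncertainty relative to full Monte Carlo transport.
* The emission calibration is tied to one measured configuration
  (220 MeV/u carbon, large angles); other beams need their own yield tables
  and shape defaults.
* Absorption unfolding assumes the exit-thickness map is known exactly (in
  a clinical setting, from the CT); uncertainties in `x` are not propagated.
* The ToF model is a straight-line flight at the post-phantom energy plus
  Gaussian noise; in-phantom slowing of the fragment is folded into the
  energy, not the timing.
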