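---
title: "Models and methods in fiberdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fiberdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberdiff)
```

# The scattering model

## Geometry and conventions

Momentum transfer is the public coordinate everywhere: `Q = 4π sin(θ)/λ`
in Å⁻¹, related to Bragg spacing by `d = 2π/Q`. The reduced reciprocal
coordinate `R = Q/2π` that is natural for the cylinder algebra is internal
only and converted at the model boundary, because every printed quantity in
this field is quoted in `Q` or `d`.

Detector pixels are addressed 0-based at pixel centers; a pixel at
in-plane distance ρ (mm) from the beam center at sample distance `L` maps
to `Q = (4π/λ) sin(½ atan(ρ/L))`. Azimuth is measured in degrees from the
fiber/field axis ("up" on the image), so the equator lies at ±90°. In
matrix coordinates (rows grow downward) our `atan2(Δcol, Δrow_up)` sweep
is the mirror image of a mathematically counterclockwise angle; every
analysis in the package is symmetric under this mirror (and under Friedel
folding to a half-turn), so no result depends on the handedness.

## Hierarchical cylinder-lattice intensity

The fibrils are modelled as infinitely long solid cylinders, justified by
the absence of small-angle meridional reflections and of any detectable
axial periodicity; only the equatorial (`Z = 0`) section is computed, and
axial structure is a declared non-goal. The equatorial intensity of a
two-level arrangement — `n0` cylinders of radius `r` on a circle of radius
`r0`, that bundle repeated `n1` times on a circle of radius `r1` — is the
factorized product

`I(Q) = scale · f²(r, Q) · Φ²(n0, r0, Q) · Φ̃²(n1, r1, Q)`

* `f(Q) = ρ π r² · 2J₁(Qr)/(Qr)`, the solid-cylinder cross-section form
  factor, with its series limit used below `Q·r = 10⁻⁶` to avoid 0/0.
* `Φ²(n, r₀, Q) = n[1 + Σ_{m=1}^{n−1} J₀(2 Q r₀ sin(πm/n))]`, the
  cylindrical average of the lattice sum of `n` equally spaced points on a
  circle; `Φ²(0) = n²` and `Φ² ≡ 1` for `n = 1`. The outer-level factor
  `Φ̃²` uses the same functional form: no separate definition exists for
  it, and we implement the literal printed product.

The factorization is *exact* for a single level (`n1 = 1`) and an
approximation otherwise, because averaging a product is not the product of
averages. Rather than guess an unstated averaging order, the package ships
a brute-force oracle (`oracle_intensity`) that places all `n0·n1` centers
explicitly, evaluates `|Σ_j F(Q) e^{iQ·c_j}|²` on ≥360 azimuthal
directions, and averages. For the three-bundles-of-three arrangement the
factorized curve stays within ~0.02% of the oracle for `Q ≤ 0.02` Å⁻¹ and
the deviation grows smoothly at higher `Q`; the test suite pins both the
single-level equivalence (to 1e-6 relative) and the low-`Q` two-level
agreement.

## Polydispersity

Gaussian polydispersity is attached to the *unit radius only* (the one
place the method statement allows it), as an incoherent ("local
monodisperse") average of `f²` over the radius distribution, computed by
41-point Gauss–Legendre quadrature on `[max(ε, r−4σ), r+4σ]` with
renormalized weights. The integrand is smooth, so a fixed rule is
reproducible and adaptive error control is unnecessary. The constructor
enforces `σ_r < r/3` so the truncated Gaussian stays a sensible radius
distribution. A useful property the tests assert: increasing `σ_r` never
deepens the form-factor minima.

# Model fitting

## R-factor

Observed and calculated profiles are compared through
`R = ∫ |I_obs − I_cal| dQ / ∫ I_obs dQ` over the analysis window
(default `Q ∈ [0.01, 0.25]` Å⁻¹), by trapezoid on the observed grid with
the calculated curve linearly interpolated onto it. As printed, the
deviation integral carries no absolute value and could cancel; standard
R-factor practice with `|·|` is used. Both curves are max-normalized to 1
inside the window before differencing ("after background subtraction and
normalization"); whether the original normalization was by height or area
is unstated, so area-normalization is exposed as an option
(`normalize = "area"`), and the intensity scale is a nuisance parameter
refit on the unnormalized data after the search.

## Search strategy

The lattice occupancies `(n0, n1)` are discrete and enumerate the roughest
axis of the landscape, so each candidate pair gets its own bounded
continuous optimization (`nlminb`) of `(r, σ_r, r0, r1)`: a coarse
parameter grid (monodisperse) is screened first, the best grid points
seed ≥5 jittered local searches, and the winner is polished. The search
phase evaluates `J0`/`J1` through a linear-interpolation table (step
5×10⁻⁴ on `[0, 220]`, absolute error below ~2×10⁻⁸) for speed; the final
parameters and *every reported R-factor* are re-evaluated with exact
`besselJ`. All randomness (start jitter) derives from one integer seed, so
fits are bit-reproducible.

**Identifiability.** Because the two interference factors share one
functional form, the factorized intensity is invariant under exchanging
the two levels, `(n0, r0) ↔ (n1, r1)` — a pure labeling degeneracy. Fit
results are canonicalized so that the structured, smaller-circle lattice
is the inner one: the bundle sits inside the superstructure, which is
also what the overlap geometry requires, and a single-level arrangement
is always reported as `(n0 = n, n1 = 1)`. On
noiseless data generated from inside the model family the fit recovers
every continuous parameter essentially exactly and the true `(n0, n1)`;
with 2% multiplicative noise the unit diameter stays within a few
percent.

## Crystallinity

`p = ∫(I − B) dQ / ∫ I dQ` with the background clipped pointwise to
`[0, I]`, which guarantees `p ∈ [0, 1]` and monotone non-increase as the
background grows. The window defaults to the fit window but is
independent, since nothing ties the two printed windows together. The
published per-sample crystallinity values are *not* reproduction targets:
the underlying beamline data were never deposited, so `p` is demonstrated
on synthetic fixtures only.

# Profile reduction

**Background.** The profile is smoothed by a centered moving average
(default window 5 points), strict local minima of the smoothed curve are
collected as anchors with both endpoints always included (preventing wild
extrapolation), and a polynomial (default degree 4) is least-squares fit
through the anchor points in centered/scaled coordinates before expansion
back to raw ascending coefficients over `Q`. If anchors are scarcer than
coefficients the degree is reduced and recorded. Evaluation against a
profile is clipped to `[0, I(Q)]`.

**Peaks.** The background-subtracted residual is fit with 1–6 Gaussians by
bounded least squares, initial centers at the largest residual maxima,
deterministic jittered restarts on poor convergence. Each peak reports its
center, height, Gaussian σ, integral intensity `h·σ·√(2π)`, integral width
(integral intensity / height) and `d = 2π/center`. Peaks with height below
three times the residual noise floor are flagged `weak` rather than
suppressed. The coherence length is the Scherrer-type reciprocal of the
integral breadth, `L = 2π/ΔQ` — the 2π matches the package's `Q = 2π/d`
convention, as no explicit constant is stated in this field's shorthand.

**Sector integration.** "10° opening" is interpreted as the *full*
opening (±5°) and includes the mirror sector, standard practice for
symmetric fiber patterns. Pixels are binned on a regular `Q` grid at the
median per-pixel `ΔQ`; empty bins are dropped. On isotropic input the
equatorial and meridional sectors agree to well under 1% and conserve
integrated flux, which the tests assert.

**Mutual orientation.** The azimuthal distribution over a radial band is
folded to a half-turn (Friedel symmetry), then fit with one and with two
Gaussians plus a constant floor; the two-population model is accepted only
if an F-test on the residual sums prefers it at α = 0.05, with ties and
numerically perfect single-Gaussian fits breaking toward the simpler
model. The separation is the angular distance between the two centers,
folded into (0, 90°]. How the published tilt angles were actually computed
is not described; this Gaussian-pair procedure is one defensible choice and
is recorded as such. Peaks are assumed to sit away from the 0°/180° fold
boundary, which holds for equatorial arcs (centers near ±90°).

**Merging.** Multi-distance curves are ordered by `Q` coverage and merged
sequentially, each newcomer scaled by the median intensity ratio over the
overlap, coincident points averaged after scaling. Duplicate-`Q` rows
anywhere in the I/O layer are averaged (σ's RMS-combined) because
multi-distance merging naturally produces overlaps.

# Exchange kinetics

The time evolution of the predominant diffraction peak is summarized by
the trapezoidal band integral per time point, and fit with the
three-parameter exponential `I(t) = i∞ + (i0 − i∞) e^{−t/τ}`. The floating
asymptote is the default because the residual (plateau) intensity is a
reported quantity in its own right and a two-parameter decay cannot
express it; `model = "simple"` pins `i∞ = 0` for comparison. Time is
measured from the D₂O→H₂O swap; an optional window (e.g. the conventional
8 h) restricts the fitted range while full 30 h series are accepted. The
incoherent-background rise that accompanies H uptake is handled by
fitting background-subtracted band intensities. An increasing curve is fit
with negative amplitude and flagged, and the residual fraction `i∞/i0` is
soft-clipped to `[0, 1]` with a warning if the optimizer exits bounds.

# Synthetic data: the stated world

The generators emulate the measured conditions, not an idealized
instrument:

* **Equatorial profiles** (`gen_profile`): model intensity plus a smooth
  polynomial background plus multiplicative Gaussian noise (σ ∝ I), the
  high-flux stand-in for counting statistics; 500 points on
  `Q ∈ [0.005, 0.25]` Å⁻¹ matches the small-angle coverage of the
  original reduction.
* **2D patterns** (`gen_pattern`): separable radial × azimuthal intensity,
  each fiber population a Gaussian arc in azimuth folded to 180°, plus an
  isotropic floor and a zeroed beam-stop disc. The default geometry
  (λ = 4.5 Å, L = 4 m, 3 mm pixels, 129×129 grid) puts the main
  interference peak comfortably inside the detector. A Gaussian arc is not
  a full orientation-distribution function, but it is sufficient for
  tilt-angle analysis.
* **Powder profiles** (`gen_powder`): Gaussian rings at `Q = 2π/d` on a
  smooth background; the cross-β fixture uses d = 10 and 4.7 Å with widths
  inverted from 30–40 Å coherence lengths.
* **Decay curves** (`gen_decay`): exact exponential plus multiplicative
  noise, floored at zero; 32 points over 8 h at 2% noise is the reference
  noisy condition.

The four named scenarios (`sample_scenarios()`) freeze the published
sample parameters: WT — four 106 Å units on a 160 Å circle, ±15.5° double
orientation, τ = 2.58 h; A2V — three 36 Å units in a 132 Å bundle, three
bundles on a 196 Å circle, single tight orientation, τ = 1.90 h; WT:A2V —
equal-weight superposition of both arrangements, ±13.5° tilt pair,
τ = 2.45 h; WT:1-6A2V — no resolvable model, a weak featureless central
blob. Where the sources state no number (noise level, background shape,
intensity scale, azimuthal σ = 6° for the tilt pairs, amplitude 100 over a
unit floor), the values above were chosen once as realistic for this kind
of measurement and are recorded in every truth attribute; they are not
tuned against test outcomes.

**What a green test establishes — and what it does not.** Synthetic
profiles are drawn from inside the model family, so noiseless recovery
demonstrates the correctness of the estimator chain (model evaluation,
R-factor, optimizer, selection), not the adequacy of the cylinder-lattice
model for real fibers. Real data add a diffuse solvent/oligomer
background, resolution smearing, orientation disorder coupling radial and
azimuthal structure, and possible inter-fibril interference — none of
which the generators emulate. The published sample-specific observables
(peak positions, crystallinity values) are therefore explicitly out of
reach and are not asserted anywhere.

# Numerical choices and degenerate inputs

* Bessel evaluations: base `besselJ`; optimizer hot loops use the
  interpolation table described above, never for reported values.
* Gauss–Legendre nodes from the Golub–Welsch eigen decomposition, cached.
* `Q = 0` limits are series-expanded; `Φ²` at `radius = 0` degenerates to
  `n²`, the coherent limit.
* Backgrounds on constant profiles reduce the polynomial degree (no strict
  minima ⇒ endpoint anchors only) and return the constant exactly.
* Flat decay curves raise a degenerate-input error rather than a
  divide-by-zero τ.
* All generator and fit randomness flows through explicit integer seeds,
  with the caller's RNG state restored.

# Known limitations

* The two-level factorized intensity is not the exact cylindrical average
  for `n1 > 1`; the oracle quantifies, but the fit does not correct, this.
* Orientation analysis assumes Friedel symmetry and well-separated arcs;
  heavily overlapping populations (< ~8° separation at σ = 6°) will
  collapse to a single-Gaussian verdict.
* No 2D model refinement: fitting is 1D-equatorial, as in the original
  analysis.
* No detector corrections (flat-field, dark, mask) and no proprietary
  beamline formats; text matrices plus a geometry header keep fixtures
  diffable.
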