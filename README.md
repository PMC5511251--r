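# fiberdiff

Mesoscale analysis of fiber diffraction from oriented amyloid assemblies.

Amyloid-forming peptides dried under a magnetic field deposit as partially
aligned fibers. Their small-angle equatorial scattering encodes how
protofilament-scale units pack laterally — how wide the units are, how many
sit on a circle, and whether those bundles organize into a superstructure —
while wide-angle powder rings near d ≈ 10 Å and d ≈ 4.7 Å report the
cross-β intersheet and hydrogen-bonding repeats. This package provides, for
workers analysing such patterns, the complete reduction-and-modelling chain:

* **Hierarchical cylinder-lattice model.** The equatorial intensity of `n0`
  solid cylinders (radius `r`, optional Gaussian polydispersity) on a
  circle of radius `r0`, repeated `n1` times on an outer circle `r1`:

  `I(Q) = scale · f²(r, Q) · Φ²(n0, r0, Q) · Φ̃²(n1, r1, Q)`

  with the solid-cylinder form factor `f(Q) = ρ π r² · 2J₁(Qr)/(Qr)` and
  the cylindrically averaged circular-lattice interference function
  `Φ²(Q) = n[1 + Σ_{m=1}^{n−1} J₀(2Q r₀ sin(πm/n))]`. A brute-force
  azimuthal-quadrature oracle (`oracle_intensity`) checks the closed form
  and quantifies the factorization error for two-level models.
* **R-factor model fitting** (`fit_model`): discrete search over `(n0, n1)`
  candidates with seeded multistart bounded optimization of the continuous
  parameters, minimizing `R = ∫|I_obs − I_cal| dQ / ∫ I_obs dQ` on
  max-normalized, background-subtracted profiles.
* **Profile reduction**: polynomial background through intensity minima
  (`estimate_background`), multi-Gaussian peak fitting with integral widths
  and Scherrer-type coherence lengths `L = 2π/Δ Q` (`fit_gaussian_peaks`,
  `coherence_length`), crystallinity `p = ∫(I−B)dQ / ∫I dQ`
  (`crystallinity`), multi-distance curve merging (`merge_profiles`).
* **2D pattern reduction**: pixel → (Q, azimuth) mapping, 10°-opening
  sector integration (`sector_integrate`), azimuthal distributions and
  mutual-orientation extraction of coexisting fiber populations
  (`azimuthal_profile`, `mutual_orientation`).
* **H-D exchange kinetics**: band-integrated peak intensity versus time and
  three-parameter exponential fits `I(t) = i∞ + (i0 − i∞)e^{−t/τ}`
  (`peak_band_timeseries`, `fit_decay`).
* **Synthetic data with ground truth** (`gen_profile`, `gen_pattern`,
  `gen_powder`, `gen_decay`, `sample_scenarios`): seed-deterministic
  generators emulating the four measured sample types (WT, A2V, their 1:1
  mixture, and the WT + N-terminal hexapeptide mixture).

## Worked example

Recover the wild-type arrangement from a synthetic equatorial profile:

```r
library(fiberdiff)

truth <- sample_scenarios()$WT$model      # 4 units, 2r = 106 A, circle 160 A
obs <- gen_profile(truth, seq(0.005, 0.25, length.out = 500))
fit <- fit_model(obs, search_space(n0 = 1:6, n1 = 1:3), seed = 1)
fit
#> <fit_result> R = 2.663e-14 | n0 = 4, n1 = 1, 2r = 106 A, r0 = 80 A, r1 = 0 A
#> top candidates:
#>  n0 n1         r      sigma_r       r0 r1     r_factor convergence
#>   4  1  53.00000 2.737901e-08 80.00000  0 2.663303e-14           1
#>   3  1  61.76457 1.220101e-05 77.85566  0 1.569809e-01           1
#>   2  1 100.00000 5.659945e-05 63.47766  0 2.108852e-01           0
```

The fit selects four units (`n0 = 4`) and returns the unit diameter
`2r = 106` Å and circle size `2r0 = 160` Å with an R-factor at numerical
noise — on noiseless data from inside the model family, the generator
parameters are recovered exactly.

Orientation analysis of a two-population pattern tilted ±15.5°:

```r
sc <- sample_scenarios()$WT
geom <- detector_geometry(4.5, 4000, 3, c(64, 64))
pat <- gen_pattern(sc$model, sc$populations, geom)
mutual_orientation(azimuthal_profile(pat, c(0.035, 0.055)))
#> <orientation_result> double population: centers 74.48 / 105.52 deg, separation 31.05 deg
```

The 31° separation is the mutual orientation of the two coexisting fiber
populations.

## Command line

A thin CLI wraps the same functions (installed at `exec/fiberdiff`):

```sh
Rscript -e 'fiberdiff::fiberdiff_cli()' convert --q 1.312
# d_A  4.78897
```

Subcommands: `simulate-profile`, `simulate-pattern`, `simulate-decay`,
`process-pattern`, `fit-model`, `crystallinity`, `fit-decay`,
`powder-peaks`, `convert`.

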