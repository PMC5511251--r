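Package: fiberdiff
Title: Mesoscale Fiber Diffraction Analysis of Amyloid Assemblies
Version: 0.1.0
Authors@R:
    person("Dana", "Keller", email = "dana.keller@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fiber diffraction data from magnetically
    oriented amyloid assemblies at the mesoscale. Implements a hierarchical
    cylinder-lattice equatorial scattering model (solid-cylinder form factor
    with Gaussian radius polydispersity and cylindrically averaged circular
    lattice interference functions), R-factor model fitting with discrete
    lattice-occupancy selection, polynomial background estimation through
    intensity minima, multi-Gaussian peak fitting with integral widths and
    coherence lengths, crystallinity quantification, sector and azimuthal
    integration of 2D detector patterns with mutual-orientation analysis,
    multi-distance curve merging, and hydrogen-deuterium exchange decay
    kinetics. Includes seed-deterministic synthetic data generators with
    machine-readable ground truth for validation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
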