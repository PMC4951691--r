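Package: moltenscope
Title: Multi-Probe Classification of Protein Conformational States in Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates the solution-biophysics evidence chain used to decide
    whether a protein behaves as a native globule, a molten globule, a
    pre-molten globule or an extended coil. Implements sequence
    charge-hydropathy (Uversky-plot) profiling and residue-class composition;
    size-exclusion chromatography partition-coefficient calibration with
    hydrodynamic-radius and apparent-mass estimation; sucrose-gradient
    sedimentation interpolation and the Siegel-Monte mass relation;
    empirical per-state Rh-versus-mass scaling laws and the Rg/Rh Q-factor;
    SAXS Guinier fitting in a fixed qRg window and dimensionless Kratky
    shape classification; Stern-Volmer quenching, unfolded-fraction and
    two-state-versus-linear unfolding cooperativity fits; and an
    evidence-integrating conformational-state classifier. A synthetic-data
    module generates analytic sphere, Gaussian-coil and hybrid scattering
    curves, SEC and gradient runs, quenching and unfolding titrations, and
    composition-controlled sequences so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Collate:
    'settings.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sequence.R'
    'hydrodynamics.R'
    'saxs.R'
    'spectroscopy.R'
    'classifier.R'
    'synthetic.R'
    'io.R'
    'moltenscope-package.R'
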