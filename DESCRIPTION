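Package: xpsdamage
Title: In Situ XPS Monitoring of Radiation Damage to DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for time-resolved X-ray photoelectron
    spectroscopy (XPS) of DNA under irradiation: Shirley background
    estimation, constrained Voigt deconvolution of the C1s/O1s/N1s/P2p
    core-level regions with covariance-based peak-area uncertainties,
    P2p-normalized damage time series with strand-break, base-damage and
    hydration indices, a layered-slab Monte Carlo photon/electron
    transport model separating direct from indirect damage contributions,
    and a synthetic-spectrum generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'voigt.R'
    'shirley.R'
    'spectra-io.R'
    'region-models.R'
    'fit.R'
    'metrics.R'
    'materials.R'
    'transport.R'
    'synthetic.R'
    'pipeline.R'
    'zzz.R'
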