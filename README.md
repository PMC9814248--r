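# xpsdamage

In-situ X-ray photoelectron spectroscopy (XPS) makes it possible to
irradiate a DNA film and watch the chemical damage accumulate in the same
measurement: the Al K&alpha; photons (1486.6 eV) that eject the
photoelectrons being analysed are also the radiation source. Under
near-ambient-pressure conditions the film can be held under vacuum, N2 or
water vapour, which separates *direct* damage (photons and secondary
low-energy electrons acting on the DNA itself) from *indirect* damage
(hydroxyl radicals and other water-radiolysis products). `xpsdamage` is an
R package for analysing such experiments end to end, for spectroscopists
and radiation biophysicists:

- **Spectral deconvolution** — Shirley inelastic background (classic fixed
  point, B(E) proportional to the integrated peak intensity at lower
  binding energy) plus constrained **Voigt** components fitted by
  bound-constrained Levenberg–Marquardt. The Voigt profile is the true
  convolution, evaluated through the Faddeeva function
  w(z) = exp(−z²) erfc(−iz). The P2p spin-orbit doublet is fitted as a
  linked pair (2:1 area ratio, 1.0 eV splitting). Area uncertainties come
  from the residual-variance-scaled inverse Gauss–Newton normal matrix.
- **Damage metrics** — every area is normalized on the total P2p signal at
  the same timepoint (one phosphorus per nucleotide) and expressed as a
  percentage of the region total at the start of irradiation. Scalar
  indices: the **strand-break index** (fractional decrease of the C1s
  286 eV C–O/C–N component, the backbone C–O–P marker), the **base-damage
  index** (fractional decrease of the total non-gas N1s signal; nitrogen
  sits exclusively in the bases) and **water molecules per nucleotide**
  (sensitivity-corrected O1s-water : P2p ratio).
- **Photon/electron transport** — a layered-slab Monte Carlo
  (gas column, adsorbed layer, DNA film) with photoelectric absorption,
  dipole photoemission, and straight-track CSDA electron transport down to
  a 20 eV cut, tallying energy deposit, photoionization and electron
  thermalization in the top 10 nm of the film — the depth XPS probes.
  Closed-form Beer–Lambert and charged-particle-equilibrium estimators are
  built in as cross-checks.
- **Synthetic data** — a generator producing spectrum time series with
  known ground truth (first-order damage kinetics, Shirley-consistent
  backgrounds, Poisson counting noise), so the whole pipeline is testable
  without access to instrument data.

## Worked example

Generate the water-atmosphere scenario, deconvolute the C1s/N1s/P2p
regions at every timepoint, and compute the damage report:

```r
library(xpsdamage)

sc  <- presetScenarios()$H2O
gen <- generateSeries(sc, seed = 42)

fits <- list()
for (r in c("C1s", "N1s", "P2p"))
  fits <- c(fits, fitRegionSeries(gen$series,
                                  fixModelWidths(sc@regionModels[[r]])))

series <- normalizeSeries(fits)
damageReport(series, condition = list(gas = "H2O"))
#> DamageReport
#>   strand-break index: 0.2591 +/- 0.0102
#>   base-damage index:  0.2024 +/- 0.0070

fits[[1]]
#> FitResult C1s (t = 0 s): converged, red. chi^2 = 0.921
#>   C1s_285    area         2753 +/- 20.1
#>   C1s_286    area         4513 +/- 24.7
#>   C1s_288    area         2314 +/- 39.1
#>   C1s_289    area         1620 +/- 46.4
```

The strand-break index of 0.26 says the P2p-normalized backbone C–O
component lost 26 % of its initial intensity over the two-hour exposure;
the base-damage index of 0.20 is the matching loss of total nitrogen.
Under the N2 scenario the same analysis gives roughly half the
strand-break index and a third of the base damage — the programmed
hydration contrast.

The transport side:

```r
simulatePhotons(defaultGeometry("vacuum"), 1e6, seed = 42)
#> TransportResult: 1e+06 histories at 1486.6 eV
#>   mean deposit in scoring layer: 1.842 +/- 0.038 eV/photon
#>   ionization fraction:           0.001642 +/- 4e-05
#>   thermalized electrons:         0.000926 +/- 3e-05 per photon
```

Each incident photon deposits ~1.8 eV in the probed 10 nm of the film,
fewer than 0.2 % of photons ionize a DNA atom there, and a comparable
number of electrons thermalize in the same region — so direct energy
input barely changes with the atmosphere, and observed damage differences
must come from chemistry, not dosimetry.

A full pipeline run (synthesis, fitting, damage report, transport
comparison, manifest) is one call: `runPipeline(list(scenario = "H2O",
seed = 1, out_dir = "run"))`, or from a shell via
`inst/scripts/run_pipeline.R`.

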