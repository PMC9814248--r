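---
title: "Models and methods behind xpsdamage"
author: "xpsdamage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xpsdamage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xpsdamage)
```

# The measurement and the analysis problem

In-situ XPS of a DNA film uses one beam twice: the Al K&alpha; photons
(1486.6 eV) both irradiate the sample and eject the photoelectrons whose
binding-energy spectrum reports the film's chemistry. Repeating the
C1s/O1s/N1s/P2p scans over an exposure of hours turns peak areas into
damage kinetics. Near-ambient-pressure operation adds an atmosphere — N2
or water vapour at a few mbar — so that the same film can be measured dry
(direct damage only: photons and secondary low-energy electrons) or
hydrated (adding the indirect channel: hydroxyl radicals and other
water-radiolysis products).

`xpsdamage` implements the full analysis: spectral deconvolution with
uncertainties, P2p-normalized damage time series and scalar indices, a
transport model that checks that the *direct* energy input is atmosphere
independent, and a ground-truth synthetic generator that makes every stage
testable.

# Spectral deconvolution

## Line shape

Each component is a true Voigt profile — the convolution of a Gaussian of
FWHM $g$ (instrumental broadening) and a Lorentzian of FWHM $l$ (core-hole
lifetime) — evaluated through the Faddeeva function,
$V(x) \propto \mathrm{Re}\,w(z)$ with
$z = (x - x_0 + i\,l/2) / (\sigma\sqrt 2)$. We evaluate $w$ with
Weideman's rational approximation (32 terms, coefficients computed once by
FFT at load time; relative accuracy about $10^{-13}$ over the region a fit
visits, no overflow at large $|z|$). The pure-Gaussian and pure-Lorentzian
limits use the closed forms; requesting both widths zero is an error. A
pseudo-Voigt (Thompson–Cox–Hastings mixture) is available as
`shape = "pseudo"` for comparisons, but the true Voigt is the default and
the literal reading of "Voigt fits". Analytic derivatives
($w'(z) = -2 z w(z) + 2i/\sqrt\pi$) feed the optimizer Jacobian and the
covariance; they are tested against numerical differentiation.

## Background

The Shirley background is the classic fixed point: with endpoint
intensities $I_{lo}, I_{hi}$ (means over the outermost `nEdge = 5` points
per side), iterate
$B(E) = I_{lo} + (I_{hi}-I_{lo})\,A_{<E}/A_{tot}$, where the areas are
trapezoid integrals of the net signal (counts minus current background).
Iteration stops at a maximum relative change below `tol = 1e-6` or after
`maxIter = 100` passes (the result records which). Negative net signal is
clipped to zero inside the area integrals and flagged.

Two refinements matter in practice and are on by default in `fitRegion()`:

* **Endpoint refresh** (`reiterateBackground = 1`). The raw edge means are
  biased upward by the Lorentzian tails of the peaks. After a first fit
  pass, the endpoints are re-derived from the de-peaked spectrum and the
  background recomputed once; it stays frozen within each optimization.
  Without this the tails bias recovered areas at the percent level.
* **Background offsets** (`fitBackgroundOffsets = TRUE`). Two free linear
  parameters adjust the background's endpoint intensities along the
  (frozen) Shirley step shape. They absorb the residual endpoint error in
  a single optimization and, importantly, carry the background's share of
  the uncertainty into the covariance, so area sigmas are not conditioned
  on a perfectly known background.

With both refinements a noiseless synthetic four-component C1s region is
recovered to better than 0.1 % in every area and 0.01 eV in every center
(asserted in the test suite); with neither, the same fixture shows
percent-level area bias. This is the package's own design choice; plain
once-from-raw-data Shirley is available by turning both options off.

## Optimization and constraints

`fitRegion()` minimizes weighted residuals
$(y - B - \sum_k V_k)\sqrt{w}$ by bound-constrained Levenberg–Marquardt
(`minpack.lm::nls.lm`) with the analytic Jacobian. Default weights are
Poisson, $w = 1/\max(y, 1)$ — correct for counting detectors; `"none"` is
available for externally noise-normalized data. Free parameters per
component: area ($\ge 0$), center (within its assignment bounds: ±0.5 eV
around single-valued literature positions, ±0.75 eV around range
midpoints), Gaussian FWHM in [0.6, 2.5] eV and Lorentzian FWHM in
[0, 0.6] eV — bounds chosen to keep component assignments stable across a
time series, not fitted values from any instrument. Constraints remove
parameters rather than penalize them: a doublet link (P2p: 2:1 area
ratio, 1.0 eV splitting, widths tied — the physics of spin-orbit
splitting) eliminates the secondary line's parameters, and an optional
shared Gaussian width collapses the instrumental widths of a region.

Starting values come from the model (warm-started from the previous
timepoint in `fitRegionSeries()`, which stabilizes component identity
along the time axis); starting areas are rescaled so their sum matches the
background-subtracted net area. Optimizer tolerances: `ftol = 1e-10`,
`ptol = 1e-6`, `maxIter = 200`. The relative-step tolerance is
deliberately the loose one: overlapping components leave nearly flat
likelihood valleys along which parameters are statistically
undetermined — walking them to $10^{-12}$ costs hundreds of iterations and
changes nothing that the data can resolve. Non-convergence is flagged,
never silent, and any parameter ending on a bound is recorded in the
result's messages.

## Uncertainties

The covariance is the residual-variance estimate (reduced chi-square)
times the inverse Gauss–Newton normal matrix $(J^\top J)^{-1}$ at the
optimum, with the Jacobian columns equilibrated before inversion so that
rank detection reflects genuine degeneracy rather than parameter units.
A rank-deficient normal matrix falls back to the pseudo-inverse with a
message naming the implicated parameters. Parameters sitting on a bound
cannot vary into the forbidden side; they are treated as fixed in the
covariance (zero rows/columns). Area sigmas are propagated through the
area parameterization, including doublet-linked areas.

Two calibration facts shape the recommended workflow. First, with all
widths free, four overlapping Voigts admit alternative width
configurations (one Lorentzian width at zero, a neighbour at the upper
bound) between which the estimator jumps from replicate to replicate; no
Gaussian covariance describes that mixture at both the 1-sigma and
3-sigma level. Second, with widths *fixed*, the estimator is cleanly
calibrated: across Poisson replicates the empirical scatter matches the
reported sigmas, 68 % intervals cover at their nominal rate, and a
parametric bootstrap agrees with the covariance sigmas (all asserted in
the acceptance tests, at 200–500 replicates). The package therefore
encodes the standard time-series protocol in `fixModelWidths()`: calibrate
widths once on a high-statistics (or first) scan with free widths, then
hold them fixed while areas and centers track the kinetics.

# Damage metrics

Phosphorus occurs exactly once per nucleotide and its P2p signal is not a
damage target, so the total P2p area at the same timepoint is the internal
reference: `normalizeSeries()` divides every component area by it, then
expresses each series as a percentage of the region's non-gas total at the
first timepoint (which therefore sums to 100 there). Gas-phase lines (the
N1s 405–406 eV N2 line, the O1s 534–536 eV water line) report the
atmosphere, not the DNA; they are fitted but excluded from totals and
indices. Error propagation assumes independence between regions (they are
separate scans); the P2p variance enters every ratio, cross-region
covariances do not.

The scalar indices are endpoint based — the fractional decrease between
the first and last timepoint — because the experiment is summarized as the
evolution between exposure start and end, and endpoints are the least
model-dependent summary. A `method = "trend"` variant (endpoints of a
straight-line fit through all timepoints) is provided for series noisy
enough that single-timepoint endpoints are fragile; no claim is made that
it matches the published protocol.

* **Strand-break index**: decrease of the C1s 286 eV component, which
  carries the backbone C–O–P bond whose cleavage is the strand-break
  signature.
* **Base-damage index**: decrease of the summed non-gas N1s signal;
  nitrogen sits exclusively in the nucleobases, so total-N loss tracks
  base damage and base release (N-glycosidic bond cleavage).
* **Water per nucleotide**: the sensitivity-corrected atomic ratio
  $(A_{water}/S_{O1s}) / (A_{P2p}/S_{P2p})$, with one phosphorus per
  nucleotide as the conversion assumption. The shipped sensitivity
  factors are Scofield-type relative photoionization cross sections at
  Al K&alpha; (C1s = 1.00, N1s = 1.80, O1s = 2.93, P2p = 1.19, see the
  provenance header of `inst/extdata/rsf_alka.tsv`); instrument
  transmission corrections, which are spectrometer specific, are the
  user's to fold into a replacement table.

# Transport model

The geometry is a stack of slabs: an optional gas column (1 mm default —
the order of the aperture–sample distance in near-ambient-pressure
instruments; ideal-gas density at the set pressure and 300 K), an optional
adsorbed-water layer (0.3 nm, H2O condition), and the DNA film (200 nm,
average-nucleotide stoichiometry C9.75 H12.25 N3.75 O7.25 P at
1.35 g/cm³). All layer parameters are package defaults, not measured film
properties. Tallies are restricted to the film's top `scoringDepth`
(10 nm), the depth XPS effectively probes.

Photon physics at 1.4 keV is photoelectric absorption only — it dominates
the inelastic cross section at this energy; coherent scattering and
fluorescence are deliberately omitted. Free paths follow layer-wise
Beer–Lambert attenuation at normal incidence, with elemental photoelectric
cross sections from a shipped plain-text table (mixture rule, log-log
interpolation; see the table's provenance header — anchor values are
approximate transcriptions of standard compilations, accurate at the
few-percent level, far inside the tolerances of every quantity computed
from them).

At an absorption in a condensed layer, a mean core-level binding energy
(400 eV, the cross-section-weighted mean core-edge energy of the DNA
constituents) is deposited locally — the Auger relaxation cascade is
short-ranged on the scale of the scoring layer — and the photoelectron
carries the remainder, emitted with the unpolarized dipole pattern about
the beam axis ($\propto \sin^2\theta$, the $\beta = 2$ distribution of the
dominant s subshells). The electron then follows a straight track in the
continuous-slowing-down approximation, using a density-scaled mass
stopping power (liquid-water proxy for all condensed layers) until the
20 eV cut, where it thermalizes and deposits the residual. The range–
energy relation is built once from the stopping table with analytic
segment integrals and is exactly invertible, so per-history energy
bookkeeping telescopes: deposits across all regions plus escaping energy
equal the photon energy to rounding, and the test suite asserts it.

Both localization choices are switchable (`photoelectronMode = "full"`
gives the photoelectron the whole photon energy;
`angular = "isotropic"` drops the dipole pattern). They are not free
dials: giving the full energy to an isotropically emitted straight-track
electron overstates energy transport out of the surface layer, and in that
configuration the Monte Carlo falls about 40 % below the
charged-particle-equilibrium closed form
$T_{gas} \cdot \mu_{film}\, t\, E$ — outside the 30 % consistency band the
estimator is meant to satisfy for a thick film. With the physically
preferable defaults the two agree within that band.

Electrons born in gas layers are *not* propagated into the film: at mbar
pressures elastic scattering randomizes low-energy-electron trajectories
over millimetre paths, so straight-track delivery would be unphysical.
Their energy is tallied to the gas layer. This matches the Beer–Lambert
reasoning under which a mbar gas column can only attenuate the beam (by
about $10^{-3}$ over 1 mm at 10 mbar), which is what makes the film
tallies atmosphere independent.

`compareAtmospheres()` runs the conditions with common random numbers,
sampling the gas column and the condensed stack from separate uniform
streams so that film histories are identical across conditions except the
few absorbed in the gas. (A single combined optical-depth stream would
shift every absorption depth by the gas optical depth — several nm, i.e.
comparable to the scoring depth — and decorrelate the pairing, burying the
contrast in noise.)

# Synthetic data

The generator encodes the statistical structure the analysis assumes,
with every parameter recorded in a `TruthRecord`:

* areas follow first-order kinetics $A(t) = A_0 e^{-kt}$ (negative rates
  grow) — chosen because the observed time courses are smooth monotone
  trends; this is an assumption of the generator, not an inference;
* the noiseless curve is the Voigt sum on a Shirley-consistent step
  background whose high-binding-energy offset is proportional to the
  *current* total peak area, so damage lowers the background too and the
  Shirley stage is exercised nontrivially;
* counts are Poisson, with one global scale per scenario chosen so the
  largest generated peak reaches the target peak signal-to-noise ratio
  (default 100, i.e. $10^4$ peak counts);
* defaults: 10 timepoints over 2 h, 0.05 eV grid step, Gaussian FWHM
  1.3 eV and Lorentzian FWHM 0.2 eV for all lines — typical laboratory
  Al K&alpha; values, not instrument-fitted ones.

`presetScenarios()` encodes the qualitative experimental findings as
exact generator truth: the H2O backbone (C1s 286 eV) decay rate is twice
the N2 rate, the H2O total-nitrogen decay three times the N2 rate, and
vacuum sits slightly below N2. Rate magnitudes
(N2: $k_{C286} = 2\times10^{-5}\,/s$, $k_{N} = 1\times10^{-5}\,/s$ over
7200 s) were chosen once so that $k\,t_{end}$ is small: endpoint indices
$1 - e^{-k t_{end}}$ then track the rate ratios (true index ratios 1.87
and 2.80 under first-order kinetics, inside the recovery bands centred on
2 and 3). The vacuum preset also carries an adsorbed-water O1s component
equivalent to 0.25 water molecules per nucleotide through the default
sensitivity factors, so the hydration index has a known truth.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: shake-up satellites, charging drift and
instrument transmission roll-off; non-exponential kinetics and
radiation-induced new species appearing at new binding energies;
correlated (non-Poisson) detector noise; sample heterogeneity.

# Validation studies and problem sizes

The acceptance tests run, as the package's own choice of problem size:
$10^6$ photon histories per transport condition (standard errors near
0.04 eV on the deposit); 200 Poisson replicates at SNR 100 for
3-sigma area recovery; 200 bootstrap resamples plus 500 replicates for
uncertainty calibration; 50 replicates per condition for the end-to-end
contrast recovery (fitting C1s, N1s, P2p at all 10 timepoints each).
All seeds are fixed in the tests; generation and transport are bitwise
reproducible given a seed.

# Known limitations

* The elemental cross-section and stopping-power tables are approximate
  anchor-point transcriptions (few-percent level); quantities that divide
  them out (normalized series, index ratios) are unaffected, absolute
  transport tallies inherit the few-percent scale uncertainty.
* The transport model has no angular photon scattering, no fluorescence,
  no electron elastic scattering (straight tracks) and no track-structure
  chemistry; it answers layer-scale energy-bookkeeping questions only.
* The one-phosphorus-per-nucleotide conversion ignores phosphate
  contamination and backbone fragmentation products that retain P.
* The quadrature identity "area over a ±40 FWHM window equals the peak
  area to $10^{-6}$" cannot hold for any line with a Lorentzian
  component — the tail mass beyond that window is
  $\approx 2\gamma/(40\pi\,\mathrm{fw}) \sim 10^{-3}$; the tests therefore
  assert exact area normalization on the infinite domain and the windowed
  value against the analytic tail bound.
* VAMAS support is a deliberately minimal ISO 14976 subset (single-block,
  NORM/REGULAR, XPS, binding-energy abscissa in eV); everything else is
  rejected with a clear message.
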