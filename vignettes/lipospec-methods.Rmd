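---
title: "Methods: band decomposition and binding stoichiometry in lipospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band decomposition and binding stoichiometry in lipospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipospec)
```

## Scope

`lipospec` analyses protein adsorption onto lipid vesicles from two kinds of
spectroscopy data: ATR-FTIR absorbance spectra (protein secondary structure
from the Amide I band; lipid headgroup, carbonyl, and acyl-chain bands) and
fluorescence measurements (anisotropy of a membrane probe, calcein leakage,
dye quantification). A geometry module converts protein-binding values
(P~B~, grams of protein per mole of lipid) into molecules-per-vesicle
stoichiometries. Because instrument data of this kind are rarely deposited,
the package ships a synthetic-data generator that produces
ground-truth-labelled inputs with the statistical structure the analyses
assume; every pipeline stage is validated against it.

## The band model

All spectral decompositions use pseudo-Voigt components

$$ b(\nu) = a\left[(1-\eta)\, e^{-4\ln 2\,\left(\frac{\nu-c}{w}\right)^2}
   + \eta\, \frac{1}{1 + 4\left(\frac{\nu-c}{w}\right)^2}\right] $$

with center $c$ (cm^-1^), FWHM $w$ (cm^-1^), peak amplitude $a$ (a.u.) and
Lorentzian fraction $\eta \in [0,1]$, plus a linear residual baseline.
Component areas use the closed forms $a w \sqrt{\pi/\ln 16}$ (Gaussian part)
and $a w \pi/2$ (Lorentzian part). Fits are bounded Levenberg–Marquardt
least squares (`minpack.lm`), relative cost-change tolerance $10^{-10}$,
at most 500 iterations. Bands start as pure Gaussians; under
`shape_policy = "gauss_lorentz"` the Lorentzian fractions are released only
if the Gaussian-only fit leaves residuals above 1.5 times the estimated
noise level — Lorentzian character is admitted only when unavoidable.

Noise is estimated from the residual of a light Savitzky–Golay smooth
(window 9, order 3), corrected for the variance the filter absorbs. The
same 1.5-sigma threshold drives a retry that adds one component at the
point where the data most exceeds the model (warm-started so the retry
cannot regress), capped at 8 components per region.

## Preprocessing

`preprocess()` slices a region, subtracts a straight line through edge
anchors — each anchor is the mean absorbance over a 5 cm^-1^ margin,
which makes the correction robust to noise — and optionally applies
Savitzky–Golay smoothing (default window 9 points, order 3, suited to
1 cm^-1^ grids). `second_derivative()` is a Savitzky–Golay second
derivative; overlapped bands appear as distinct negative lobes even when
the absorbance shows a single envelope. `pick_peaks()` keeps local minima
whose depth is at least a set fraction (default 5%) of the deepest
minimum.

## Amide I secondary structure

Protein conformation is quantified from the Amide I band (C=O stretching
of the peptide backbone, 1600–1700 cm^-1^). Sub-bands are assigned to
elements by center position, using expanded helix/coil ranges appropriate
for albumin:

| element | range (cm^-1^) |
|---|---|
| β-sheet | 1628–1639 |
| random coil | 1640–1649 |
| α-helix | 1650–1660 |
| β-turn | 1664–1687 |
| aggregates (intermolecular β-sheet) | 1618–1626, 1688–1696 |

Ranges are half-open $[low, high)$; a center falling in a gap goes to the
nearest range, with ties resolved toward the lower-wavenumber range.
Percentages are area shares normalized over the non-aggregate total, so
the four conformational elements always sum to 100; the aggregate share is
reported separately against the full area. The fit window (default
1618–1696 cm^-1^) deliberately includes the flanking aggregation bands.

### Why the pipeline constrains band positions

This is the package's central numerical design decision. Amide I sub-bands
of albumin sit roughly 10 cm^-1^ apart with FWHM near 20 cm^-1^. At that
overlap the decomposition is not a well-posed free fit:

* the *true, noiseless* second derivative of a three-band
  helix/sheet/coil sum has only **two** minima — the middle (coil) band
  never produces one at any realistic bandwidth; and
* a two-Gaussian-plus-line model reproduces the noiseless three-band sum
  to a residual an order of magnitude *below* a 1% noise floor, so the
  data alone cannot fix the number or the positions of the components.
  A fully free fit has an alpha-helix standard deviation of ~10–18
  percentage points across noise realizations — useless.

The classical resolution in infrared protein work is to impose the band
positions and fit the intensities, and that is what `amide_i_analysis()`
does: one component per structural element, seeded at the midpoint of its
assignment range, centers held fixed with a single shared bandwidth
(a near-linear, well-conditioned problem), followed by a final polish in
which centers may move at most 0.5 cm^-1^. Under the validation
conditions (SNR 100, FWHM 20) this recovers element percentages to within
about one percentage point with a seed-to-seed spread of ~0.5 points;
wider release bounds trade a small bias reduction for a many-fold variance
increase, and ±0.5 is the measured optimum of that trade.

The second derivative still earns its place: it confirms which features
are present and, in a dedicated scan (narrower window of 7 points, 3%
relative depth, restricted to the aggregate ranges), detects the weak
aggregation shoulders near 1624 and 1692 cm^-1^, which join the model as
extra components only when actually observed. The derivative stage runs on
a window padded by 12 cm^-1^ beyond the fit window (clipped to the data),
because one-sided Savitzky–Golay edge fits cannot show a minimum for a
band sitting within half a filter window of the edge. False positives in
the aggregate scan are benign: a spurious fixed-center component in a
signal-free range fits an amplitude at the noise level and perturbs the
percentages by well under a point.

`fit_bands()` keeps the conventional free-center (±5 cm^-1^) per-component
interface for regions where components are resolvable — its constrained
modes (`fix_centers`, `width = "shared"`) are what the Amide I pipeline
uses.

## Lipid band analyses

`band_position()` estimates sub-grid band positions by a single-Gaussian
plus-line fit over the supplied window, which should span roughly 2–3
times the band FWHM: much narrower windows make the position estimate
unstable (we measured a ~10-fold inflation of the shift standard error
when the window is narrower than the band). If the residual is clearly
structured — above 1.5 times the noise estimate — a second, freely placed
component is tried and kept only when it reduces the residual RMS at
least five-fold; this protects the position of a dominant band against a
partially overlapping neighbor. `band_shift()` is the difference of two
such positions; positive shifts point to higher wavenumber, the
dehydration direction for the phosphate band.

`carbonyl_hydration()` classifies fitted ester-carbonyl components at
1700–1760 cm^-1^ by center: below 1735 cm^-1^ are hydrogen-bonded
(the doubly H-bonded shoulder near 1714 and hydrated *sn-2* carbonyls near
1727–1731), at or above it free (~1738, ~1742), and reports the H-bonded
area share. The 1714 shoulder counts toward the hydrogen-bonded numerator
since it represents carbonyls in two hydrogen bonds.

## Fluorescence

Anisotropy is $r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$ with
$G = I_{HV}/I_{HH}$; values outside the one-photon physical range
$[0, 0.4]$ trigger an advisory warning, not an error. Calcein release is

$$ CR = \left(\frac{I_t}{I_{max,t}} - \frac{I_0}{I_{max,0}}\right)
   \frac{I_{max,t}}{I_{max,t} - I_0} \times 100\% $$

computed from intensities before and after detergent lysis. Noisy inputs
can push CR slightly below 0 or above 100; values are returned unclipped
with a warning, because clipping would bias the means of replicate
triplicates. Dye concentrations use Beer–Lambert with calcein defaults
($\epsilon$ = 74,000 M^-1^cm^-1^ at 504 nm). Emission peaks are reported
at grid resolution with ties toward lower wavelength — surface
hydrophobicity work with ANS is intensity-based, not position-based, so no
sub-nm fit is attempted.

## Vesicle geometry and stoichiometry

A unilamellar vesicle of outer diameter $d$ with bilayer thickness $h$
(default 5 nm) and area per lipid $A_L$ (default 0.71 nm², fluid PC)
contains $[4\pi(d/2)^2 + 4\pi(d/2-h)^2]/A_L$ lipids — both leaflets
counted. These two constants are reconciliation defaults: they reproduce
the reference lipid count of a 110 nm PC vesicle (~97,700) to 0.1%, and
both are overridable. The monolayer protein capacity divides the outer
surface by the elliptical footprint $\pi a b$ with the footprint axes
entering directly (14 × 4 nm side-on and 4 × 4 nm end-on for albumin,
giving 216 and 756 molecules on a 110 nm vesicle — this convention
uniquely reproduces both reference capacities). Capacities are floored;
lipid counts rounded. Bound stoichiometry is
$N = P_B \cdot N_{lipids} / M_{protein}$ with the BSA molar mass default
66,430 g/mol, exposed because back-calculations are sensitive to it at the
3–6% level.

## Statistics

Replicates are summarized as mean ± SD (dispersion) or mean ± SE
(precision). Conformation comparisons use an independent two-sample
t-test at significance level 0.05 with a 95% CI for the mean difference.
"Independent test" is interpreted as the classical pooled-variance
Student's test; Welch is available since equal variances are an
assumption, not a certainty. No multiple-testing correction is applied
across elements or timepoints, matching the protocol the package
implements; the report notes this. The test's type-I error is calibrated
in the test suite by a seeded 10,000-replicate null simulation.

## The synthetic-data generator

`gen_spectrum()` evaluates true pseudo-Voigt components plus a straight
baseline on a regular grid (default 900–3000 cm^-1^ at 1 cm^-1^; the
recording range of a typical protein–liposome ATR experiment, with a step
finer than the usual 2–4 cm^-1^ ATR resolution so grid artifacts are
negligible) and adds iid Gaussian absorbance noise — the white-noise model
that Savitzky–Golay smoothing presumes. `gen_polarized()` constructs the
four polarized intensities so that the anisotropy and G-factor formulas
invert it exactly at zero noise. `gen_release_trace()` builds
first-order leakage kinetics, $f(t) = 1 - (1-f_0)e^{-kt}$, with a
residual fluorescence factor (default 0.1) for self-quenched encapsulated
dye and full dequenching on lysis, so the CR formula applied to noiseless
timepoints returns $(f(t)-f_0)/(1-f_0) \times 100$ exactly. Kinetic and
polarized-intensity noise is multiplicative, since photometric noise
scales with signal. All generators take a seed and are bit-reproducible.

Validation conditions follow the study the package models: Amide I
spectra from the published albumin compositions (59.9/23.2/16.9% for free
albumin; 52.8/19.1/28.0% after adsorption on phosphatidylinositol-rich
membranes) at SNR 100 with FWHM 20 cm^-1^ and 10 noise seeds; band-shift
pairs (phosphate 1230.2 → 1233.6 cm^-1^, methylene 2924 → 2925 cm^-1^) at
SNR 50. What the generator does *not* emulate — water-vapor lines,
atmospheric compensation residues, ATR penetration-depth wavelength
dependence, scattering baselines, correlated detector noise — bounds what
passing tests show about real instrument data: they validate the
estimators under the stated noise model, not the full messiness of an
instrument.

## Orchestration

`run_pipeline()` ties the stages together for a whole synthetic
incubation experiment (control and incubated compositions, several
timepoints and replicates, band-shift and carbonyl series, statistics
versus the 0-min control) and `write_report()` emits CSV tables plus a
JSON manifest recording the seed and every configuration value. All
randomness funnels through one base seed, so reruns are byte-identical.
Configurations round-trip through YAML (`write_config()` /
`read_config()`), with unspecified fields falling back to package
defaults. Default problem sizes (3 replicates, 5 timepoints, 10 seeds in
the validation runs) keep a full run in the low seconds on one core while
holding the Monte-Carlo error of recovered percentages near 0.2 points.

## Known limitations

* Amide I percentages inherit a small bias (≲1 point) from imposing
  canonical band positions; this is the price of a well-posed fit and is
  shared by any fixed-position protocol.
* The JCAMP-DX reader covers fixed-point/AFFN `XYDATA=(X++(Y..Y))`
  blocks only; compressed forms are rejected with a clear message.
* No Fourier self-deconvolution is implemented; second-derivative-guided
  fitting covers its use case here.
* Amide II is not quantified, and no atmospheric or ATR penetration-depth
  corrections are applied — inputs are assumed pre-compensated.
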