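# lipospec

Spectroscopy analysis of protein adsorption onto liposome membranes.

When liposomal drug carriers meet serum, albumin and other plasma proteins
adsorb onto the bilayer. That adsorption can destabilize the membrane
(leakage of the aqueous cargo) and partially denature the protein
(conversion of α-helix to random coil), which in turn changes how the
carrier is cleared. `lipospec` implements the quantitative analyses used
to characterize this interaction from ATR-FTIR and fluorescence
spectroscopy, for researchers working on liposome formulations and the
protein corona:

* **Amide I band decomposition** — protein secondary structure
  (α-helix / β-sheet / β-turn / random coil, plus intermolecular
  β-sheet aggregates) from the 1600–1700 cm⁻¹ C=O stretching band, by
  Savitzky–Golay second-derivative band detection and constrained
  pseudo-Voigt fitting (Levenberg–Marquardt):
  `amide_i_analysis()`, `fit_bands()`, `assign_secondary_structure()`.
* **Lipid band analyses** — sub-grid peak positions and shifts of the
  asymmetric phosphate (1220–1260 cm⁻¹), choline (~970 cm⁻¹) and
  methylene (~2924 cm⁻¹) bands, and the hydrogen-bonded fraction of ester
  carbonyls (1700–1760 cm⁻¹): `band_position()`, `band_shift()`,
  `carbonyl_hydration()`.
* **Fluorescence** — anisotropy *r* = (I_VV − G·I_VH)/(I_VV + 2G·I_VH)
  with G = I_HV/I_HH; calcein release
  CR = (I_t/I_max,t − I_0/I_max,0) · I_max,t/(I_max,t − I_0) · 100%;
  Beer–Lambert dye quantification; emission peaks:
  `anisotropy()`, `calcein_release()`, `dye_concentration()`.
* **Vesicle stoichiometry** — lipids per vesicle
  [4π(d/2)² + 4π(d/2−h)²]/A_L, monolayer protein capacity
  ⌊4π(d/2)²/(πab)⌋, and bound protein per vesicle from P_B values
  (g protein / mol lipid): `lipids_per_vesicle()`,
  `protein_surface_capacity()`, `bound_protein_per_vesicle()`.
* **Statistics** — replicate summaries and pooled/Welch two-sample
  t-tests for conformation comparisons: `summarize_replicates()`,
  `two_sample_ttest()`.
* **Synthetic data** — seeded generators for ground-truth-labelled
  spectra, polarized intensities, and leakage kinetics, so every stage is
  testable without instrument data: `gen_spectrum()`, `gen_polarized()`,
  `gen_release_trace()`; orchestration via `run_pipeline()`.

See the methods vignette (`vignettes/lipospec-methods.Rmd`) for the band
model, the identifiability analysis behind the constrained Amide I fit,
and all defaults.

## Worked example

Decompose a synthetic free-albumin Amide I band (generated from the
composition 59.9 / 23.2 / 16.9% with 1% noise) and compute binding
stoichiometry:

```r
library(lipospec)

tr <- components_from_areas(c(1655, 1633, 1645), c(59.9, 23.2, 16.9),
                            fwhm = 20)
clean <- gen_spectrum(spectrum_spec(tr, grid_start = 1580, grid_end = 1730))
s <- gen_spectrum(spectrum_spec(tr, grid_start = 1580, grid_end = 1730,
                                baseline_slope = 5e-5,
                                baseline_offset = 0.02,
                                noise_sd = max(clean$absorbance) / 100,
                                seed = 1))
amide_i_analysis(s)
#> Secondary structure (% of non-aggregate Amide I area)
#>   alpha-helix     60.7
#>   beta-sheet      23.3
#>   beta-turn        0.0
#>   random coil     16.0
#>   (sheet+turn     23.3)
#>   aggregates       0.0  (% of total area, reported apart)
```

The decomposition recovers the generating composition to about one
percentage point at this noise level. Stoichiometry from measured
diameters and P_B values:

```r
binding_table(data.frame(sample = c("PC", "10GM1"),
                         diameter = c(121.3, 118.5),
                         p_b = c(4.72, 2.48)))
#>   sample diameter  p_b lipids_per_vesicle protein_per_vesicle
#> 1     PC    121.3 4.72             119918            8.520442
#> 2  10GM1    118.5 2.48             114223            4.264234
```

A 121 nm phosphatidylcholine vesicle carries ~120,000 lipids; a P_B of
4.72 g/mol then corresponds to about 8.5 bound albumin molecules per
vesicle — far below the ~216 side-on monolayer capacity
(`protein_surface_capacity(110, protein_footprint(14, 4))`), i.e. the
tightly bound corona is sparse. Comparing helix percentages of two
conditions:

```r
two_sample_ttest(c(59.9, 61.1, 58.7), c(52.8, 54.3, 51.3))
#> Pooled two-sample t-test: t = 6.4019, df = 4, p = 0.0031
#> mean difference 7.1, 95% CI [4.021, 10.18]; significant at 0.05
```

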