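# hbspec

Quantitative analytics for hemoglobin preparations and hemoglobin–ligand
complexes, aimed at the assays that matter in hemoglobin-based oxygen
carrier (HBOC) work: how oxygenated a sample is, how fast it autoxidizes to
methemoglobin, how avidly it binds oxygen, and how strongly an effector
binds the protein.

The package implements, with a seeded synthetic-data generator and a
test suite that validates parameter recovery against recorded ground truth:

* **Four-wavelength species quantification.** From the optical densities at
  560/576/630/700 nm, with $d_\lambda = OD_\lambda - OD_{700}$:

  $\mathrm{Met} = 2.985\,d_{630} + 0.194\,d_{576} - 0.4023\,d_{560}$,
  $\mathrm{Deoxy} = 1.373\,d_{560} - 0.747\,d_{576} - 0.737\,d_{630}$,
  $\mathrm{Oxy} = 1.013\,d_{576} - 0.3269\,d_{630} - 0.7353\,d_{560}$,
  and $\mathrm{OxyHb\%} = 100\,\mathrm{Oxy}/(\mathrm{Met}+\mathrm{Deoxy}+\mathrm{Oxy})$.

* **Full-spectrum deconvolution** of an absorbance spectrum into three
  species concentrations plus baseline and Rayleigh scattering:
  $D(\lambda) = (\epsilon_{oxy}C_{oxy} + \epsilon_{deoxy}C_{deoxy} +
  \epsilon_{met}C_{met})L + K + S/\lambda^4$, by (optionally non-negative)
  linear least squares.

* **Time courses**: OxyHb% per 5-min deoxygenation cycle, metHb% per hour of
  autoxidation (optional pseudo-first-order rate), and the hydroxyl-radical
  clearance statistic $100\,(A_t - A_c)/(A_0 - A_c)$.

* **Oxygen affinity**: Hill fits $SO_2(p) = 100\,p^n/(P_{50}^n + p^n)$ for
  P50 and cooperativity, a model-free P50 cross-check, and the Bohr
  coefficient $-\Delta\log_{10}(P_{50})/\Delta\mathrm{pH}$ across pH.

* **SPR kinetics**: closed-form 1:1 Langmuir sensorgram simulation
  (240 s association / 480 s dissociation schedule) and global
  $(k_a, k_d, R_{max})$ fitting across a concentration series, with
  $K_D = k_d/k_a$.

* **MM/GBSA table auditing**: recomputes $\Delta G_{gas} = \Delta G_{vdw} +
  \Delta G_{ele}$, $\Delta G_{solv} = \Delta G_{polar} + \Delta G_{nonpolar}$
  and their total, flagging printed values inconsistent beyond rounding.

See `vignettes/hemoglobin-analytics.Rmd` for the models, assumptions and
design decisions.

## Worked example

```r
library(hbspec)

# Species composition from the four diagnostic wavelengths
s <- quantify_quartet(od_quartet(0.5, 0.8, 0.1, 0))
s
#> <hb_species_signal> met 0.25255, deoxy 0.0152, oxy 0.41006
oxy_fraction(s)   # 60.50 (% oxygenated hemoglobin)

# Full-spectrum deconvolution of a noisy synthetic 3 uM mixture (60/30/10)
b <- make_basis()
gen <- make_mixture_series(b, matrix(c(0.6, 0.3, 0.1), 1), k_offset = 0.01,
                           s_scatter = 5e8, noise_sd = 0.002, seed = 1)
unmix(gen$series$spectra[[1]], b, window = c(350, 700))
#> <hb_unmix> c_oxy 1.798e-06 M, c_deoxy 9.006e-07 M, c_met 3.04e-07 M
#>   K 0.01005 AU, S 5.003e+08 AU nm^4, rms 0.00193 AU (351 points, nonneg)
#>   metHb fraction 10.12%

# Oxygen dissociation curve: P50 and cooperativity
fit_hill(make_odc(p50 = 14.24, n = 2.6, noise_sd = 2, seed = 1)$odc)
#> <hb_hill_fit> P50 14.098 mmHg, n 2.495, rmse 1.55% (pH 7.4)

# Global 1:1 fit of an SPR dilution series
fit_1to1(make_sensorgrams(noise_sd = 1, seed = 1)$sensorgrams)
#> <hb_binding_fit> ka 9986 /M/s, kd 0.009014 /s, Rmax 100.2 RU
#>   KD = kd/ka = 9.027e-07 M (rmse 1.4 RU)
```

The concentrations, offset and scattering are recovered within the noise
from the generating truth (1.8/0.9/0.3 µM, K = 0.01 AU, S = 5×10⁸ AU·nm⁴);
the Hill and binding fits recover their generating parameters
(P50 = 14.24 mmHg, n = 2.6; ka = 10⁴ M⁻¹s⁻¹, kd = 9.03×10⁻³ s⁻¹,
KD = 9.03×10⁻⁷ M) to within a few percent at realistic noise.

A full configured run (generation → deconvolution → kinetics → affinity →
binding → audit) goes through `run_pipeline()`; see
`hbspec_example_config()` and the thin CLI at
`inst/cli/hbspec.R` (`Rscript hbspec.R run config.yaml`).

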