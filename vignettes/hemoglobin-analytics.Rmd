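---
title: "Models and methods behind hbspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hbspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbspec)
```

## Scope

hbspec analyzes the optical and biophysical assays used to characterize
hemoglobin preparations and hemoglobin–ligand complexes, the kind of
measurements that drive hemoglobin-based oxygen carrier (HBOC) development:
how much of the protein is oxygenated, how fast the ferrous heme autoxidizes
to non-functional methemoglobin (metHb), how avidly the protein binds and
releases oxygen (P50, Bohr effect), how strongly a small-molecule effector
binds (SPR kinetics), and whether a reported binding free-energy
decomposition is internally consistent. Every analysis can be exercised on
synthetic data with recorded ground truth, which is how the test suite
validates parameter recovery end to end.

## Four-wavelength species quantification

The fastest estimate of sample composition uses the optical densities at
560, 576, 630 and 700 nm. With the 700-nm reading subtracted as a common
baseline, three fixed linear combinations give unitless met-, deoxy- and
oxyhemoglobin signals:

$$\mathrm{Met} = 2.985\,d_{630} + 0.194\,d_{576} - 0.4023\,d_{560}$$
$$\mathrm{Deoxy} = 1.373\,d_{560} - 0.747\,d_{576} - 0.737\,d_{630}$$
$$\mathrm{Oxy} = 1.013\,d_{576} - 0.3269\,d_{630} - 0.7353\,d_{560}$$

with $d_\lambda = OD_\lambda - OD_{700}$, and
$\mathrm{OxyHb\%} = 100\,\mathrm{Oxy}/(\mathrm{Met}+\mathrm{Deoxy}+\mathrm{Oxy})$.

The coefficients are published calibration constants; hbspec stores them as
a named matrix (`hb_quartet_coefficients`) so they can be audited
digit-for-digit, and makes no attempt to re-derive them from extinction
spectra. Because all terms are differences against $OD_{700}$, the signals
are exactly invariant to a wavelength-independent offset and homogeneous of
degree one in the optical densities — both properties are enforced by tests.
Two deliberate choices:

* **Negative signals are flagged, never clipped.** The percentage uses the
  raw signal sum in its denominator; silently clipping a slightly negative
  deoxy signal would bias OxyHb% with no visible trace.
* **The percentage has a denominator floor** (`1e-6` by default). On a blank
  or a saturated artifact the signal sum approaches zero and the ratio is
  numerically meaningless; an error naming the situation is more useful than
  a huge number.

When the measured grid lacks one of the four wavelengths, the value is taken
by linear interpolation between the nearest neighbours. Instrument grids are
1–2 nm; higher-order interpolation would change nothing measurable and is
harder to audit.

## Full-spectrum deconvolution

Where the full visible spectrum (350–700 nm at 1 nm) is recorded, the
species concentrations come from the five-parameter linear model

$$D(\lambda) = \big(\epsilon_{oxy}(\lambda) C_{oxy} +
\epsilon_{deoxy}(\lambda) C_{deoxy} + \epsilon_{met}(\lambda) C_{met}\big) L
+ K + S/\lambda^4,$$

least-squares fitted over the chosen wavelength window. $K$ absorbs the
instrumental baseline, $S/\lambda^4$ is a Rayleigh-type turbidity term, and
$L$ is the optical path length (default 1 cm; a plate-reader path can be
supplied on the basis set).

Numerical choices:

* **Scattering column rescaling.** A raw $\lambda^{-4}$ column has magnitude
  ~$10^{-11}$ next to extinction products of order $10^{-1}$, which ruins the
  conditioning of the normal equations. Internally the column is
  $(\lambda_{ref}/\lambda)^4$ with $\lambda_{ref} = 500$ nm, and $S$ is
  rescaled back to AU·nm⁴ on output. The model is mathematically identical.
* **Non-negativity** (default on) applies to the three concentrations and
  $S$, which are physical, but not to $K$, which is instrumental and may be
  negative. The constrained problem is solved as a single non-negative
  least-squares fit with the offset split into positive and negative parts.
  With the constraint off the solution is the exact linear one; tests verify
  it against an independent normal-equations oracle.
* **Fit window.** The default window is 450–700 nm because the Soret region
  saturates easily at working concentrations; passing `window = c(350, 700)`
  fits everything measured, and that full-range setting is what the
  synthetic-recovery tests and the acceptance script use, since synthetic
  data cannot saturate.
* **The basis is interpolated onto the spectrum grid**, never the reverse:
  the measured absorbances enter the fit untouched.
* **Degeneracy is an error.** If the design matrix loses rank (two identical
  species curves, a zero curve), the fit refuses rather than returning an
  arbitrary solution from the null space.

The package ships no measured extinction curves. Basis sets come from a user
CSV or from the synthetic generator below; the deconvolution itself is
agnostic to their origin.

## Time courses

**Deoxygenation assay.** A series of spectra recorded as 5-minute cycles is
reduced to OxyHb% per cycle, by either the quartet pathway or full
deconvolution. The curve's `start_pct` is read at the configured end of the
oxygenation phase and `end_pct` at the last cycle. Both the oxygenation
length (default 10 cycles, i.e. 50 min) and the total cycle count are
configuration, not constants: published schedules differ between 50- and
60-cycle runs, so hardcoding either would be wrong for someone's data.
Cycles whose fraction is undefined are excluded with a warning; only a
series with no usable cycle errors out.

**Autoxidation.** Hourly spectra over 8 h are deconvolved and reported as
metHb% per timepoint. The optional pseudo-first-order fit
$m(t) = 100 - (100 - m_0)e^{-kt}$ is an explicitly labelled extension — the
assay itself reports per-hour percentages — and is off by default. The fit
uses Levenberg–Marquardt on the residual function directly (not the formula
interface, which fails spuriously on exactly flat series) with $m_0$ bounded
to [0, 100].

**Radical scavenging.** The o-phenanthroline–ferrous clearance statistic is
$100\,(A_t - A_c)/(A_0 - A_c)$ from the 536-nm absorbances of blank, control
and sample tubes, applied exactly as defined: out-of-range results carry a
flag instead of being clamped, and coinciding blank/control absorbances
(denominator below `1e-9`) raise an error.

## Oxygen affinity

Saturation curves are fitted with the two-parameter Hill model
$SO_2(p) = 100\,p^n/(P_{50}^n + p^n)$, asymptote fixed at 100% because
instrument output is normalized. A two-parameter sigmoid is identifiable
from the 20-point instrument-style grids this package targets; a
four-constant Adair scheme would not be, and nothing downstream needs it.
Starting values come from a model-free P50 (linear interpolation of the
first bracketing pair — also exposed as `p50_model_free()`, a useful
cross-check that agrees with the Hill fit within 2% on clean data) and the
log-logit slope for $n$. Data that never cross 50% saturation cannot yield a
P50 and raise an error rather than an extrapolation.

The Bohr effect is summarized as $-\Delta\log_{10}(P_{50})/\Delta\mathrm{pH}$,
estimated by least-squares regression of $\log_{10}(P_{50})$ on pH over at
least two runs. This regression convention is this package's definition —
reported pH series are short (7.2/7.4/7.6) and a slope on the log scale is
the standard way to make runs comparable.

## SPR binding kinetics

Sensorgrams follow the closed-form 1:1 Langmuir solution: association
$R(t) = R_{eq}(1 - e^{-(k_a C + k_d)t})$ with
$R_{eq} = k_a C R_{max}/(k_a C + k_d)$, then dissociation
$R(t_{end}) e^{-k_d (t - t_{end})}$, on the default schedule of 240 s
association and 480 s dissociation sampled at 1 Hz. Using the exact
expressions instead of an ODE integrator removes solver tolerance as a
variable from both simulation and fitting.

The global fit shares $(k_a, k_d, R_{max})$ across the concentration series
(default 5/2.5/1.25/0.625/0 µM) and optimizes their logarithms, which
enforces positivity and equalizes step sizes across nine orders of
magnitude. A zero-concentration curve is used purely as a reference
subtraction. $K_D = k_d/k_a$ is definitional, so the identity holds to
machine precision in every fit result. Mass-transport limitation and bulk
refractive-index jumps are not modelled; a single curve fitted with shared
parameters triggers an identifiability warning because $k_a$ and $R_{max}$
are then confounded.

## Energy-table audit

MM/GBSA decomposition tables obey three additive identities: gas-phase
energy is van der Waals plus electrostatics, solvation is polar plus
nonpolar, and the total is their sum. `audit_energy_table()` recomputes all
three from the four components and flags printed values that differ by more
than 0.0005 kcal/mol — last-digit rounding for a four-decimal table.
Standard-deviation columns are parsed and carried through but never
propagated, since component covariances are unknown. A consistent table from
an HbA–spermine generalized-Born calculation ships in
`inst/extdata/mmgbsa_hba_spermine.csv` as a worked input.

## Synthetic data and what it can show

The generator produces every input the pipeline consumes, with a truth
record alongside:

* **Basis spectra** are sums of Gaussian bands placed at the named features
  of each species (oxyHb 414/541/577 nm, deoxyHb 430/555 nm, metHb
  405/500/630 nm) with per-heme-scale amplitudes (Soret ~1.3×10⁵,
  Q bands ~10⁴ M⁻¹cm⁻¹). They are full-rank and realistically shaped, but
  they are *pseudo*-extinction curves, not literature tables.
* **Mixture series** apply the exact deconvolution forward model at a total
  concentration of 3 µM (a typical working concentration) plus additive
  Gaussian noise in AU. Default noise 0.002 AU is ordinary
  spectrophotometer-grade; heteroscedastic or wavelength-correlated noise is
  out of scope.
* **ODCs** are Hill curves (defaults P50 14.24 mmHg, n 2.6 — native-tetramer
  scale values) on 20 log-spaced pressures over 1–150 mmHg, mimicking the
  dense low-pressure sampling of dissociation analyzers, with noise in
  percentage points clipped to [0, 100] and clip events counted.
* **Sensorgrams** use the closed-form model at ka 10⁴ M⁻¹s⁻¹,
  kd 9.03×10⁻³ s⁻¹ (KD ≈ 0.9 µM, a typical weak effector), Rmax 100 RU,
  noise 1 RU.

Determinism is a contract: identical configuration and seed give
bit-identical outputs, and per-object seeds derive from the master seed by a
counter (`seed + index`), so any subset regenerates identically.

Because the generators invert exactly the models the fitters assume,
recovery tests demonstrate correctness of the estimation machinery — that
the code solves its stated problem — not robustness to model misspecification
in real instruments (saturated Soret bands, drifting baselines,
mass-transport-limited sensorgrams). That distinction is why the fit window,
the non-negativity switch and the reference subtraction are all exposed
rather than baked in.

## Problem sizes and runtime

The shipped tests and the acceptance script run at the assay's native sizes:
351-wavelength spectra, 9-point autoxidation series, 60-cycle deoxygenation
runs, 20-point ODCs, and five 721-point sensorgrams, with Monte-Carlo
repetition at 100 seeded replicates for the noisy-recovery properties. The
complete suite takes well under a minute on one core.

## Known limitations

* Three species only (oxy/deoxy/met); hemichromes, sulf- and carboxy-Hb are
  not modelled.
* The quartet coefficients are instrument-calibration constants; applying
  them to spectra from a very different optical setup transfers that
  calibration error.
* The Hill model compresses cooperativity into one exponent; curves from
  strongly heterogeneous samples will show structured residuals.
* The 1:1 binding model has no mass-transport or avidity terms; a good fit
  does not prove the mechanism.
* The energy audit checks arithmetic self-consistency of a reported table,
  nothing about the simulation that produced it.

## Pipeline

`run_pipeline()` executes configured stages in a fixed order
(generate → unmix → deoxygenation → autoxidation → clearance → ODC → Bohr →
SPR → energy audit), writes per-stage CSV/JSON next to a `summary.json`
containing stage statuses, surfaced warnings and a hash of the effective
configuration (excluding the output location), and is reproducible
bit-for-bit under a fixed seed. `hbspec_example_config()` returns a complete
runnable configuration; a thin command-line wrapper lives at
`system.file("cli", "hbspec.R", package = "hbspec")`.

```{r example, eval = FALSE}
cfg <- hbspec_example_config(output_dir = "run1", seed = 1)
rep <- run_pipeline(cfg)
rep$stages$odc$results$p50_mmhg
```
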