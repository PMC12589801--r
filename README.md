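# pbctmicro

Microdosimetric analysis pipeline for proton boron capture therapy (PBCT)
studies with silicon-on-insulator (SOI) microdosimeters.

## The problem

PBCT proposes to boost the biological effectiveness of proton therapy through
the p + ¹¹B → 3α capture reaction: the three alpha particles released near
the Bragg peak are densely ionizing, so even without measurable extra dose
they can raise the *radiation quality* at the cellular scale. The quantity of
interest is the **dose-averaged lineal energy**

```
ȳ_D = Σ y² f(y) / Σ y f(y)        [keV/µm]
```

where `y` is the lineal energy of a single event (energy deposited in a
micron-scale sensitive volume divided by the mean chord length) and `f(y)`
its frequency. A single-sensitive-volume SOI microdosimeter (2,500 µm² area,
10 µm silicon layer) records voltage pulses on an oscilloscope; the linear
calibration `y = a · P + b` converts peak amplitudes `P` (mV) into lineal
energies, with the coefficients fitted once per beam energy at the entrance
depth against a reference spectrum and then transferred to all depths.

Raw oscilloscope data for such experiments are rarely released, so this
package pairs the analysis chain with a fully seeded **synthetic event
generator** whose defaults emulate the published study conditions:
monoenergetic 70 and 190 MeV beams, entrance plateau near 2 keV/µm rising to
about 8 keV/µm at the Bragg peak, ten repeats per condition, and an optional
boron-induced alpha admixture bounded by the 8.68 MeV reaction Q-value and
filtered through a 30–50 µm separation gap using tabulated alpha
range–energy anchors in PMMA (33, 45, 58, 73 µm at 5, 6, 7, 8 MeV).

The package provides, module by module:

- **alpha physics** — range–energy interpolation with power-law
  extrapolation, mass-thickness material equivalence, gap transmission
  fractions, residual energies, and alpha lineal-energy conversion;
- **beam model** — parameterized ȳ_D depth profiles (tabulated override
  supported), per-depth lognormal/gamma spectrum models with closed-form
  moment matching, and fluence accounting;
- **synthetic data** — seeded generators for ground-truth lineal-energy
  event lists, oscilloscope peak lists, and raw voltage traces;
- **signal pipeline** — baseline thresholding, peak extraction,
  quantile–quantile calibration fitting, conversion, 0.5 keV/µm binning over
  0–20 keV/µm, and Monte Carlo propagation of calibration uncertainty;
- **microdosimetry** — ȳ_D, ȳ_F, dose-weighted distributions, repeat
  aggregation, and Welch two-tailed unpaired comparisons (raw repeats or
  `(mean, sd, n)` summaries);
- **study runner** — the end-to-end depth scans and the four-condition boron
  comparison, with per-beam entrance calibration, full seed determinism, and
  CSV/JSON/figure reporting.

## Worked example

```r
library(pbctmicro)

cfg <- study_config(master_seed = 7)   # calibrated preset conditions, 10 repeats
res <- run_boron_study(cfg)
res
```

```
Condition summary:
  energy_MeV       depth_label depth_cm boron ydbar_mean  ydbar_sd n_repeats
1         70      Entrance (2)      2.0 FALSE   2.290470 0.5287642        10
2         70      Entrance (2)      2.0  TRUE   2.331341 0.8371791        10
3         70  Bragg Peak (3.8)      3.8 FALSE   7.936282 1.0239037        10
4         70  Bragg Peak (3.8)      3.8  TRUE   9.531201 1.1281343        10
5        190      Entrance (5)      5.0 FALSE   2.109364 0.3734058        10
6        190      Entrance (5)      5.0  TRUE   1.965950 0.5118425        10
7        190 Bragg Peak (22.5)     22.5 FALSE   7.481461 0.3879195        10
8        190 Bragg Peak (22.5)     22.5  TRUE   9.612244 1.1562599        10

Boron comparisons (Welch, two-tailed):
  energy_MeV depth_cm t_statistic degrees_of_freedom      p_value
1         70      2.0   0.1305264           15.19476 0.8978623604
2         70      3.8   3.3105103           17.83345 0.0039283952
3        190      5.0  -0.7158035           16.46532 0.4841412232
4        190     22.5   5.5248756           11.00068 0.0001793567
```

Each row is one condition: the mean and SD of ȳ_D over ten simulated repeats
after the full pipeline (truth → pulses → entrance-fitted calibration →
lineal energies → ȳ_D). Boron raises ȳ_D at both Bragg peaks, strongly
significantly at 190 MeV (p ≈ 2 × 10⁻⁴), while the entrance rows show no
effect — the alpha admixture is zero there because upstream alphas cannot
cross the separation gap.

The alpha-side geometry behind that admixture:

```r
tb <- pmma_range_table()
invert_range(40, tb)
#> 5.583333            # MeV needed to cross a 40 µm PMMA gap
transmission_fraction(alpha_spectrum_model(), gap_geometry(40), tb)
#> 0.3567588           # fraction of a uniform (0, 8.68] MeV spectrum crossing
equivalent_thickness(40, 0.92, 1.18)
#> 31.18644            # 40 µm LDPE window expressed as PMMA, µm
```

Depth scans (`run_depth_scan(cfg)`) return a tidy table of ȳ_D versus depth
per beam; `report(res, dir, depth_scan = scan, plots = TRUE)` writes the CSV
tables, a JSON summary with provenance, and the standard figures.

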