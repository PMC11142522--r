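# multiqmap

Multiparametric quantitative MRI (qMRI) turns a multi-sequence brain
acquisition into voxel-wise maps of physical tissue parameters instead of
arbitrary contrast. `multiqmap` implements a complete analysis for a
45-minute 3 T brain protocol, for imaging scientists who want the whole
chain — simulation, fitting, and cohort statistics — in one tested,
seeded, scriptable package:

- **Relaxometry** — T1 from inversion-recovery data (signed three-parameter
  model `S(TI) = a + b e^{-TI/T1}`) and from variable-flip-angle
  spoiled-GRE data with transmit-field (B1+) correction; T2 by
  extended-phase-graph (EPG) echo-modulation-curve dictionary matching of
  multi-echo spin-echo trains; T2* by truncated log-linear fitting.
- **Susceptibility (QSM)** — nonlinear complex field fitting, Laplacian
  phase unwrapping, noise-based mask erosion, projection onto dipole
  fields, and iterative Tikhonov dipole inversion
  (`chi = argmin ||M(F^-1 D F chi - f)||^2 + alpha ||chi||^2`, alpha = 0.05,
  `D(k) = 1/3 - k_z^2/|k|^2`).
- **Tissue fractions** — water fraction from CSF-referenced proton
  density with polynomial receive-bias removal; macromolecular tissue
  volume fraction `MTVF = 100% - WF`.
- **Diffusion** — log-linear tensor fit over a 64-direction b = 1000
  s/mm^2 shell; mean diffusivity `MD = (l1+l2+l3)/3` and fractional
  anisotropy `FA = sqrt(3/2) sqrt(sum(l_i - MD)^2) / sqrt(sum l_i^2)`.
- **Magnetization transfer** — `MTR = 1 - S+/S0` and
  `ihMTR = ((S+ + S-) - (S+- + S-+))/S0` from the five-image ihMT set.
- **Digital phantom** — a bilateral labeled brain phantom with
  per-ROI ground truth drawn from a packaged cohort reference table,
  inter-subject variation, smooth intra-ROI texture, smooth B1+/receive
  bias fields, Rician noise, and repeat sessions; every sequence is
  simulated from its forward model.
- **Cohort statistics** — ROI extraction with single-voxel erosion and a
  weak (3 SD) Chauvenet outlier pass; inter-subject vs intra-ROI
  variability tables with CV = 100 SD/mean; right/left hemispheric
  regression; Bland-Altman scan-rescan agreement with 95% limits of
  agreement at mean ± 1.96 SD.

## A worked example

Simulate a two-subject study with repeat scans, fit the MT maps, and run
the three analyses:

```r
library(multiqmap)

st <- run_study(n_subjects = 2, n_rescans = 2, snr = 60, seed = 12,
                grid = c(48, 48, 48), map_types = c("MTR", "ihMTR"))

head(subset(st$variability, map == "MTR",
            select = c(roi, mean, sd_inter, cv_pct, sd_intra)), 4)
#>            roi  mean sd_inter cv_pct sd_intra
#> 8  cerebral_wm 15.95  0.09797 0.6140    2.565
#> 6      caudate 13.72  0.54074 3.9416    2.287
#> 20     putamen 13.78  0.38752 2.8112    2.149
#> 18    pallidum 14.89  0.30767 2.0656    2.118
st$hemispheres
#>         map     slope intercept         r      p_value  n
#> ihMTR ihMTR 0.7242161  1.025540 0.8753827 9.652548e-08 22
#> MTR     MTR 0.8224750  2.709949 0.8086173 5.257929e-06 22
st$bland_altman[, c("map", "mean_diff", "sd_diff", "loa_upper", "loa_lower", "n_pairs")]
#>         map  mean_diff   sd_diff loa_upper loa_lower n_pairs
#> ihMTR ihMTR 0.24173457 0.6372169 1.4906797 -1.007211      24
#> MTR     MTR 0.05592104 0.3544225 0.7505891 -0.638747      24
```

Reading the MTR rows: the cohort mean in cerebral white matter is about
16 %, the spread of subject means (here: two subjects drawn from the
reference distribution plus measurement noise) is far smaller than the
within-ROI spread (`sd_intra`, inflated by the simulated SNR of 60), the
hemispheres agree with slope near 1 and r > 0.8, and the session
difference is near zero with 95 % limits of agreement of roughly
±0.7 MTR percentage points.

The variability table mirrors the study layout (per map and ROI: voxel
counts, mean across subjects, between-subject SD, CV, and mean within-ROI
SD); the hemispheric table regresses left on right ROI means over all
bilateral ROIs; the Bland-Altman table compares the two sessions per map.
With 28 subjects the hemispheric regression pools 28 x 11 = 308 values;
with 23 rescanned subjects the Bland-Altman analysis pairs 23 x 12 = 276
comparisons.

Individual fitters work on in-memory `image_series` objects:

```r
ph  <- build_phantom(c(48, 48, 48), seed = 1)
sub <- sample_subject(ph, subject_seed = 5)
ser <- simulate_acquisitions(sub, default_protocol(), snr = Inf)

dict <- build_emc_dictionary()                 # EPG dictionary, T2 1-300 ms
t2   <- fit_t2_emc(ser$MESE, dict)$t2
mean(t2$data[ph$labels == 1], na.rm = TRUE)    # cerebral-WM T2 [ms]
#> [1] 59.56255
mean(sub$truth$T2[ph$labels == 1])             # generating truth
#> [1] 59.56544
```

A thin command-line front end (`inst/cli/multiqmap.R`) exposes
`simulate`, `fit`, `stats` and `run-study` with `--protocol`, `--seed`,
`--snr` and output-directory options; all outputs are NIfTI volumes, CSV
tables and a YAML manifest under one run directory.

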