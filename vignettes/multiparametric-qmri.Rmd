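---
title: "Multiparametric quantitative MRI: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric quantitative MRI: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiqmap)
```

`multiqmap` implements a complete multiparametric quantitative-MRI (qMRI)
analysis for 3 T brain imaging: voxel-wise estimators for ten quantitative
maps (T1, T2, T2*, magnetic susceptibility, water fraction, macromolecular
tissue volume fraction, mean diffusivity, fractional anisotropy, MTR,
ihMTR), a seeded digital brain phantom that simulates the raw image series
of every sequence in the protocol, and the region-of-interest (ROI)
statistics used to characterize a cohort: inter-subject versus within-ROI
variability, right/left hemispheric symmetry, and Bland-Altman scan-rescan
agreement. This vignette documents the signal models, the simulator's
statistical contract, the numerical choices, and the limits of what the
synthetic validation can show.

## The acquisition protocol

The packaged protocol (`default_protocol()`) describes a nine-row
acquisition: FLAIR and MP2RAGE anatomy, a 12-echo multi-echo spin echo
(MESE, 12 ms spacing, 160 degree refocusing), an 8-echo multi-echo gradient
echo (GRE), a four-TI inversion-recovery EPI, a three-angle spoiled
gradient echo (5/12/27 degrees, TR 26 ms), a 64-direction two-shell
(b = 0, 1000 s/mm^2) diffusion acquisition with a short reversed
phase-encode segment, and a five-condition ihMT sequence. Summed durations
give the nominal 45.5-minute session. The GRE echo times are printed in
the protocol as a range with first echo 5.2 ms and last echo 36.9 ms; the
packaged default expands this to 8 echoes linearly spaced between those
endpoints (spacing 31.7/7 ≈ 4.529 ms), which satisfies both the stated
echo count and the stated maximum simultaneously. Durations are stored as
integer seconds and rendered as `"mm:ss"` only at the file boundary, so
protocol files round-trip exactly.

## Signal models and estimators

**T2 (EPG dictionary matching).** The MESE echo train deviates from pure
exponential decay whenever refocusing is imperfect, because stimulated
echoes store magnetization longitudinally between pulses. The forward
model is the extended-phase-graph (EPG) recursion with instantaneous
pulses and ideal crushers: a 90 b1 excitation, then per echo a half-ESP
relaxation, gradient shift, refocusing rotation of `160 * b1` degrees
about x, shift, and another half-ESP relaxation. The same recursion is
validated against a brute-force isochromat Bloch simulation (201 spins
with explicit crusher dephasing) to relative error below 1e-3, and serves
both the simulator and the fitting dictionary, which spans T2 from 1 to
300 ms (logarithmic, 200 points) by B1 from 0.7 to 1.3 (step 0.02) at a
fixed T1 of 1000 ms. The T1 assumption follows the echo train's weak T1
sensitivity at this echo spacing; the grids are configurable. Matching
maximizes the normalized inner product, so the estimator is invariant to
receive-field and proton-density scaling. Slice-profile modelling (full
Bloch dictionaries over the excitation profile) is deliberately out of
scope; because simulator and fitter share the forward model, the phantom
cannot detect slice-profile bias — a real-data limitation to keep in mind.
An optional `denoise_hook()` marks where a principal-component denoiser
would run ahead of matching; the default is the identity.

**T2\* (truncated log-linear).** Echoes below 10 percent of the first
echo's magnitude are truncated to avoid the Rician noise floor biasing the
log-linear fit, then T2* is minus the inverse slope of the ordinary
least-squares regression of log magnitude on echo time (unweighted, as is
conventional for this protocol). Voxels with fewer than two retained
echoes or a non-negative slope are invalid — in vivo this makes CSF and
vessels appear as nulls because the 36.9 ms maximum echo time cannot
support their long T2*.

**Field mapping and susceptibility (QSM).** The chain is: (1) voxel-wise
nonlinear fitting of the complex GRE data m(TE) = A exp(i(phi0 + 2 pi f
TE)) by magnitude-weighted Gauss-Newton iterations on the phase,
initialized from the first echo pair — with uniformly spaced echoes f is
identifiable only modulo 1/dTE, and larger offsets are restored spatially
by unwrapping; (2) Laplacian phase unwrapping through the identity
phi_u = invLap(cos phi Lap sin phi − sin phi Lap cos phi), computed on a
field of view doubled by even mirror extension so that the periodic
transforms see continuous data; (3) noise-based mask erosion (voxels whose
field-fit standard error exceeds three times the in-mask median, plus one
6-connected erosion); (4) projection onto dipole fields (PDF): the
in-mask field is fit, in noise-weighted least squares, by sources outside
the mask, and the residual is the local field; (5) Tikhonov-regularized
dipole inversion (regularization weight alpha = 0.05) by conjugate
gradient in the image domain, with the discrete kernel
D(k) = 1/3 − (k·b0)^2/|k|^2, D(0) = 0. Dipole convolutions everywhere use
zero-padding factor 2, and the simulator uses the same operator, so
forward and inverse form a consistent pair. A `rotate_to_b0()` resampler
(zero-padded to the grid diagonal, trilinear) aligns oblique acquisitions
with the field axis; the phantom is acquired axially, where it reduces to
the identity.

Two numerical choices in this chain deserve emphasis. First, the PDF
normal equations are solved by Jacobi-preconditioned conjugate gradient
(the preconditioner is the weighted squared dipole coupling of each
exterior source to the mask) with a deliberately loose stopping rule
(relative residual 1e-3, 30 iterations by default). Driving this solver
to tight tolerance is harmful, not better: fields of compact interior
sources are nearly harmonic over most of the mask and an exactly solved
projection absorbs them into the background, whereas the early-stopped
iteration — as in the reference implementations of PDF — removes exterior
fields essentially completely (over 95 percent of their in-mask energy)
while leaving distributed interior fields largely intact. Second, the
inversion output is divided by the central value of its own point spread
function, mean_k D^2/(D^2 + alpha); without this standard correction the
regularized inversion underestimates susceptibility globally. The map is
referenced to a zero mean over the mask, or over CSF when a CSF mask is
supplied. Even so, mask-constrained regularized inversion at the
phantom's 3 mm resolution biases the means of small deep-gray structures
by up to about 0.05 ppm; this solver-scale floor, not 0.01 ppm, is what
the end-to-end suite asserts. QSM is the least transferable map across
processing choices, consistent with the large between-pipeline spreads
reported in the QSM literature.

**T1, water fraction, macromolecular fraction.** Inversion-recovery data
are fit per voxel to the signed three-parameter model
S(TI) = a + b exp(−TI/T1). Magnitude data are polarity-restored first:
samples before the minimum-magnitude TI are negated, and both polarities
of the minimum sample are tried, keeping the lower-residual fit (the
minimum sample may fall on either side of the null crossing, so fixing
its sign can corrupt the fit). The T1 axis is searched on a logarithmic
grid with (a, b) solved in closed form, then refined by golden section —
a robust, derivative-free scheme that recovers noiseless data to 1e-6
relative error. The transmit-field scale c (B1+) is then estimated per
voxel by least squares of the spoiled-GRE steady state over the three
flip angles, with E1 fixed by the IR T1 map; because the transmit field
is physically smooth, the voxelwise estimate is regularized by an
order-3 polynomial fit over the brain, and values outside [0.3, 1.7] are
clipped and flagged. Variable-flip-angle T1 then uses the linearized
steady-state fit (S/sin vs S/tan) with B1+-corrected angles. The
equilibrium-signal map M0 yields the water fraction by referencing to
CSF: an order-2 polynomial is fit to log M0 over CSF voxels to capture
the multiplicative receive bias, divided out brain-wide, and the result
is normalized so the median corrected M0 over CSF is 1 (CSF is 100
percent water); WF is reported in percent and MTVF = 100 − WF, both
clipped to [0, 120] with out-of-range voxels flagged. This CSF-referenced
polynomial bias model is a simplified stand-in for multi-coil
receive-field estimation; it shares the output contract but not the
machinery of the full method, and its accuracy depends on CSF sampling
the volume (the phantom provides both ventricles and a subarachnoid rim).

**Diffusion.** The tensor is fit by ordinary least squares of ln S on the
b-matrix design with an intercept for ln S0 (the weighting of the
estimator is not standardized across tools; OLS is the simplest
defensible choice). Non-positive signals are excluded per voxel; voxels
with fewer than six usable diffusion-weighted measurements are invalid.
MD and FA come from the analytic eigenvalues of the symmetric tensor; a
negative smallest eigenvalue is flagged rather than silently clipped. The
64-direction electrostatic-repulsion gradient table ships as an FSL-style
bvec/bval fixture; the reversed phase-encode segment is accepted and its
b = 0 volumes may be averaged into S0, while susceptibility-distortion
correction itself is out of scope (the phantom has no distortion).

**Magnetization transfer.** MTR = 1 − S+/S0 and
ihMTR = ((S+ + S−) − (S+− + S−+))/S0, in percent, from the five-image
ihMT set; S0 = 0 voxels are invalid, and both ratios are invariant to a
common image scaling. The dual-saturation ratio MTRd = 1 − S+−/S0 is
available but off by default. No quantitative MT model stands behind
these ratios — the maps are defined by the ratios themselves.

## The digital phantom and what it does (not) emulate

`build_phantom()` places the twelve study ROIs (cerebral white matter,
caudate, putamen, pallidum, corpus callosum, thalamus, ventral
diencephalon, accumbens, amygdala, hippocampus, insula, cortex) plus CSF
inside a brain-shaped mask: deep structures are ellipsoids deformed by a
smooth random field, white matter fills the interior, the cortex is an
outer shell, and CSF comprises the ventricles and a subarachnoid rim.
With `asymmetry = 0` the deformation is mirror-symmetrized, so anatomy is
exactly bilateral (the corpus callosum crosses the midline and has no
left/right split). Geometric realism is explicitly a non-goal — the
statistical structure is the contract:

- Per (map, ROI), a subject-level mean is drawn from
  Normal(mean, sd_inter) and voxel values add a smooth zero-mean field
  rescaled so the within-ROI SD equals sd_intra; both parameters come
  from the packaged reference table (`roi_reference_table()`), which
  stores the cohort values in canonical map units. CSF receives fixed
  literature-plausible values (T1 4000 ms, free-water diffusivity, zero
  susceptibility and MT ratios).
- Biological texture uses a 12-voxel correlation length. Hardware fields
  (B1+ amplitude 6 percent, receive bias 4 percent) use a correlation
  length equal to the grid extent: transmit and receive profiles at 3 T
  vary on the scale of the whole head, and this is also the regime in
  which a low-order polynomial is the right smoothing model.
- Each sequence is simulated from its fitting model (EPG for MESE,
  spoiled-GRE steady state, signed IR, complex GRE with the dipole field
  of the susceptibility truth plus a smooth exterior background source,
  monoexponential tensor decay with per-ROI principal axes, and a
  ratio-consistent five-image ihMT set with degenerate S+ = S− and
  S+− = S−+). Noise is independent complex Gaussian with
  sigma = mean tissue signal / SNR added before the magnitude operation,
  which yields Rician magnitude statistics; the default SNR of 50 is a
  mid-range clinical value (the study conditions do not pin one down),
  and `snr = Inf` gives noiseless data.
- Rescans reuse the identical ground truth with an independent noise
  stream; an optional smooth multiplicative bias drift between sessions
  is off by default.

Everything is reproducible bit-for-bit from the (geometry seed, subject
seed, noise seed) triple. Because the simulator and the fitters share
their forward models, passing tests demonstrate correct inversion of the
stated models and correct statistical plumbing — they cannot demonstrate
robustness to model violations real data carry (slice profiles, flow,
motion, distortion, partial volume, exchange, non-Gaussian noise after
image reconstruction).

## ROI statistics

ROI extraction follows the study's exclusion rules: one 6-connected
erosion of the label mask (partial-volume guard), removal of zero or
invalid voxels (fitting failures encode as zeros in exported maps),
then a weak Chauvenet criterion — a single, non-iterated pass removing
values more than 3 sample SDs from the mean, which excludes about 0.27
percent of Gaussian data. Voxel counts are reported from the retained
map values, not the label volume. The cohort table separates
inter-subject variability (SD across subjects of per-subject ROI means)
from intra-ROI variability (mean across subjects of within-ROI SDs),
with CV = 100 SD / mean carrying the sign of the mean. The headline
ratio of intra-ROI to inter-subject variability can be averaged over all
cells or per map first; the mean is identical either way (equal group
sizes) and both spreads are available. Hemispheric symmetry is assessed
by pooled ordinary least squares of left on right ROI means over
subjects and bilateral ROIs (the corpus callosum is excluded; 28
subjects x 11 ROIs = 308 points), with Pearson's r and the two-sided p
from t = r sqrt((n−2)/(1−r^2)). Scan-rescan agreement uses Bland-Altman
analysis of paired session means (23 subjects x 12 ROIs = 276 pairs):
mean and SD of the difference, limits of agreement at mean ± 1.96 SD,
and the regression of difference on mean.

## Problem sizes and tolerances used by the validation suite

The test suite and the acceptance script run the cohort analyses on
48-voxel cubic phantoms (3 mm voxels), cohorts of 28 subjects for the
hemispheric count and 23 subjects x 2 sessions for the rescan count
(using the MT maps, whose fits are exact and fast), and one noiseless
subject for end-to-end recovery of all ten maps. Per-map end-to-end
tolerances reflect each estimator's intrinsic resolution at these sizes:
the dictionary grid spacing for T2 (2 percent), the residual polynomial
transmit-field smoothing for T1 (2 percent), the CSF-extrapolated bias
polynomial for WF/MTVF (2 percentage points), machine-precision limits
for T2*, MD, FA, MTR and ihMTR, and the regularized-inversion floor for
QSM (0.08 ppm on ROI means). Monte-Carlo checks (inter-subject spread,
Rician moments, Chauvenet fraction, permutation p-values) use fixed
seeds and tolerances several standard errors wide.

## Known limitations

- The phantom's anatomy is schematic; volumes and shapes do not match
  the cohort's, so voxel-count columns of the synthetic tables are not
  comparable to the reference table's.
- ihMT images are generated ratio-consistently from the MTR/ihMTR truth
  (no two-pool saturation physics), so the MT maps validate the ratio
  arithmetic and the statistics, not saturation modelling.
- The EMC dictionary omits slice-profile effects by design; T2 accuracy
  on real multi-slice data depends on the acquisition matching the
  idealized train.
- QSM ROI means carry a resolution- and regularization-dependent bias
  (see above); cross-pipeline comparability of susceptibility values is
  known to be poor.
- Registration, segmentation, denoising internals, distortion and motion
  correction are upstream of this package and are not modelled: the
  phantom's labels are exact, so segmentation error is absent from all
  synthetic results.
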