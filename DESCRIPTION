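Package: multiqmap
Title: Multiparametric Quantitative MRI Mapping, Simulation and Reproducibility Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise estimation of ten quantitative MRI maps from a
    multi-sequence 3 Tesla brain protocol: T1 (inversion-recovery and
    B1+-corrected variable flip angle), T2 (extended-phase-graph echo
    modulation curve dictionary matching), T2* (truncated log-linear fit),
    quantitative susceptibility (nonlinear complex field fitting, Laplacian
    unwrapping, projection onto dipole fields, iterative Tikhonov dipole
    inversion), water and macromolecular tissue volume fractions, diffusion
    tensor mean diffusivity and fractional anisotropy, and magnetization
    transfer ratios (MTR, ihMTR). Includes a seeded bilateral digital brain
    phantom that simulates every raw image series with Rician noise, bias
    fields and repeat sessions, plus region-of-interest statistics for
    inter-subject variability, hemispheric symmetry and Bland-Altman
    scan-rescan agreement.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
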