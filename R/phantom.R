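#' Region labels of the digital brain phantom
#'
#' Twelve bilateral brain structures plus CSF. Labels 1-12 follow the
#' study's ROI list (cerebral white matter, caudate, putamen, pallidum,
#' corpus callosum, thalamus, ventral diencephalon, accumbens, amygdala,
#' hippocampus, insular cortex, whole cortex); label 13 is CSF and 0 is
#' background. All ROIs except the corpus callosum are mirrored across the
#' mid-sagittal plane.
#'
#' @return data.frame with columns `id`, `name`, `bilateral`.
#' @export
roi_labels <- function() {
  data.frame(
    id = 1:13,
    name = c("cerebral_wm", "caudate", "putamen", "pallidum",
             "corpus_callosum", "thalamus", "ventral_dc", "accumbens",
             "amygdala", "hippocampus", "insula", "cortex", "csf"),
    bilateral = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Per-ROI parameter reference table
#'
#' The packaged cohort reference: per (map type, ROI), the mean value, the
#' between-subject SD and the mean within-ROI SD, in canonical map units
#' (ms, ppm, percent, 1e-4 mm^2/s, unitless), plus the voxel-count
#' statistics. These values parameterize the phantom generator's default
#' ground truth.
#'
#' @return data.frame with columns `map`, `roi`, `units`, `n_mean`,
#'   `n_sd`, `n_cv_pct`, `mean`, `sd_inter`, `cv_pct`, `sd_intra`.
#' @export
roi_reference_table <- function() {
  utils::read.csv(system.file("extdata", "roi_reference_values.csv",
                              package = "multiqmap", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Scan-rescan agreement reference table
#'
#' The packaged per-map Bland-Altman reference of the cohort's two-session
#' comparison (23 subjects x 12 ROIs per map): mean and SD of the session
#' difference, the 95 percent limits of agreement, and the regression of
#' difference on mean.
#'
#' @return data.frame with columns `map`, `units`, `mean_diff`, `sd_diff`,
#'   `loa_upper`, `loa_lower`, `slope`, `intercept`, `r`, `p_value`.
#' @export
rescan_reference_table <- function() {
  utils::read.csv(system.file("extdata", "rescan_reference_values.csv",
                              package = "multiqmap", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# Plausible CSF parameter values (long relaxation, free water); the
# reference table covers tissue ROIs only.
csf_truth_defaults <- function() {
  c(T1 = 4000, T2 = 1800, T2star = 300, QSM = 0, WF = 100, MTVF = 0,
    MD = 30, FA = 0.02, MTR = 0, ihMTR = 0)
}

# Ellipsoid definitions in normalized [-1, 1] head coordinates:
# centre (cx >= 0 half for bilateral structures), semi-axes.
phantom_geometry <- function() {
  list(
    brain = list(c = c(0, 0, 0), r = c(0.90, 0.95, 0.85)),
    ventricle = list(c = c(0.14, 0.10, 0.10), r = c(0.075, 0.26, 0.11)),
    corpus_callosum = list(c = c(0, 0.02, 0.30), r = c(0.34, 0.16, 0.11)),
    caudate = list(c = c(0.25, 0.20, 0.16), r = c(0.10, 0.20, 0.12)),
    putamen = list(c = c(0.38, 0.10, 0.02), r = c(0.10, 0.17, 0.13)),
    pallidum = list(c = c(0.22, 0.04, -0.04), r = c(0.09, 0.11, 0.10)),
    thalamus = list(c = c(0.16, -0.18, 0.06), r = c(0.13, 0.15, 0.12)),
    ventral_dc = list(c = c(0.15, -0.14, -0.22), r = c(0.11, 0.13, 0.11)),
    accumbens = list(c = c(0.14, 0.34, -0.14), r = c(0.10, 0.10, 0.09)),
    amygdala = list(c = c(0.38, 0.28, -0.28), r = c(0.11, 0.11, 0.10)),
    hippocampus = list(c = c(0.38, -0.24, -0.24), r = c(0.10, 0.17, 0.10)),
    insula = list(c = c(0.56, 0.10, 0.00), r = c(0.09, 0.21, 0.17)))
}

#' Build a bilateral labeled brain phantom
#'
#' Procedurally places the twelve study ROIs and CSF inside a brain-shaped
#' mask on a 3D grid: deep structures are ellipsoids deformed by a smooth
#' random field, white matter fills the interior, the cortex is an outer
#' shell, and CSF comprises the ventricles plus a subarachnoid rim. With
#' `asymmetry = 0` the deformation field is mirror-symmetrized so labels
#' are exactly symmetric about the mid-sagittal plane (corpus callosum and
#' CSF cross the midline). Deterministic given `seed`.
#'
#' @param grid Grid dimension, each at least 32.
#' @param asymmetry Non-negative amplitude of the symmetry-breaking
#'   deformation component (0 = perfectly mirrored anatomy).
#' @param seed Integer seed.
#' @param voxel_mm Voxel size in mm.
#' @return An object of class `phantom_labels`: list with `labels` (3D
#'   integer), `brain_mask`, `voxel_mm`, `grid`, `seed`.
#' @export
build_phantom <- function(grid = c(64, 64, 64), asymmetry = 0, seed = 1,
                          voxel_mm = c(3, 3, 3)) {
  if (any(grid < 32)) stop("grid must be at least 32 voxels per axis", call. = FALSE)
  stopifnot(asymmetry >= 0)
  u <- lapply(1:3, function(a) (seq_len(grid[a]) - (grid[a] + 1) / 2) / (grid[a] / 2))
  X <- kaxis(u[[1]], grid, 1); Y <- kaxis(u[[2]], grid, 2)
  Z <- kaxis(u[[3]], grid, 3)

  s_sym <- smooth_field(grid, corr_len = max(grid) / 5,
                        seed = child_seed(seed, 101))
  s_sym <- (s_sym + mirror_x(s_sym)) / 2
  s_asym <- smooth_field(grid, corr_len = max(grid) / 5,
                         seed = child_seed(seed, 102))
  deform <- 0.08 * s_sym + asymmetry * s_asym

  geom <- phantom_geometry()
  qfun <- function(g, mirror = FALSE) {
    cx <- if (mirror) -g$c[1] else g$c[1]
    ((X - cx) / g$r[1])^2 + ((Y - g$c[2]) / g$r[2])^2 +
      ((Z - g$c[3]) / g$r[3])^2
  }
  blob <- function(g, bilateral) {
    m <- (qfun(g) + deform) < 1
    if (bilateral) m <- m | ((qfun(g, mirror = TRUE) + deform) < 1)
    m
  }

  qb <- qfun(geom$brain)
  brain <- qb < 1
  labels <- array(0L, grid)
  labels[brain & qb <= 0.70] <- 1L                 # white matter interior
  labels[brain & qb > 0.70 & qb <= 0.88] <- 12L    # cortical shell
  labels[brain & qb > 0.88] <- 13L                 # subarachnoid CSF rim
  labels[blob(geom$ventricle, bilateral = TRUE)] <- 13L
  labels[blob(geom$corpus_callosum, bilateral = FALSE) & brain] <- 5L
  ids <- c(caudate = 2L, putamen = 3L, pallidum = 4L, thalamus = 6L,
           ventral_dc = 7L, accumbens = 8L, amygdala = 9L,
           hippocampus = 10L, insula = 11L)
  for (nm in names(ids)) {
    labels[blob(geom[[nm]], bilateral = TRUE) & brain] <- ids[[nm]]
  }
  labels[!brain] <- 0L

  counts <- tabulate(labels, nbins = 13)
  if (any(counts == 0)) {
    stop("grid too small to place all ROIs (empty: ",
         paste(roi_labels()$name[counts == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(labels = labels, brain_mask = labels > 0,
                 voxel_mm = voxel_mm, grid = grid, seed = seed,
                 asymmetry = asymmetry),
            class = "phantom_labels")
}

#' Draw a subject's ground-truth parameter volumes
#'
#' For every map type and ROI, draws a subject-level mean from
#' Normal(mean, sd_inter) and adds a smooth zero-mean spatial field scaled
#' so the within-ROI SD equals sd_intra (both from the reference table).
#' The spatial fields are mirror-symmetrized, so left/right ROI truth means
#' are equal by construction. Values are clipped to their physical ranges
#' (positive relaxation times, WF in [0, 100] percent, FA in [0, 1]).
#' Smooth multiplicative transmit (B1+) and receive bias fields and
#' per-ROI diffusion principal axes are drawn alongside.
#'
#' @param phantom A `phantom_labels` from [build_phantom()].
#' @param table Reference table in the layout of [roi_reference_table()].
#' @param subject_seed Integer seed for this subject.
#' @param session Session index (metadata).
#' @param b1_amplitude,bias_amplitude Relative SD of the B1+ and receive
#'   bias fields.
#' @return An object of class `phantom_subject`: list with `labels`,
#'   `brain_mask`, `truth` (named list of 3D arrays, one per map type),
#'   `b1_plus`, `receive_bias`, `dti_axes` (13 x 3), `voxel_mm`, seeds.
#' @export
sample_subject <- function(phantom, table = roi_reference_table(),
                           subject_seed = 1, session = 1L,
                           b1_amplitude = 0.06, bias_amplitude = 0.04) {
  stopifnot(inherits(phantom, "phantom_labels"))
  labels <- phantom$labels
  grid <- dim(labels)
  rois <- roi_labels()
  tissue_ids <- 1:12
  for (mt in MAP_TYPES[MAP_TYPES != "B1"]) {
    have <- table$roi[table$map == mt]
    missing <- setdiff(rois$name[tissue_ids], have)
    if (length(missing) > 0) {
      stop("reference table lacks (", mt, ", ",
           paste(missing, collapse = ", "), ")", call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(subject_seed, 201))

  csf <- csf_truth_defaults()
  truth <- list()
  map_i <- 0
  for (mt in names(csf)) {
    map_i <- map_i + 1
    vol <- array(0, grid)
    fld <- smooth_field(grid, corr_len = 12,
                        seed = child_seed(subject_seed, 300 + map_i))
    fld <- (fld + mirror_x(fld)) / 2
    for (id in tissue_ids) {
      row <- table[table$map == mt & table$roi == rois$name[id], ]
      mu <- stats::rnorm(1, row$mean, row$sd_inter)
      vox <- labels == id
      f <- fld[vox] - mean(fld[vox])
      sf <- stats::sd(f)
      if (is.na(sf) || sf == 0) f <- 0 else f <- f * row$sd_intra / sf
      vol[vox] <- mu + f
    }
    if (mt == "MTVF") {
      # MTVF and WF are one degree of freedom (MTVF = 100 - WF); deriving
      # MTVF from the drawn WF keeps the subject's truth self-consistent.
      vol <- (100 - truth$WF) * (labels > 0)
      truth[[mt]] <- vol
      next
    }
    vol[labels == 13L] <- csf[[mt]]
    # physical clipping
    vol <- switch(mt,
                  T1 = , T2 = , T2star = pmax(vol, 1) * (labels > 0),
                  WF = pmin(pmax(vol, 0), 100) * (labels > 0),
                  MTVF = pmin(pmax(vol, 0), 100) * (labels > 0),
                  FA = pmin(pmax(vol, 0), 0.99) * (labels > 0),
                  MD = pmax(vol, 0.1) * (labels > 0),
                  MTR = , ihMTR = pmax(vol, 0) * (labels > 0),
                  vol * (labels > 0))
    truth[[mt]] <- vol
  }
  # Hardware fields vary on the scale of the whole head (RF wavelength and
  # coil geometry), much more slowly than the 12-voxel biological texture.
  b1 <- 1 + b1_amplitude *
    smooth_field(grid, corr_len = max(grid),
                 seed = child_seed(subject_seed, 401))
  rb <- 1 + bias_amplitude *
    smooth_field(grid, corr_len = max(grid),
                 seed = child_seed(subject_seed, 402))
  b1 <- pmax(b1, 0.5); rb <- pmax(rb, 0.5)
  axes <- matrix(stats::rnorm(13 * 3), 13, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  structure(list(labels = labels, brain_mask = phantom$brain_mask,
                 truth = truth, b1_plus = b1, receive_bias = rb,
                 dti_axes = axes, voxel_mm = phantom$voxel_mm,
                 seed = phantom$seed, subject_seed = subject_seed,
                 session = as.integer(session)),
            class = "phantom_subject")
}
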