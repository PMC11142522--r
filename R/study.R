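#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file, reorients data and affine to the canonical RAS
#' convention, and returns the data array with its voxel sizes.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (array), `voxel_mm`, and `orientation`
#'   (always `"RAS"` after canonicalization).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  # files without any qform/sform cannot be reoriented; keep them as-is
  if (!identical(unname(RNifti::orientation(img)), "")) {
    RNifti::orientation(img) <- "RAS"
  }
  vox <- RNifti::pixdim(img)
  list(data = unclass(as.array(img)),
       voxel_mm = unname(vox[seq_len(min(3, length(vox)))]),
       orientation = "RAS")
}

#' Write a NIfTI volume
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path.
#' @param voxel_mm Voxel size in mm.
#' @return The path, invisibly.
#' @export
write_nifti <- function(data, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_mm
  aff <- diag(c(voxel_mm, 1))   # canonical RAS axes
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Fit all quantitative maps from one subject's simulated series
#'
#' Runs every fitting pipeline on the named series list produced by
#' [simulate_acquisitions()]: EPG dictionary T2, truncated log-linear T2*,
#' the full QSM chain, inversion-recovery T1 with B1+-corrected variable
#' flip angle T1 and WF/MTVF, the diffusion tensor scalars, and the ihMT
#' ratios. Segmentation is taken from the known phantom labels.
#'
#' @param series Named list of [image_series()] (keys as in the packaged
#'   protocol: MESE, MEGRE, IR-EPI, VFA-SPGR, DWI, ihMT).
#' @param labels 3D integer label volume (13 = CSF).
#' @param map_types Map types to fit (subset of the ten; default all).
#' @param dict Optional EPG dictionary (built from the MESE series
#'   defaults when absent).
#' @param qsm_args List of overrides passed to [qsm_pipeline()].
#' @return Named list of [quantitative_map()]s.
#' @export
fit_subject_maps <- function(series, labels,
                             map_types = c("T1", "T2", "T2star", "QSM", "WF",
                                           "MTVF", "MD", "FA", "MTR", "ihMTR"),
                             dict = NULL, qsm_args = list()) {
  maps <- list()
  brain <- labels > 0
  csf <- labels == 13L
  if ("T2" %in% map_types) {
    sq <- series$MESE
    if (is.null(dict)) {
      esp <- if (dim(sq$data)[4] > 1) diff(sq$axis_values)[1] else sq$axis_values
      dict <- build_emc_dictionary(esp_ms = esp, n_echoes = dim(sq$data)[4])
    }
    maps$T2 <- fit_t2_emc(denoise_hook(sq), dict)$t2
  }
  if ("T2star" %in% map_types) {
    mag <- series$MEGRE
    if (is.complex(mag$data)) {
      mag <- image_series(Mod(mag$data), "te_ms", mag$axis_values,
                          mag$voxel_mm, tr_ms = mag$tr_ms)
    }
    maps$T2star <- fit_t2star_loglinear(mag)
  }
  if ("QSM" %in% map_types) {
    qp <- do.call(qsm_pipeline,
                  c(list(series = series$MEGRE, mask = brain, csf_mask = csf),
                    qsm_args))
    maps$QSM <- qp$chi
  }
  if (any(c("T1", "WF", "MTVF") %in% map_types)) {
    ir <- fit_ir_t1(series$`IR-EPI`)
    b1 <- estimate_b1_from_ir(series$`VFA-SPGR`, ir$t1, mask = brain)
    vfa <- fit_t1_vfa(series$`VFA-SPGR`, b1$b1)
    if ("T1" %in% map_types) maps$T1 <- vfa$t1
    if (any(c("WF", "MTVF") %in% map_types)) {
      wm <- compute_wf_mtvf(vfa$m0, csf, brain)
      if ("WF" %in% map_types) maps$WF <- wm$wf
      if ("MTVF" %in% map_types) maps$MTVF <- wm$mtvf
    }
  }
  if (any(c("MD", "FA") %in% map_types)) {
    tf <- fit_dti_loglinear(series$DWI)
    tm <- tensor_metrics(tf)
    if ("MD" %in% map_types) maps$MD <- tm$md
    if ("FA" %in% map_types) maps$FA <- tm$fa
  }
  if (any(c("MTR", "ihMTR") %in% map_types)) {
    mt <- compute_mtr_ihmtr(ihmt_set_from_series(series$ihMT))
    if ("MTR" %in% map_types) maps$MTR <- mt$mtr
    if ("ihMTR" %in% map_types) maps$ihMTR <- mt$ihmtr
  }
  maps[intersect(map_types, names(maps))]
}

#' Simulate and analyze a full synthetic study
#'
#' End-to-end orchestration: builds a phantom cohort, simulates every
#' sequence per subject (plus repeat sessions for the first `n_rescans`
#' subjects), fits the requested quantitative maps, and runs the three
#' study-level analyses - the cohort variability table, the right/left
#' hemispheric regression (corpus callosum excluded), and the per-map
#' Bland-Altman scan-rescan comparison. Fully reproducible from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param n_rescans Number of subjects with a second session.
#' @param snr Simulated signal-to-noise ratio.
#' @param seed Master seed.
#' @param grid Phantom grid dimension.
#' @param protocol A `sequence_protocol`.
#' @param map_types Map types to fit.
#' @param asymmetry Phantom asymmetry amplitude.
#' @param out_dir Optional output directory: maps are written as NIfTI,
#'   tables as CSV, plus a YAML manifest and a text log.
#' @param qsm_args Solver overrides for the QSM chain.
#' @param verbose Print progress.
#' @return List with `variability` (cohort table), `hemispheres` (per-map
#'   regression rows), `bland_altman` (per-map rows), `summaries`
#'   (per-subject ROI table), and `manifest`.
#' @export
run_study <- function(n_subjects = 2, n_rescans = 0, snr = 50, seed = 1,
                      grid = c(48, 48, 48), protocol = default_protocol(),
                      map_types = c("T1", "T2", "T2star", "QSM", "WF", "MTVF",
                                    "MD", "FA", "MTR", "ihMTR"),
                      asymmetry = 0, out_dir = NULL,
                      qsm_args = list(pdf_maxit = 60, tik_maxit = 150),
                      verbose = FALSE) {
  stopifnot(n_rescans <= n_subjects)
  log_lines <- c(sprintf("multiqmap %s study: %d subjects, %d rescans, snr=%s, seed=%d",
                         as.character(utils::packageVersion("multiqmap")),
                         n_subjects, n_rescans, format(snr), seed),
                 sprintf("grid=%s, maps=%s", paste(grid, collapse = "x"),
                         paste(map_types, collapse = ",")))
  dict <- NULL
  mese <- Filter(function(s) s$kind == "mese", protocol$sequences)
  if ("T2" %in% map_types && length(mese) > 0) {
    sq <- mese[[1]]
    esp <- if (length(sq$te_ms) > 1) diff(sq$te_ms)[1] else sq$te_ms
    dict <- build_emc_dictionary(esp_ms = esp, n_echoes = length(sq$te_ms),
                                 refocus_deg = sq$refocus_deg)
  }

  summaries <- list()
  hemi_rows <- list()
  files <- list()
  rois <- roi_labels()
  for (s in seq_len(n_subjects)) {
    if (verbose) message("subject ", s)
    phantom <- build_phantom(grid, asymmetry = asymmetry,
                             seed = child_seed(seed, 1000 + s))
    subject <- sample_subject(phantom,
                              subject_seed = child_seed(seed, 2000 + s))
    sessions <- if (s <= n_rescans) 1:2 else 1
    for (sess in sessions) {
      series <- if (sess == 1) {
        simulate_acquisitions(subject, protocol, snr = snr,
                              noise_seed = child_seed(seed, 3000 + s))
      } else {
        simulate_rescan(subject, protocol, snr = snr,
                        rescan_seed = child_seed(seed, 4000 + s))
      }
      maps <- fit_subject_maps(series, subject$labels, map_types = map_types,
                               dict = dict, qsm_args = qsm_args)
      summaries[[length(summaries) + 1]] <-
        subject_roi_summary(maps, subject$labels, subject = s, session = sess)
      if (sess == 1) {
        for (mt in names(maps)) {
          for (id in setdiff(1:12, 5L)) {  # corpus callosum has no L/R split
            hm <- hemisphere_means(maps[[mt]], subject$labels, id)
            hemi_rows[[length(hemi_rows) + 1]] <- data.frame(
              subject = s, map = mt, roi = rois$name[id],
              left = hm$left, right = hm$right, stringsAsFactors = FALSE)
          }
        }
      }
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sprintf("sub-%02d_ses-%d", s, sess))
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        write_nifti(subject$labels, file.path(sdir, "labels.nii.gz"),
                    subject$voxel_mm)
        for (mt in names(maps)) {
          p <- file.path(sdir, paste0(mt, ".nii.gz"))
          dat <- maps[[mt]]$data
          dat[!is.finite(dat)] <- 0
          write_nifti(dat, p, subject$voxel_mm)
          writeLines(c(paste0("map: ", mt),
                       paste0("units: ", maps[[mt]]$units)),
                     file.path(sdir, paste0(mt, "_units.txt")))
          files[[paste(s, sess, mt, sep = "_")]] <- p
        }
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  ses1 <- summaries[summaries$session == 1, ]
  variability <- summarize_cohort(ses1)
  hemi <- do.call(rbind, hemi_rows)
  hemispheres <- do.call(rbind, lapply(split(hemi, hemi$map), function(g) {
    lr <- lr_regression(g$left, g$right)
    data.frame(map = g$map[1], slope = lr$slope, intercept = lr$intercept,
               r = lr$r, p_value = lr$p_value, n = lr$n,
               stringsAsFactors = FALSE)
  }))
  bland <- NULL
  if (n_rescans >= 2) {
    ses2 <- summaries[summaries$session == 2, ]
    key <- function(d) paste(d$subject, d$map, d$roi)
    ses1r <- ses1[ses1$subject <= n_rescans, ]
    ses2 <- ses2[match(key(ses1r), key(ses2)), ]
    bland <- do.call(rbind, lapply(split(seq_len(nrow(ses1r)), ses1r$map),
                                   function(ii) {
      ba <- bland_altman(ses1r$mean[ii], ses2$mean[ii])
      data.frame(map = ses1r$map[ii][1], mean_diff = ba$mean_diff,
                 sd_diff = ba$sd_diff, loa_upper = ba$loa_upper,
                 loa_lower = ba$loa_lower, slope = ba$slope,
                 intercept = ba$intercept, r = ba$r, p_value = ba$p_value,
                 n_pairs = ba$n_pairs, stringsAsFactors = FALSE)
    }))
  }
  manifest <- list(subjects = seq_len(n_subjects), n_rescans = n_rescans,
                   seed = seed, snr = snr, grid = grid,
                   map_types = map_types,
                   version = as.character(utils::packageVersion("multiqmap")),
                   files = lapply(files, identity))
  if (!is.null(out_dir)) {
    utils::write.csv(variability, file.path(out_dir, "variability.csv"),
                     row.names = FALSE)
    utils::write.csv(hemispheres, file.path(out_dir, "hemispheres.csv"),
                     row.names = FALSE)
    if (!is.null(bland)) {
      utils::write.csv(bland, file.path(out_dir, "bland_altman.csv"),
                       row.names = FALSE)
    }
    write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
    writeLines(c(log_lines, sprintf("completed: %s", format(Sys.time()))),
               file.path(out_dir, "study.log"))
  }
  list(variability = variability, hemispheres = hemispheres,
       bland_altman = bland, summaries = summaries, hemi_means = hemi,
       manifest = manifest)
}

#' Study manifest round-trip
#'
#' The manifest records subject and session identifiers, seeds, file
#' paths, and the package version of a study run; it round-trips
#' losslessly through YAML. [read_manifest()] optionally validates that
#' every referenced file exists.
#'
#' @param manifest Named list as produced by [run_study()].
#' @param path YAML file path.
#' @param validate_files Error if a referenced file is missing.
#' @return [read_manifest()] returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, validate_files = FALSE) {
  m <- yaml::read_yaml(path)
  if (validate_files && length(m$files) > 0) {
    missing <- Filter(function(p) !file.exists(p), unlist(m$files))
    if (length(missing) > 0) {
      stop("manifest references missing file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  m
}
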