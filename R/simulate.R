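# Proton-density volume implied by the WF truth (CSF = 1 by construction).
subject_pd <- function(subject) subject$truth$WF / 100

# Subject-level background susceptibility outside the head (air cavities,
# shim imperfections): smooth sources supported outside the brain mask,
# reproducible from the subject seed. Used by the gradient-echo simulator
# and exercised by background-field removal.
background_chi <- function(subject, amplitude_ppm = 2) {
  grid <- dim(subject$labels)
  f <- smooth_field(grid, corr_len = max(grid) / 4,
                    seed = child_seed(subject$subject_seed, 403))
  f[subject$brain_mask] <- 0
  amplitude_ppm * f
}

#' Simulate the raw image series of every protocol sequence
#'
#' Applies each sequence's forward signal model to a phantom subject's
#' ground-truth volumes: the EPG echo train for multi-echo spin-echo (with
#' the local transmit field), the spoiled-GRE steady state for variable
#' flip angle, the three-parameter inversion-recovery model, a complex
#' multi-echo gradient echo whose phase evolves with the field obtained by
#' dipole-convolving the susceptibility truth, the monoexponential tensor
#' model for diffusion, and a ratio-consistent five-image ihMT set. Noise
#' is added as independent complex Gaussian with sigma = mean tissue signal
#' / snr before the magnitude operation, yielding Rician magnitude
#' statistics; `snr = Inf` gives noiseless data.
#'
#' @param subject A `phantom_subject` from [sample_subject()].
#' @param protocol A `sequence_protocol`; defaults to the packaged one.
#' @param snr Signal-to-noise ratio (> 0, possibly `Inf`).
#' @param noise_seed Integer seed for the noise streams.
#' @param b0_dir Main-field direction for the gradient-echo phase.
#' @param field_strength_T Main field in Tesla.
#' @return Named list of [image_series()], keyed by sequence name.
#' @export
simulate_acquisitions <- function(subject, protocol = default_protocol(),
                                  snr = Inf, noise_seed = 1,
                                  b0_dir = c(0, 0, 1), field_strength_T = 3) {
  stopifnot(inherits(subject, "phantom_subject"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive", call. = FALSE)
  grid <- dim(subject$labels)
  pd <- subject_pd(subject)
  rb <- subject$receive_bias
  amp <- rb * pd
  brain <- subject$brain_mask
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  add_noise <- function(data, seq_name, complex_out = FALSE) {
    if (!is.finite(snr)) {
      return(data)
    }
    sigma <- mean(Mod(data[, , , 1])[brain]) / snr
    set.seed(child_seed(noise_seed, sum(utf8ToInt(seq_name))))
    nre <- array(stats::rnorm(length(data), 0, sigma), dim(data))
    nim <- array(stats::rnorm(length(data), 0, sigma), dim(data))
    noisy <- data + nre + 1i * nim
    if (complex_out) noisy else Mod(noisy)
  }

  out <- list()
  for (sq in protocol$sequences) {
    series <- switch(
      sq$kind,
      anatomical = {
        dat <- array(amp, c(grid, 1))
        image_series(add_noise(dat, sq$name), "te_ms", sq$te_ms[1],
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      mese = {
        esp <- if (length(sq$te_ms) > 1) diff(sq$te_ms)[1] else sq$te_ms
        ne <- length(sq$te_ms)
        idx <- which(brain)
        curves <- epg_mese_curves(subject$truth$T2[idx],
                                  subject$truth$T1[idx],
                                  subject$b1_plus[idx],
                                  esp, ne, sq$refocus_deg)
        dat <- array(0, c(grid, ne))
        for (e in seq_len(ne)) {
          vol <- array(0, grid)
          vol[idx] <- curves[e, ] * amp[idx]
          dat[, , , e] <- vol
        }
        image_series(add_noise(dat, sq$name), "te_ms", sq$te_ms,
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      megre = {
        chi <- subject$truth$QSM + background_chi(subject)
        f_hz <- dipole_convolve(chi, subject$voxel_mm, b0_dir) *
          GAMMA_MHZ_PER_T * field_strength_T
        dat <- array(0i, c(grid, length(sq$te_ms)))
        for (e in seq_along(sq$te_ms)) {
          te <- sq$te_ms[e]
          mag <- amp * exp(-te / pmax(subject$truth$T2star, 1e-6)) * brain
          dat[, , , e] <- mag * exp(1i * 2 * pi * f_hz * te / 1000)
        }
        image_series(add_noise(dat, sq$name, complex_out = TRUE), "te_ms",
                     sq$te_ms, sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      irepi = {
        dat <- array(0, c(grid, length(sq$ti_ms)))
        for (k in seq_along(sq$ti_ms)) {
          s <- amp * (1 - 2 * exp(-sq$ti_ms[k] / pmax(subject$truth$T1, 1e-6)))
          dat[, , , k] <- abs(s) * brain
        }
        image_series(add_noise(dat, sq$name), "ti_ms", sq$ti_ms,
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      vfa = {
        E1 <- exp(-sq$tr_ms / pmax(subject$truth$T1, 1e-6))
        dat <- array(0, c(grid, length(sq$flip_deg)))
        for (k in seq_along(sq$flip_deg)) {
          a <- subject$b1_plus * sq$flip_deg[k] * pi / 180
          dat[, , , k] <- amp * spgr_shape(a, E1) * brain
        }
        image_series(add_noise(dat, sq$name), "flip_deg", sq$flip_deg,
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      dwi = {
        scheme <- if (is.null(sq$n_directions) || sq$n_directions >= 64) {
          default_gradient_scheme()
        } else {
          revpe_gradient_scheme()
        }
        md_mm <- subject$truth$MD * 1e-4
        fa <- subject$truth$FA
        delta <- fa * md_mm * sqrt(3 / (9 - 6 * pmin(fa, 0.99)^2))
        nmeas <- length(scheme$bvalues_s_mm2)
        dat <- array(0, c(grid, nmeas))
        lab <- subject$labels
        lab1 <- pmax(lab, 1L)
        for (k in seq_len(nmeas)) {
          b <- scheme$bvalues_s_mm2[k]
          if (b == 0) {
            dat[, , , k] <- amp * brain
          } else {
            g <- scheme$directions[k, ]
            dotl <- as.vector(subject$dti_axes %*% g)
            dot2 <- array(dotl[lab1]^2, grid)
            adc <- (md_mm - delta) + 3 * delta * dot2
            dat[, , , k] <- amp * exp(-b * adc) * brain
          }
        }
        image_series(add_noise(dat, sq$name), "diffusion",
                     list(bvalues = scheme$bvalues_s_mm2,
                          directions = scheme$directions),
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      },
      ihmt = {
        s0 <- amp * brain
        mtr <- subject$truth$MTR / 100
        ih <- subject$truth$ihMTR / 100
        dat <- array(0, c(grid, 5))
        dat[, , , 1] <- s0
        dat[, , , 2] <- s0 * (1 - mtr)
        dat[, , , 3] <- s0 * (1 - mtr)
        dat[, , , 4] <- s0 * pmax(1 - mtr - ih / 2, 0)
        dat[, , , 5] <- s0 * pmax(1 - mtr - ih / 2, 0)
        image_series(add_noise(dat, sq$name), "mt_condition",
                     c("S0", "S+", "S-", "S+-", "S-+"),
                     sq$voxel_mm, tr_ms = sq$tr_ms)
      })
    out[[sq$name]] <- series
  }
  out
}

#' Simulate a repeat scan session
#'
#' Re-runs the forward models on the identical ground truth with an
#' independent noise realization; optionally the bias fields drift by a
#' small smooth multiplicative factor between sessions (off by default).
#'
#' @inheritParams simulate_acquisitions
#' @param rescan_seed Seed of the second session's noise streams.
#' @param drift_sd Relative SD of the optional session-to-session bias
#'   field drift.
#' @return Named list of [image_series()], as [simulate_acquisitions()].
#' @export
simulate_rescan <- function(subject, protocol = default_protocol(), snr = Inf,
                            rescan_seed = 2, drift_sd = 0,
                            b0_dir = c(0, 0, 1), field_strength_T = 3) {
  if (drift_sd > 0) {
    grid <- dim(subject$labels)
    drift <- 1 + drift_sd *
      smooth_field(grid, corr_len = max(grid) / 2,
                   seed = child_seed(rescan_seed, 501))
    subject$receive_bias <- subject$receive_bias * pmax(drift, 0.5)
  }
  subject$session <- subject$session + 1L
  simulate_acquisitions(subject, protocol, snr = snr,
                        noise_seed = rescan_seed, b0_dir = b0_dir,
                        field_strength_T = field_strength_T)
}
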