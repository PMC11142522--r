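#' Extended-phase-graph echo amplitudes for a multi-echo spin-echo train
#'
#' Computes the echo modulation curve of a CPMG-style MESE acquisition by
#' the extended-phase-graph (EPG) recursion with ideal crushers and
#' instantaneous pulses. The excitation is a 90 degree pulse scaled by the
#' local transmit field `b1`; every refocusing pulse is `refocus_deg * b1`.
#' Under imperfect refocusing (below 180 degrees) part of the magnetization
#' is stored longitudinally between pulses, producing the characteristic
#' deviation of the echo train from pure exponential decay that the
#' dictionary fit exploits.
#'
#' @param t2_ms,t1_ms Relaxation times in ms (positive).
#' @param b1 Transmit field scale (1 = nominal).
#' @param esp_ms Echo spacing in ms.
#' @param n_echoes Number of echoes.
#' @param refocus_deg Nominal refocusing flip angle in degrees.
#' @return Numeric vector of `n_echoes` echo amplitudes (unit equilibrium
#'   magnetization).
#' @examples
#' # At b1 = 1 and 180 degree refocusing the train is mono-exponential:
#' epg_mese_curve(80, 1000, 1, 12, 6, 180)
#' exp(-(1:6) * 12 / 80)
#' @export
epg_mese_curve <- function(t2_ms, t1_ms, b1, esp_ms, n_echoes, refocus_deg) {
  drop(epg_mese_curves(t2_ms, t1_ms, b1, esp_ms, n_echoes, refocus_deg))
}

# Vectorised EPG over parameter atoms: t2_ms, t1_ms, b1 are equal-length
# vectors; returns an n_echoes x n_atoms matrix of echo amplitudes.
epg_mese_curves <- function(t2_ms, t1_ms, b1, esp_ms, n_echoes, refocus_deg) {
  n <- max(length(t2_ms), length(t1_ms), length(b1))
  t2 <- rep_len(t2_ms, n); t1 <- rep_len(t1_ms, n); b1 <- rep_len(b1, n)
  if (any(t2 <= 0) || any(t1 <= 0)) stop("t2_ms and t1_ms must be positive")
  stopifnot(esp_ms > 0, n_echoes >= 1)
  K1 <- n_echoes + 1L              # state orders 0..n_echoes
  bc <- function(v) matrix(v, K1, n, byrow = TRUE)

  E2h <- bc(exp(-esp_ms / 2 / t2))
  E1h <- bc(exp(-esp_ms / 2 / t1))
  regrow <- 1 - exp(-esp_ms / 2 / t1)

  # Pulse transition entries for angle a (per atom) and phase p (scalar).
  pulse <- function(Fp, Fm, Z, a, p) {
    co2 <- cos(a / 2)^2; si2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
    T11 <- bc(co2); T12 <- bc(exp(2i * p) * si2); T13 <- bc(-1i * exp(1i * p) * sa)
    T21 <- bc(exp(-2i * p) * si2); T22 <- bc(co2); T23 <- bc(1i * exp(-1i * p) * sa)
    T31 <- bc(-0.5i * exp(-1i * p) * sa); T32 <- bc(0.5i * exp(1i * p) * sa)
    T33 <- bc(ca)
    list(Fp = T11 * Fp + T12 * Fm + T13 * Z,
         Fm = T21 * Fp + T22 * Fm + T23 * Z,
         Z  = T31 * Fp + T32 * Fm + T33 * Z)
  }
  # Ideal-crusher dephasing by one gradient unit.
  shift <- function(Fp, Fm) {
    Fp_new <- rbind(Conj(Fm[2, , drop = FALSE]), Fp[-K1, , drop = FALSE])
    Fm_new <- rbind(Fm[-1, , drop = FALSE], matrix(0i, 1, n))
    list(Fp = Fp_new, Fm = Fm_new)
  }
  relax <- function(Fp, Fm, Z) {
    Fp <- Fp * E2h; Fm <- Fm * E2h; Z <- Z * E1h
    Z[1, ] <- Z[1, ] + regrow
    list(Fp = Fp, Fm = Fm, Z = Z)
  }

  Fp <- matrix(0i, K1, n); Fm <- matrix(0i, K1, n); Z <- matrix(0i, K1, n)
  Z[1, ] <- 1
  st <- pulse(Fp, Fm, Z, b1 * pi / 2, pi / 2)            # excitation about y
  Fp <- st$Fp; Fm <- st$Fm; Z <- st$Z

  aref <- b1 * refocus_deg * pi / 180
  echoes <- matrix(0, n_echoes, n)
  for (e in seq_len(n_echoes)) {
    st <- relax(Fp, Fm, Z); Fp <- st$Fp; Fm <- st$Fm; Z <- st$Z
    sh <- shift(Fp, Fm); Fp <- sh$Fp; Fm <- sh$Fm
    st <- pulse(Fp, Fm, Z, aref, 0)                      # refocusing about x
    Fp <- st$Fp; Fm <- st$Fm; Z <- st$Z
    sh <- shift(Fp, Fm); Fp <- sh$Fp; Fm <- sh$Fm
    st <- relax(Fp, Fm, Z); Fp <- st$Fp; Fm <- st$Fm; Z <- st$Z
    echoes[e, ] <- Mod(Fp[1, ])
  }
  echoes
}

#' Build an echo-modulation-curve dictionary for T2 fitting
#'
#' Simulates EPG echo trains over a (T2, B1) grid at a fixed assumed T1 and
#' normalizes each curve to unit l2 norm. The default grid spans T2 from 1
#' to 300 ms (logarithmic, 200 points) and B1 from 0.7 to 1.3 in steps of
#' 0.02; T1 is fixed at 1000 ms, reflecting the weak T1 sensitivity of the
#' echo train at typical echo spacings.
#'
#' @param esp_ms Echo spacing in ms.
#' @param n_echoes Number of echoes.
#' @param refocus_deg Nominal refocusing angle in degrees.
#' @param t2_grid_ms Increasing vector of candidate T2 values in ms.
#' @param b1_grid Increasing vector of candidate B1 scales.
#' @param t1_ms Fixed T1 assumption in ms.
#' @return An `epg_dictionary`: list with the grids, the acquisition
#'   settings, `curves` (n_echoes x n_atoms, unit l2 columns) and the per
#'   atom `t2` / `b1` lookups.
#' @export
build_emc_dictionary <- function(esp_ms = 12, n_echoes = 12, refocus_deg = 160,
                                 t2_grid_ms = exp(seq(log(1), log(300),
                                                      length.out = 200)),
                                 b1_grid = seq(0.7, 1.3, by = 0.02),
                                 t1_ms = 1000) {
  g <- expand.grid(t2 = t2_grid_ms, b1 = b1_grid)
  curves <- epg_mese_curves(g$t2, t1_ms, g$b1, esp_ms, n_echoes, refocus_deg)
  nrm <- sqrt(colSums(curves^2))
  curves <- sweep(curves, 2, pmax(nrm, .Machine$double.eps), "/")
  structure(list(t2_grid_ms = t2_grid_ms, b1_grid = b1_grid, t1_ms = t1_ms,
                 esp_ms = esp_ms, n_echoes = n_echoes,
                 refocus_deg = refocus_deg, curves = curves,
                 atom_t2 = g$t2, atom_b1 = g$b1),
            class = "epg_dictionary")
}

#' Dictionary T2 fitting of multi-echo spin-echo data
#'
#' Matches every voxel's echo vector against the EPG dictionary by
#' maximizing the normalized inner product (both sides unit l2), returning
#' the T2 and B1 of the best-matching grid point. All-zero voxels are
#' marked invalid.
#'
#' @param series An [image_series()] with `axis_kind = "te_ms"` whose echo
#'   count matches the dictionary.
#' @param dict An `epg_dictionary` from [build_emc_dictionary()].
#' @param chunk_voxels Number of voxels scored per block (memory control).
#' @return List with `t2` and `b1` [quantitative_map()]s.
#' @export
fit_t2_emc <- function(series, dict, chunk_voxels = 4096) {
  stopifnot(inherits(series, "image_series"), inherits(dict, "epg_dictionary"))
  if (dim(series$data)[4] != dict$n_echoes) {
    stop("series echo count (", dim(series$data)[4],
         ") does not match dictionary n_echoes (", dict$n_echoes, ")")
  }
  V <- series_matrix(series)
  nvox <- nrow(V)
  nrm <- sqrt(rowSums(V^2))
  ok <- nrm > 0
  best <- integer(nvox)
  idx_ok <- which(ok)
  for (start in seq_len(ceiling(length(idx_ok) / chunk_voxels)) * chunk_voxels -
         chunk_voxels + 1) {
    ii <- idx_ok[start:min(start + chunk_voxels - 1, length(idx_ok))]
    S <- (V[ii, , drop = FALSE] / nrm[ii]) %*% dict$curves
    best[ii] <- max.col(S, ties.method = "first")
  }
  d3 <- dim(series$data)[1:3]
  t2 <- b1 <- rep(NA_real_, nvox)
  t2[ok] <- dict$atom_t2[best[ok]]
  b1[ok] <- dict$atom_b1[best[ok]]
  list(t2 = quantitative_map(vec_to_vol(t2, d3), "T2"),
       b1 = quantitative_map(vec_to_vol(b1, d3), "B1"))
}

#' Truncated log-linear T2* fitting of multi-echo gradient-echo magnitude
#'
#' Per voxel, echoes whose magnitude falls below 10 percent of the first
#' echo are truncated (guarding against the Rician noise floor), and T2* is
#' minus the inverse slope of the ordinary least-squares regression of the
#' log magnitude on echo time. Voxels with fewer than two retained echoes,
#' a non-negative slope, or zero signal are invalid.
#'
#' @param series Magnitude [image_series()] with `axis_kind = "te_ms"` and
#'   at least 3 echoes.
#' @param truncate_frac Truncation threshold relative to the first echo.
#' @return A `T2star` [quantitative_map()] in ms.
#' @export
fit_t2star_loglinear <- function(series, truncate_frac = 0.1) {
  stopifnot(inherits(series, "image_series"),
            series$axis_kind == "te_ms", dim(series$data)[4] >= 3)
  te <- series$axis_values
  V <- series_matrix(series)
  W <- (V > 0) & (V >= truncate_frac * V[, 1])
  L <- matrix(0, nrow(V), ncol(V))
  L[W] <- log(V[W])
  Wn <- W * 1
  sw <- rowSums(Wn)
  sx <- Wn %*% te
  sxx <- Wn %*% te^2
  sy <- rowSums(L)
  sxy <- L %*% te
  denom <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / denom
  t2s <- -1 / slope
  bad <- sw < 2 | !is.finite(slope) | slope >= 0 | abs(denom) < .Machine$double.eps
  t2s[bad] <- NA_real_
  quantitative_map(vec_to_vol(as.vector(t2s), dim(series$data)[1:3]), "T2star")
}

#' Inversion-recovery T1 fitting (three-parameter signed model)
#'
#' Fits S(TI) = a + b exp(-TI / T1) per voxel. Magnitude data are polarity
#' restored first: samples acquired before the minimum-magnitude inversion
#' time are negated, and both polarities of the minimum sample are tried,
#' keeping the lower-residual fit. The T1 axis is searched on a logarithmic
#' grid refined by golden-section, with (a, b) solved in closed form at each
#' candidate.
#'
#' @param series Magnitude [image_series()] with `axis_kind = "ti_ms"` and
#'   at least 3 inversion times.
#' @param t1_grid_ms Candidate T1 grid (log-spaced by default, 50-5000 ms).
#' @param refine_iters Golden-section refinement iterations.
#' @return List with `t1`, `a` and `b` [quantitative_map()]s (`a`, `b` are
#'   returned as plain 3D arrays in the `a` and `b` elements).
#' @export
fit_ir_t1 <- function(series,
                      t1_grid_ms = exp(seq(log(50), log(5000), length.out = 120)),
                      refine_iters = 40) {
  stopifnot(inherits(series, "image_series"),
            series$axis_kind == "ti_ms", dim(series$data)[4] >= 3)
  ti <- series$axis_values
  m <- length(ti)
  V <- series_matrix(series)
  nvox <- nrow(V)
  d3 <- dim(series$data)[1:3]

  nonzero <- rowSums(abs(V)) > 0
  imin <- max.col(-abs(V), ties.method = "first")
  # Two polarity hypotheses: minimum sample kept positive / negated.
  signs1 <- outer(imin, seq_len(m), function(i, j) ifelse(j < i, -1, 1))
  signs2 <- outer(imin, seq_len(m), function(i, j) ifelse(j <= i, -1, 1))

  fit_hypothesis <- function(Y) {
    syy <- rowSums(Y^2)
    best_rss <- rep(Inf, nvox); best_t1 <- rep(NA_real_, nvox)
    best_i <- rep(1L, nvox)
    for (i in seq_along(t1_grid_ms)) {
      x <- exp(-ti / t1_grid_ms[i])
      sx <- sum(x); sxx <- sum(x^2)
      sy <- rowSums(Y); sxy <- Y %*% x
      den <- m * sxx - sx^2
      b <- (m * sxy - sx * sy) / den
      a <- (sy - b * sx) / m
      rss <- syy + a^2 * m + b^2 * sxx - 2 * a * sy - 2 * b * sxy + 2 * a * b * sx
      upd <- rss < best_rss
      best_rss[upd] <- rss[upd]; best_t1[upd] <- t1_grid_ms[i]; best_i[upd] <- i
    }
    lo <- t1_grid_ms[pmax(best_i - 1L, 1L)]
    hi <- t1_grid_ms[pmin(best_i + 1L, length(t1_grid_ms))]
    rss_at <- function(t1) {
      X <- exp(-outer(1 / t1, ti))   # rows: exp(-ti / t1)
      sx <- rowSums(X); sxx <- rowSums(X^2)
      sy <- rowSums(Y); sxy <- rowSums(Y * X)
      den <- m * sxx - sx^2
      b <- (m * sxy - sx * sy) / den
      a <- (sy - b * sx) / m
      syy + a^2 * m + b^2 * sxx - 2 * a * sy - 2 * b * sxy + 2 * a * b * sx
    }
    t1 <- golden_min(rss_at, lo, hi, iters = refine_iters)
    # Final closed-form (a, b) and residual at the refined T1.
    X <- exp(-outer(1 / t1, ti))
    sx <- rowSums(X); sxx <- rowSums(X^2)
    sy <- rowSums(Y); sxy <- rowSums(Y * X)
    den <- m * sxx - sx^2
    b <- (m * sxy - sx * sy) / den
    a <- (sy - b * sx) / m
    rss <- syy + a^2 * m + b^2 * sxx - 2 * a * sy - 2 * b * sxy + 2 * a * b * sx
    list(t1 = t1, a = a, b = b, rss = rss)
  }

  f1 <- fit_hypothesis(signs1 * V)
  f2 <- fit_hypothesis(signs2 * V)
  take2 <- f2$rss < f1$rss
  t1 <- ifelse(take2, f2$t1, f1$t1)
  a <- ifelse(take2, f2$a, f1$a)
  b <- ifelse(take2, f2$b, f1$b)

  scale <- apply(abs(V), 1, max)
  bad <- !nonzero | !is.finite(t1) | t1 <= 0 | abs(b) < 1e-6 * pmax(scale, .Machine$double.eps)
  t1[bad] <- NA_real_
  list(t1 = quantitative_map(vec_to_vol(t1, d3), "T1"),
       a = vec_to_vol(a, d3), b = vec_to_vol(b, d3))
}

# Spoiled gradient-echo steady-state signal shape for unit M0.
spgr_shape <- function(alpha_rad, E1) {
  sin(alpha_rad) * (1 - E1) / (1 - cos(alpha_rad) * E1)
}

#' Transmit field (B1+) estimation from variable-flip-angle data
#'
#' Per voxel, finds the flip-angle scale c minimizing the residual of the
#' spoiled-GRE signal model S(alpha) = M0 sin(c alpha)(1 - E1) /
#' (1 - cos(c alpha) E1), with E1 fixed by an inversion-recovery T1 map
#' (M0 solved in closed form). B1+ is the ratio of true to nominal flip
#' angle. Because the transmit field is spatially smooth, the raw voxelwise
#' estimate is regularized by a low-order 3D polynomial fit over the brain
#' mask.
#'
#' @param vfa_series Magnitude [image_series()] with `axis_kind =
#'   "flip_deg"` (at least two flip angles) and a `tr_ms`.
#' @param ir_t1 A `T1` [quantitative_map()] on the same grid.
#' @param mask Optional 3D logical brain mask; defaults to voxels with a
#'   valid IR T1 and non-zero signal.
#' @param c_range Search range for the flip-angle scale.
#' @param poly_order Order of the smoothing polynomial.
#' @param smooth Set `FALSE` to return the raw voxelwise estimate.
#' @return List with `b1` (smoothed `B1` [quantitative_map()]), `b1_raw`,
#'   and `clipped` (logical volume flagging out-of-range raw estimates).
#' @export
estimate_b1_from_ir <- function(vfa_series, ir_t1, mask = NULL,
                                c_range = c(0.3, 1.7), poly_order = 3,
                                smooth = TRUE) {
  stopifnot(inherits(vfa_series, "image_series"),
            vfa_series$axis_kind == "flip_deg",
            length(vfa_series$axis_values) >= 2,
            !is.null(vfa_series$tr_ms))
  alpha <- vfa_series$axis_values * pi / 180
  V <- series_matrix(vfa_series)
  d3 <- dim(vfa_series$data)[1:3]
  t1 <- as.vector(ir_t1$data)
  if (is.null(mask)) mask <- ir_t1$valid & array(rowSums(V) > 0, d3)
  idx <- which(as.vector(mask) & is.finite(t1) & t1 > 0)
  E1 <- exp(-vfa_series$tr_ms / t1[idx])
  Y <- V[idx, , drop = FALSE]
  syy <- rowSums(Y^2)

  rss_at <- function(cc) {
    num <- rep(0, length(idx)); den <- rep(0, length(idx))
    for (k in seq_along(alpha)) {
      g <- spgr_shape(cc * alpha[k], E1)
      num <- num + Y[, k] * g
      den <- den + g^2
    }
    syy - num^2 / pmax(den, .Machine$double.eps)
  }
  grid <- seq(c_range[1], c_range[2], by = 0.01)
  best_rss <- rep(Inf, length(idx)); best_c <- rep(1, length(idx))
  for (cc in grid) {
    r <- rss_at(rep(cc, length(idx)))
    upd <- r < best_rss
    best_rss[upd] <- r[upd]; best_c[upd] <- cc
  }
  lo <- pmax(best_c - 0.01, c_range[1]); hi <- pmin(best_c + 0.01, c_range[2])
  cfit <- golden_min(rss_at, lo, hi, iters = 40)
  clipped_v <- cfit < c_range[1] | cfit > c_range[2]
  cfit <- pmin(pmax(cfit, c_range[1]), c_range[2])

  raw <- array(NA_real_, d3)
  raw[idx] <- cfit
  clipped <- array(FALSE, d3); clipped[idx] <- clipped_v
  if (smooth) {
    sm <- poly3_fit(raw, !is.na(raw), d3, order = poly_order, eval_mask = mask)
    b1 <- quantitative_map(sm, "B1", valid = mask & is.finite(sm))
  } else {
    b1 <- quantitative_map(raw, "B1")
  }
  list(b1 = b1, b1_raw = quantitative_map(raw, "B1"), clipped = clipped)
}

#' Variable-flip-angle T1 mapping with B1+ correction
#'
#' Linearized fit of the spoiled-GRE steady state across flip angles:
#' regressing S / sin(b1 alpha) on S / tan(b1 alpha) gives slope E1 =
#' exp(-TR / T1) and intercept M0 (1 - E1). Voxels with E1 outside (0, 1)
#' or fewer than two usable angles are invalid.
#'
#' @param vfa_series Magnitude [image_series()] with `axis_kind =
#'   "flip_deg"` and a `tr_ms`.
#' @param b1 Optional `B1` [quantitative_map()]; defaults to nominal angles.
#' @return List with `t1` (`T1` map, ms) and `m0` (equilibrium signal map,
#'   arbitrary units, plain array).
#' @export
fit_t1_vfa <- function(vfa_series, b1 = NULL) {
  stopifnot(inherits(vfa_series, "image_series"),
            vfa_series$axis_kind == "flip_deg",
            !is.null(vfa_series$tr_ms))
  alpha <- vfa_series$axis_values * pi / 180
  if (length(alpha) < 2) stop("at least two flip angles are required")
  V <- series_matrix(vfa_series)
  d3 <- dim(vfa_series$data)[1:3]
  nvox <- nrow(V)
  b1v <- if (is.null(b1)) rep(1, nvox) else as.vector(b1$data)
  b1v[!is.finite(b1v)] <- 1

  m <- length(alpha)
  sy <- sx <- sxx <- sxy <- rep(0, nvox)
  for (k in seq_len(m)) {
    a <- b1v * alpha[k]
    y <- V[, k] / sin(a)
    x <- V[, k] / tan(a)
    sy <- sy + y; sx <- sx + x; sxx <- sxx + x^2; sxy <- sxy + x * y
  }
  den <- m * sxx - sx^2
  E1 <- (m * sxy - sx * sy) / den
  icpt <- (sy - E1 * sx) / m
  bad <- !is.finite(E1) | E1 <= 0 | E1 >= 1 | rowSums(V) <= 0
  t1 <- -vfa_series$tr_ms / log(E1)
  t1[bad] <- NA_real_
  m0 <- icpt / (1 - E1)
  m0[bad] <- NA_real_
  list(t1 = quantitative_map(vec_to_vol(t1, d3), "T1"),
       m0 = vec_to_vol(m0, d3))
}

#' Water fraction and macromolecular tissue volume fraction
#'
#' Estimates the multiplicative receive-sensitivity bias by fitting a
#' low-order 3D polynomial to log(M0) over CSF voxels (whose proton density
#' is spatially constant and serves as the 100 percent water reference),
#' divides it out brain-wide, and normalizes so that the median corrected
#' M0 over CSF equals 1. WF is the corrected proton density in percent and
#' MTVF = 100 - WF.
#'
#' @param m0 3D array of equilibrium signal (from [fit_t1_vfa()]).
#' @param csf_mask 3D logical mask of CSF voxels (non-empty).
#' @param brain_mask 3D logical mask of voxels to report.
#' @param poly_order Receive-bias polynomial order.
#' @return List with `wf` and `mtvf` [quantitative_map()]s in percent,
#'   clipped to [0, 120] (voxels outside that range are flagged invalid).
#' @export
compute_wf_mtvf <- function(m0, csf_mask, brain_mask, poly_order = 2) {
  if (!any(csf_mask)) stop("CSF mask is empty", call. = FALSE)
  d3 <- dim(m0)
  ok_csf <- csf_mask & is.finite(m0) & m0 > 0
  lnb <- poly3_fit(log(pmax(m0, .Machine$double.eps)), ok_csf, d3,
                   order = poly_order, eval_mask = brain_mask)
  rel <- m0 / exp(lnb)
  med <- stats::median(rel[ok_csf], na.rm = TRUE)
  wf <- 100 * rel / med
  wf[!brain_mask] <- NA_real_
  in_range <- is.finite(wf) & wf >= 0 & wf <= 120
  wf_cl <- pmin(pmax(wf, 0), 120)
  list(wf = quantitative_map(wf_cl, "WF", valid = in_range),
       mtvf = quantitative_map(100 - wf_cl, "MTVF", valid = in_range))
}

#' Optional denoising hook for multi-echo series
#'
#' Placeholder for plugging a principal-component denoiser into the T2
#' pipeline ahead of dictionary fitting. The default implementation returns
#' the series unchanged.
#'
#' @param series An [image_series()].
#' @return The (possibly denoised) series.
#' @export
denoise_hook <- function(series) series
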