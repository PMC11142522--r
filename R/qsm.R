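GAMMA_MHZ_PER_T <- 42.577  # gyromagnetic ratio / 2 pi

#' Discrete dipole kernel in k-space
#'
#' D(k) = 1/3 - (k . b0)^2 / |k|^2 in the B0-aligned frame, with D(0) = 0.
#' Multiplying the Fourier transform of a susceptibility distribution by D
#' yields the unit-field (ppm-per-ppm) induced field shift.
#'
#' @param dim Grid dimension (length 3).
#' @param voxel_mm Voxel size in mm.
#' @param b0_dir Unit vector of the main field direction.
#' @return 3D real array of kernel values (unshifted FFT ordering).
#' @export
dipole_kernel <- function(dim, voxel_mm = c(1, 1, 1), b0_dir = c(0, 0, 1)) {
  b0_dir <- b0_dir / sqrt(sum(b0_dir^2))
  ks <- kgrid(dim, voxel_mm)
  kx <- kaxis(ks[[1]], dim, 1); ky <- kaxis(ks[[2]], dim, 2)
  kz <- kaxis(ks[[3]], dim, 3)
  k2 <- kx^2 + ky^2 + kz^2
  kb <- kx * b0_dir[1] + ky * b0_dir[2] + kz * b0_dir[3]
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Field induced by a susceptibility distribution
#'
#' Convolves `chi` with the discrete dipole kernel via zero-padded FFTs
#' (padding factor 2 avoids circular wrap-around). The same operator is
#' used by the phantom simulator and by the dipole inversion, so forward
#' and inverse form a consistent pair.
#'
#' @param chi 3D susceptibility array (ppm).
#' @param voxel_mm Voxel size in mm.
#' @param b0_dir Unit B0 direction.
#' @param pad Zero-padding factor (1 = circular convolution).
#' @return 3D array of field shift in ppm of B0.
#' @export
dipole_convolve <- function(chi, voxel_mm = c(1, 1, 1), b0_dir = c(0, 0, 1),
                            pad = 2) {
  dipole_conv_fun(dim(chi), voxel_mm, b0_dir, pad)(chi)
}

# Closure with a cached padded kernel: use inside iterative solvers so the
# kernel is built once, not per application.
dipole_conv_fun <- function(dim, voxel_mm = c(1, 1, 1), b0_dir = c(0, 0, 1),
                            pad = 2) {
  dp <- dim * pad
  D <- dipole_kernel(dp, voxel_mm, b0_dir)
  function(x) unpad3(Re(ifft3(fft3(pad3(x, dp)) * D)), dim)
}

# (Preconditioned) conjugate gradient for a symmetric positive
# (semi)definite operator; Minv is an optional Jacobi preconditioner array.
cg_solve <- function(Afun, b, x0 = NULL, tol = 1e-6, maxit = 1000,
                     Minv = NULL) {
  x <- if (is.null(x0)) array(0, dim(b)) else x0
  r <- b - Afun(x)
  z <- if (is.null(Minv)) r else Minv * r
  p <- z
  rz <- sum(r * z)
  r2 <- sum(r * r)
  b2 <- sum(b * b)
  if (b2 == 0) return(list(x = array(0, dim(b)), iters = 0L, converged = TRUE,
                           relres = 0))
  it <- 0L
  while (it < maxit && sqrt(r2 / b2) > tol) {
    Ap <- Afun(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- if (is.null(Minv)) r else Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    r2 <- sum(r * r)
    it <- it + 1L
  }
  list(x = x, iters = it, converged = sqrt(r2 / b2) <= tol,
       relres = sqrt(r2 / b2))
}

#' Total field estimation by nonlinear fitting of complex multi-echo data
#'
#' Per voxel, fits m(TE) = A exp(i (phi0 + 2 pi f TE)) to the complex echo
#' series by magnitude-weighted Gauss-Newton iterations on the phase,
#' initialized from the phase difference of the first echo pair. With
#' uniformly spaced echoes the field is identifiable modulo 1/dTE; larger
#' fields are restored spatially by [laplacian_unwrap()].
#'
#' @param series Complex [image_series()] with `axis_kind = "te_ms"`, at
#'   least two echoes.
#' @param iters Gauss-Newton iterations.
#' @return List of 3D arrays: `field_hz`, `phi0` (rad), `noise_sd_hz`
#'   (per-voxel standard error of f from the fit residuals), and
#'   `magnitude` (mean echo magnitude).
#' @export
fit_total_field <- function(series, iters = 8) {
  stopifnot(inherits(series, "image_series"), is.complex(series$data),
            series$axis_kind == "te_ms", dim(series$data)[4] >= 2)
  te_s <- series$axis_values / 1000
  V <- series_matrix(series)
  d3 <- dim(series$data)[1:3]
  w <- Mod(V)^2
  ok <- rowSums(w) > 0
  n <- length(te_s)

  f <- Arg(V[, 2] * Conj(V[, 1])) / (2 * pi * (te_s[2] - te_s[1]))
  phi0 <- Arg(V[, 1]) - 2 * pi * f * te_s[1]
  for (it in seq_len(iters)) {
    # wrapped phase residuals about the current model
    R <- matrix(0, nrow(V), n)
    for (k in seq_len(n)) {
      R[, k] <- Arg(V[, k] * exp(-1i * (phi0 + 2 * pi * f * te_s[k])))
    }
    sw <- rowSums(w)
    sx <- w %*% te_s; sxx <- w %*% te_s^2
    sy <- rowSums(w * R); sxy <- rowSums(w * R * matrix(te_s, nrow(V), n, byrow = TRUE))
    den <- sw * sxx - sx^2
    df <- (sw * sxy - sx * sy) / den / (2 * pi)
    dphi <- (sy - 2 * pi * df * sx) / sw
    f <- f + as.vector(df)
    phi0 <- phi0 + as.vector(dphi)
  }
  # residual-based per-voxel noise estimate for the field (slope std. error)
  R <- matrix(0, nrow(V), n)
  for (k in seq_len(n)) {
    R[, k] <- Arg(V[, k] * exp(-1i * (phi0 + 2 * pi * f * te_s[k])))
  }
  sw <- rowSums(w)
  sx <- as.vector(w %*% te_s); sxx <- as.vector(w %*% te_s^2)
  rss <- rowSums(w * R^2)
  sd_f <- sqrt(pmax(rss, 0) / pmax(n - 2, 1) / pmax(sxx - sx^2 / sw, .Machine$double.eps)) / (2 * pi)
  f[!ok] <- NA_real_; phi0[!ok] <- NA_real_; sd_f[!ok] <- NA_real_
  list(field_hz = vec_to_vol(f, d3), phi0 = vec_to_vol(phi0, d3),
       noise_sd_hz = vec_to_vol(sd_f, d3),
       magnitude = vec_to_vol(rowMeans(Mod(V)), d3))
}

#' Laplacian phase unwrapping
#'
#' Fourier-domain implementation of the Laplacian identity
#' phi_u = invLap(cos(phi) Lap(sin(phi)) - sin(phi) Lap(cos(phi))).
#' The field of view is doubled before the transforms (factor-2 padding by
#' even mirror extension, so sin/cos stay continuous at the grid edges and
#' the inverse Laplacian is well posed under the periodic transform). The
#' output is congruent to the input modulo 2 pi up to a harmonic
#' component, which downstream background-field removal absorbs.
#'
#' @param phase 3D array of wrapped phase in (-pi, pi].
#' @param mask Optional 3D logical mask (only used to centre the output's
#'   mean on the input's within the mask).
#' @param pad Zero-padding factor.
#' @return 3D array of unwrapped phase (rad).
#' @export
laplacian_unwrap <- function(phase, mask = NULL, pad = 2) {
  d <- dim(phase)
  dp <- d * pad
  mirror_pad <- function(x) {
    rep_axis <- function(n, m) rep_len(c(seq_len(n), n:1), m)
    x[rep_axis(d[1], dp[1]), rep_axis(d[2], dp[2]), rep_axis(d[3], dp[3])]
  }
  ks <- kgrid(dp, c(1, 1, 1))
  k2 <- kaxis(ks[[1]], dp, 1)^2 + kaxis(ks[[2]], dp, 2)^2 +
    kaxis(ks[[3]], dp, 3)^2
  lap <- function(x) Re(ifft3(fft3(x) * (-k2)))
  invlap <- function(x) {
    X <- fft3(x) / ifelse(k2 == 0, 1, -k2)
    X[1, 1, 1] <- 0
    Re(ifft3(X))
  }
  sp <- mirror_pad(sin(phase)); cp <- mirror_pad(cos(phase))
  u <- invlap(cp * lap(sp) - sp * lap(cp))
  u <- unpad3(u, d)
  if (is.null(mask)) mask <- array(TRUE, d)
  u + mean(phase[mask]) - mean(u[mask])
}

#' Noise-based mask erosion
#'
#' Removes voxels whose field-fit noise estimate exceeds three times the
#' in-mask median (unreliable phase), then applies one 6-connected
#' morphological erosion.
#'
#' @param mask 3D logical brain mask.
#' @param noise_sd 3D array of per-voxel noise estimates (or `NULL`).
#' @return Eroded 3D logical mask.
#' @export
noise_erode_mask <- function(mask, noise_sd = NULL) {
  if (!is.null(noise_sd)) {
    med <- stats::median(noise_sd[mask], na.rm = TRUE)
    keep <- is.na(noise_sd) | noise_sd <= 3 * med | med == 0
    mask <- mask & keep
  }
  erode6(mask)
}

#' Background field removal by projection onto dipole fields
#'
#' Fits the in-mask total field as the field of susceptibility sources
#' supported outside the mask (noise-weighted least squares solved by
#' conjugate gradient); the local field is the residual, zeroed outside
#' the mask. Fields generated by sources outside the mask are (near)
#' harmonic inside it and are thereby removed, while fields of internal
#' sources are largely preserved.
#'
#' @param total_field_hz 3D array, total field in Hz.
#' @param mask 3D logical mask of the reliable brain region.
#' @param noise_sd_hz Optional per-voxel noise array used as inverse
#'   weights.
#' @param voxel_mm,b0_dir Geometry of the dipole kernel.
#' @param tol,maxit Conjugate-gradient stopping parameters; non-convergence
#'   raises a warning and returns the best iterate.
#' @return List with `local_field_hz` (3D array, zero outside mask),
#'   `background_field_hz`, and the CG diagnostics.
#' @export
pdf_remove_background <- function(total_field_hz, mask, noise_sd_hz = NULL,
                                  voxel_mm = c(1, 1, 1), b0_dir = c(0, 0, 1),
                                  tol = 1e-3, maxit = 30) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  f <- total_field_hz
  f[!is.finite(f)] <- 0
  w <- array(1, dim(f))
  if (!is.null(noise_sd_hz)) {
    ns <- noise_sd_hz
    med <- stats::median(ns[mask], na.rm = TRUE)
    if (is.finite(med) && med > 0) {
      w <- med / pmax(ns, med / 10)
      w[!is.finite(w)] <- 1
    }
  }
  w[!mask] <- 0
  Min <- array(0, dim(f)); Min[mask] <- 1
  Mout <- 1 - Min
  conv <- dipole_conv_fun(dim(f), voxel_mm, b0_dir)
  Afun <- function(x) Mout * conv(w^2 * Min * conv(Mout * x))
  b <- Mout * conv(w^2 * Min * f)
  # Jacobi preconditioner: diag(A'A)_j = sum_i w_i^2 d(i - j)^2, the
  # weighted squared dipole coupling of each exterior source to the mask;
  # it decays fast with distance and dominates the conditioning.
  dp <- dim(f) * 2
  imp <- array(0, dp); imp[1, 1, 1] <- 1
  dimg <- Re(ifft3(fft3(imp) * dipole_kernel(dp, voxel_mm, b0_dir)))
  diagA <- unpad3(Re(ifft3(fft3(pad3(w^2 * Min, dp)) * Conj(fft3(dimg^2)))),
                  dim(f))
  diagA <- pmax(diagA, 1e-6 * max(diagA))
  sol <- cg_solve(Afun, b, tol = tol, maxit = maxit, Minv = Mout / diagA)
  if (!sol$converged) {
    warning(sprintf("PDF conjugate gradient stopped at %d iterations (relative residual %.2e)",
                    sol$iters, sol$relres))
  }
  bg <- conv(Mout * sol$x)
  local <- (f - bg) * Min
  list(local_field_hz = local, background_field_hz = bg,
       iters = sol$iters, converged = sol$converged)
}

#' Iterative Tikhonov-regularized dipole inversion
#'
#' Solves chi = argmin || M (F^-1 D F chi - f) ||^2 + alpha ||chi||^2 by
#' conjugate gradient in the image domain, where D is the discrete dipole
#' kernel in the B0-aligned frame, M restricts the data term to the brain
#' mask, and f is the local field converted to ppm of B0. The solution is
#' constrained to the mask and referenced by subtracting its in-mask mean.
#'
#' @param local_field_hz 3D array, local (background-free) field in Hz.
#' @param mask 3D logical mask.
#' @param alpha Tikhonov regularization weight (default 0.05).
#' @param b0_dir Unit B0 direction.
#' @param voxel_mm Voxel size in mm.
#' @param field_strength_T Main field in Tesla (default 3).
#' @param tol,maxit Conjugate-gradient stopping parameters.
#' @return A `QSM` [quantitative_map()] in ppm (zero-mean over the mask,
#'   `NA` outside).
#' @export
tikhonov_invert <- function(local_field_hz, mask, alpha = 0.05,
                            b0_dir = c(0, 0, 1), voxel_mm = c(1, 1, 1),
                            field_strength_T = 3, tol = 1e-6, maxit = 1000,
                            psf_correct = TRUE) {
  stopifnot(alpha >= 0)
  hz_per_ppm <- GAMMA_MHZ_PER_T * field_strength_T
  fn <- local_field_hz / hz_per_ppm
  fn[!is.finite(fn)] <- 0
  M <- array(0, dim(fn)); M[mask] <- 1
  conv <- dipole_conv_fun(dim(fn), voxel_mm, b0_dir)
  Afun <- function(x) M * conv(M * conv(M * x)) + alpha * x
  b <- M * conv(M * fn)
  sol <- cg_solve(Afun, b, tol = tol, maxit = maxit)
  chi <- sol$x * M
  if (psf_correct && alpha > 0) {
    # Tikhonov inversion attenuates susceptibility by the central value of
    # its point spread function, mean_k D^2/(D^2 + alpha); divide it out
    # (the standard underestimation correction of thresholded / Tikhonov
    # dipole inversions).
    D <- dipole_kernel(dim(fn) * 2, voxel_mm, b0_dir)
    chi <- chi / mean(D^2 / (D^2 + alpha))
  }
  chi <- chi - mean(chi[mask])
  chi[!mask] <- NA_real_
  quantitative_map(chi, "QSM", valid = mask & is.finite(chi))
}

# Rotation with minimal angle taking the unit vector v to the +z axis.
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * (K %*% K)   # Rodrigues, sin(theta) = s
}

# Trilinear resampling of vol under rotation R about the grid centre, on an
# output grid of dimension out_dim (same voxel size).
resample_rotate <- function(vol, R, out_dim, voxel_mm = c(1, 1, 1)) {
  d <- dim(vol)
  ctr_in <- (d + 1) / 2
  ctr_out <- (out_dim + 1) / 2
  idx <- arrayInd(seq_len(prod(out_dim)), out_dim)
  # physical (mm) offsets from centre, rotate back into the source frame
  P <- sweep(idx, 2, ctr_out) * rep(voxel_mm, each = nrow(idx))
  S <- P %*% R  # R^T applied to row vectors: source = R^-1 target
  S <- sweep(S, 2, voxel_mm, "/")
  S <- sweep(S, 2, ctr_in, "+")
  x0 <- floor(S[, 1]); y0 <- floor(S[, 2]); z0 <- floor(S[, 3])
  fx <- S[, 1] - x0; fy <- S[, 2] - y0; fz <- S[, 3] - z0
  out <- numeric(nrow(S))
  get <- function(i, j, k) {
    inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    v <- numeric(length(i))
    ii <- which(inside)
    v[ii] <- vol[cbind(i[ii], j[ii], k[ii])]
    v
  }
  out <- get(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    get(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    get(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    get(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    get(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    get(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    get(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    get(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  array(out, out_dim)
}

#' Rotate volumes into the B0-aligned frame
#'
#' Rigidly resamples the input volume(s) so that the third grid axis is
#' parallel to the B0 direction. The field of view is zero-padded before
#' rotation (to the grid diagonal) so that no voxel leaves the grid;
#' interpolation is trilinear. With `b0_dir = c(0, 0, 1)` the input is
#' returned unchanged.
#'
#' @param volumes A 3D array or a list of 3D arrays on a common grid.
#' @param b0_dir Unit B0 direction.
#' @param voxel_mm Voxel size in mm.
#' @param inverse Apply the inverse rotation instead.
#' @return List with `volumes` (list of rotated padded arrays), `rotation`
#'   (the applied matrix) and `orig_dim`.
#' @export
rotate_to_b0 <- function(volumes, b0_dir, voxel_mm = c(1, 1, 1),
                         inverse = FALSE) {
  single <- !is.list(volumes)
  if (single) volumes <- list(volumes)
  b0_dir <- b0_dir / sqrt(sum(b0_dir^2))
  d <- dim(volumes[[1]])
  if (all(abs(b0_dir - c(0, 0, 1)) < 1e-12)) {
    return(list(volumes = volumes, rotation = diag(3), orig_dim = d))
  }
  R <- rotation_to_z(b0_dir)
  if (inverse) R <- t(R)
  diag_len <- ceiling(sqrt(sum((d * voxel_mm / min(voxel_mm))^2)))
  out_dim <- pmax(d, rep(diag_len, 3))
  padded <- lapply(volumes, function(v) {
    vp <- array(0, out_dim)
    off <- floor((out_dim - d) / 2)
    vp[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- v
    vp
  })
  rot <- lapply(padded, resample_rotate, R = R, out_dim = out_dim,
                voxel_mm = voxel_mm)
  list(volumes = rot, rotation = R, orig_dim = d)
}

#' Full susceptibility mapping chain
#'
#' Runs the complete QSM reconstruction on a complex multi-echo
#' gradient-echo series: nonlinear total-field fitting, Laplacian phase
#' unwrapping of the per-dTE phase, noise-based mask erosion, projection
#' onto dipole fields, and Tikhonov dipole inversion. The returned map is
#' referenced either to a zero in-mask mean (default) or to a zero mean
#' over a supplied CSF mask.
#'
#' @param series Complex [image_series()] (`axis_kind = "te_ms"`).
#' @param mask 3D logical brain mask.
#' @param alpha Regularization weight.
#' @param b0_dir,field_strength_T Field geometry and strength.
#' @param csf_mask Optional CSF mask for referencing.
#' @param pdf_maxit,tik_maxit,tol Solver controls.
#' @return List with `chi` (`QSM` map, ppm), the eroded `mask`, and the
#'   intermediate fields.
#' @export
qsm_pipeline <- function(series, mask, alpha = 0.05, b0_dir = c(0, 0, 1),
                         field_strength_T = 3, csf_mask = NULL,
                         pdf_maxit = 30, tik_maxit = 200, tol = 1e-6) {
  ff <- fit_total_field(series)
  te_s <- series$axis_values / 1000
  dte <- mean(diff(te_s))
  psi <- ff$field_hz * 2 * pi * dte
  psi[!is.finite(psi)] <- 0
  wrapped <- atan2(sin(psi), cos(psi))
  uw <- laplacian_unwrap(wrapped, mask)
  field <- uw / (2 * pi * dte)
  mask_e <- noise_erode_mask(mask, ff$noise_sd_hz)
  pdf <- pdf_remove_background(field, mask_e, ff$noise_sd_hz,
                               voxel_mm = series$voxel_mm, b0_dir = b0_dir,
                               tol = 1e-3, maxit = pdf_maxit)
  chi <- tikhonov_invert(pdf$local_field_hz, mask_e, alpha = alpha,
                         b0_dir = b0_dir, voxel_mm = series$voxel_mm,
                         field_strength_T = field_strength_T,
                         tol = tol, maxit = tik_maxit)
  if (!is.null(csf_mask)) {
    ref_mask <- csf_mask & chi$valid
    if (any(ref_mask)) {
      dat <- chi$data - mean(chi$data[ref_mask])
      chi <- quantitative_map(dat, "QSM", valid = chi$valid)
    }
  }
  list(chi = chi, mask = mask_e, total_field_hz = field,
       local_field_hz = pdf$local_field_hz, noise_sd_hz = ff$noise_sd_hz)
}

#' Rescale scanner-integer phase to radians
#'
#' Some scanners export phase images as integers spanning [-4096, 4094]
#' rather than radians; this maps that range linearly onto (-pi, pi].
#'
#' @param x Array of integer-dialect phase values.
#' @return Array of phase in radians.
#' @export
scanner_phase_to_radians <- function(x) {
  x * pi / 4096
}
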