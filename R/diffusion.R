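#' Diffusion gradient scheme
#'
#' Pairs each measurement's b-value with its (unit) gradient direction.
#' Directions of b = 0 entries are ignored. [read_gradient_scheme()] parses
#' the FSL bval/bvec dialect (one row of b-values; three rows of direction
#' components); [default_gradient_scheme()] returns the packaged
#' 64-direction electrostatic-repulsion set with one leading b = 0 volume.
#'
#' @param bvalues_s_mm2 Numeric vector of b-values in s/mm^2.
#' @param directions n x 3 matrix of gradient directions (normalized here).
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvalues_s_mm2, directions) {
  directions <- as.matrix(directions)
  if (nrow(directions) != length(bvalues_s_mm2)) {
    stop("direction count must equal b-value count", call. = FALSE)
  }
  if (any(bvalues_s_mm2 < 0)) stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  nz <- bvalues_s_mm2 > 0
  if (any(nrm[nz] == 0)) stop("b > 0 entries need a non-zero direction", call. = FALSE)
  directions[nz, ] <- directions[nz, ] / nrm[nz]
  directions[!nz, ] <- 0
  structure(list(bvalues_s_mm2 = as.numeric(bvalues_s_mm2),
                 directions = directions), class = "gradient_scheme")
}

#' @param bvec_path,bval_path Paths to FSL-style bvec/bval text files.
#' @rdname gradient_scheme
#' @export
read_gradient_scheme <- function(bvec_path, bval_path) {
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3) stop("bvec file must have three rows", call. = FALSE)
  bval <- scan(bval_path, quiet = TRUE)
  gradient_scheme(bval, t(bvec))
}

#' @rdname gradient_scheme
#' @export
default_gradient_scheme <- function() {
  read_gradient_scheme(
    system.file("extdata", "dwi_64.bvec", package = "multiqmap", mustWork = TRUE),
    system.file("extdata", "dwi_64.bval", package = "multiqmap", mustWork = TRUE))
}

# Six-direction reversed-phase-encode scheme (b = 0 + octahedral pairs).
revpe_gradient_scheme <- function() {
  d <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  gradient_scheme(c(0, rep(1000, 6)), d)
}

# Design row for ln(S) = ln(S0) - b g' D g, tensor order
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
dti_design <- function(scheme) {
  b <- scheme$bvalues_s_mm2
  g <- scheme$directions
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Log-linear diffusion tensor fit
#'
#' Per voxel, ordinary least squares of ln(S) on the b-matrix design
#' (intercept ln S0 plus the six unique tensor elements). Non-positive
#' signals are excluded from the fit; voxels with fewer than six usable
#' diffusion-weighted measurements, no b = 0 measurement, or a degenerate
#' design are invalid.
#'
#' @param series Magnitude [image_series()] with `axis_kind = "diffusion"`.
#' @param scheme A [gradient_scheme()] matching the series (defaults to the
#'   scheme stored on the series axis).
#' @return A `tensor_field`: list with `tensor` (nvox x 6 matrix, mm^2/s,
#'   order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `s0`, `valid`, and `dim`.
#' @export
fit_dti_loglinear <- function(series, scheme = NULL) {
  stopifnot(inherits(series, "image_series"), series$axis_kind == "diffusion")
  if (is.null(scheme)) {
    scheme <- gradient_scheme(series$axis_values$bvalues,
                              series$axis_values$directions)
  }
  V <- series_matrix(series)
  d3 <- dim(series$data)[1:3]
  nvox <- nrow(V)
  X <- dti_design(scheme)
  nz <- scheme$bvalues_s_mm2 > 0
  usable <- V > 0
  full <- rowSums(usable) == ncol(V)
  n_dw <- rowSums(usable[, nz, drop = FALSE])
  n_b0 <- rowSums(usable[, !nz, drop = FALSE])
  fit_ok <- n_dw >= 6 & n_b0 >= 1

  B <- matrix(NA_real_, nvox, 7)
  # fast path: all measurements positive, common design
  idx_f <- which(full & fit_ok)
  if (length(idx_f) > 0) {
    qrX <- qr(X)
    B[idx_f, ] <- t(qr.coef(qrX, t(log(V[idx_f, , drop = FALSE]))))
  }
  # slow path: per-voxel exclusion of non-positive signals
  idx_s <- which(!full & fit_ok)
  for (i in idx_s) {
    u <- usable[i, ]
    Xi <- X[u, , drop = FALSE]
    if (qr(Xi)$rank < 7) { fit_ok[i] <- FALSE; next }
    B[i, ] <- qr.coef(qr(Xi), log(V[i, u]))
  }
  valid <- fit_ok & is.finite(rowSums(B))
  B[!valid, ] <- NA_real_
  structure(list(tensor = B[, 2:7, drop = FALSE], s0 = exp(B[, 1]),
                 valid = vec_to_vol(valid, d3), dim = d3),
            class = "tensor_field")
}

# Analytic eigenvalues of symmetric 3x3 tensors, vectorized over rows of
# the (n x 6) component matrix; returned sorted descending.
tensor_eigenvalues <- function(Tm) {
  dxx <- Tm[, 1]; dyy <- Tm[, 2]; dzz <- Tm[, 3]
  dxy <- Tm[, 4]; dxz <- Tm[, 5]; dyz <- Tm[, 6]
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  nz <- which(p > 0)
  if (length(nz) > 0) {
    a11 <- (dxx[nz] - q[nz]) / p[nz]; a22 <- (dyy[nz] - q[nz]) / p[nz]
    a33 <- (dzz[nz] - q[nz]) / p[nz]
    a12 <- dxy[nz] / p[nz]; a13 <- dxz[nz] / p[nz]; a23 <- dyz[nz] / p[nz]
    # det of the normalized deviatoric tensor
    detB <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

#' Scalar invariants of the eigenvalue triple
#'
#' MD is the eigenvalue mean; FA the normalized eigenvalue dispersion
#' FA = sqrt(3/2) sqrt(sum (lambda_i - MD)^2) / sqrt(sum lambda_i^2).
#'
#' @param l1,l2,l3 Eigenvalues (any common diffusivity unit).
#' @return For [md_from_eigenvalues()], MD in the input unit; for
#'   [fa_from_eigenvalues()], FA in [0, 1] (0/0 gives `NaN`).
#' @export
md_from_eigenvalues <- function(l1, l2, l3) (l1 + l2 + l3) / 3

#' @rdname md_from_eigenvalues
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  sqrt(1.5) * sqrt(num / den)
}

#' Mean diffusivity and fractional anisotropy maps from a tensor field
#'
#' MD is reported in 1e-4 mm^2/s and FA is clipped to [0, 1]. Voxels whose
#' tensor has a negative eigenvalue are flagged in `negative_ev` (they stay
#' valid in the maps; callers may exclude them). All-zero tensors give an
#' invalid FA.
#'
#' @param tensor A `tensor_field` from [fit_dti_loglinear()].
#' @return List with `md` and `fa` [quantitative_map()]s, `eigenvalues`
#'   (nvox x 3, mm^2/s, descending), and `negative_ev` (3D logical).
#' @export
tensor_metrics <- function(tensor) {
  stopifnot(inherits(tensor, "tensor_field"))
  lam <- tensor_eigenvalues(tensor$tensor)
  md <- md_from_eigenvalues(lam[, 1], lam[, 2], lam[, 3])
  fa <- fa_from_eigenvalues(lam[, 1], lam[, 2], lam[, 3])
  fa <- pmin(pmax(fa, 0), 1)
  vvec <- as.vector(tensor$valid)
  allzero <- rowSums(abs(tensor$tensor)) == 0
  md[!vvec] <- NA_real_
  fa[!vvec | allzero] <- NA_real_
  neg <- vvec & lam[, 3] < 0
  list(md = quantitative_map(vec_to_vol(md * 1e4, tensor$dim), "MD"),
       fa = quantitative_map(vec_to_vol(fa, tensor$dim), "FA"),
       eigenvalues = lam,
       negative_ev = vec_to_vol(neg, tensor$dim))
}

#' Axially symmetric tensor from (MD, FA)
#'
#' Builds the unique axially symmetric diffusion tensor with the given mean
#' diffusivity, fractional anisotropy and principal axis: eigenvalues
#' (MD + 2 delta, MD - delta, MD - delta) with
#' delta = FA MD sqrt(3 / (9 - 6 FA^2)).
#'
#' @param md Mean diffusivity (any unit; output tensor is in the same unit).
#' @param fa Fractional anisotropy in [0, 1).
#' @param axis Principal axis (unit 3-vector, normalized here).
#' @return Length-6 tensor component vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#'   or an n x 6 matrix for vector `md` / `fa` with a common axis.
#' @export
axisym_tensor <- function(md, fa, axis) {
  axis <- axis / sqrt(sum(axis^2))
  delta <- fa * md * sqrt(3 / (9 - 6 * fa^2))
  iso <- md - delta
  n <- axis
  out <- cbind(iso + 3 * delta * n[1]^2,
               iso + 3 * delta * n[2]^2,
               iso + 3 * delta * n[3]^2,
               3 * delta * n[1] * n[2],
               3 * delta * n[1] * n[3],
               3 * delta * n[2] * n[3])
  if (length(md) == 1) drop(out) else out
}
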