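# Internal numerical helpers shared across modules.

MAP_TYPES <- c("T1", "T2", "T2star", "QSM", "WF", "MTVF", "MD", "FA",
               "MTR", "ihMTR", "B1")

MAP_UNITS <- c(T1 = "ms", T2 = "ms", T2star = "ms", QSM = "ppm",
               WF = "%", MTVF = "%", MD = "1e-4 mm^2/s", FA = "unitless",
               MTR = "%", ihMTR = "%", B1 = "unitless")

#' @keywords internal
map_units <- function(map_type) {
  unname(MAP_UNITS[match.arg(map_type, MAP_TYPES)])
}

# Angular spatial-frequency grids (rad/mm) for an FFT of dimension dim with
# voxel size voxel_mm, in R's unshifted frequency ordering.
kgrid <- function(dim, voxel_mm = c(1, 1, 1)) {
  lapply(seq_along(dim), function(i) {
    n <- dim[i]
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / (n * voxel_mm[i])
    2 * pi * f
  })
}

# Broadcast a 1-d frequency vector along axis `axis` of a 3D array shape.
kaxis <- function(k, dim, axis) {
  switch(axis,
         `1` = array(k, dim),
         `2` = aperm(array(k, dim[c(2, 1, 3)]), c(2, 1, 3)),
         `3` = aperm(array(k, dim[c(3, 1, 2)]), c(2, 3, 1)))
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Zero-pad a 3D array to dimension `dim2` (top-left anchored).
pad3 <- function(x, dim2) {
  out <- array(0, dim2)
  d <- dim(x)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

unpad3 <- function(x, dim1) {
  x[seq_len(dim1[1]), seq_len(dim1[2]), seq_len(dim1[3]), drop = FALSE]
}

# Gaussian-filtered white noise: a smooth zero-mean random field with
# approximate correlation length `corr_len` voxels, rescaled to unit SD.
smooth_field <- function(dim, corr_len = 12, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  w <- array(stats::rnorm(prod(dim)), dim)
  f <- gaussian_smooth3(w, sigma = corr_len / 2)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

# Save/restore the global RNG stream so seeded helpers do not perturb it.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# FFT Gaussian smoothing (circular boundary; fields are used well inside the
# brain mask so wrap-around is immaterial).
gaussian_smooth3 <- function(x, sigma) {
  d <- dim(x)
  ks <- kgrid(d, c(1, 1, 1))
  k2 <- kaxis(ks[[1]], d, 1)^2 + kaxis(ks[[2]], d, 2)^2 + kaxis(ks[[3]], d, 3)^2
  h <- exp(-k2 * sigma^2 / 2)
  Re(ifft3(fft3(x) * h))
}

# Mirror a 3D logical/numeric array about the mid-sagittal plane (axis 1).
mirror_x <- function(x) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]

# Binary erosion with the 6-connected (face-neighbour) structuring element.
erode6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx
    if (by == 1) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else         { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  mask & shift(mask, 1, 1) & shift(mask, 1, -1) &
    shift(mask, 2, 1) & shift(mask, 2, -1) &
    shift(mask, 3, 1) & shift(mask, 3, -1)
}

# Design matrix of 3D monomials x^i y^j z^k, i+j+k <= order, on coordinates
# normalised to [-1, 1] (columns in a fixed deterministic order).
poly3_design <- function(coords, dim, order) {
  u <- 2 * (coords[, 1] - 1) / max(dim[1] - 1, 1) - 1
  v <- 2 * (coords[, 2] - 1) / max(dim[2] - 1, 1) - 1
  w <- 2 * (coords[, 3] - 1) / max(dim[3] - 1, 1) - 1
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    cols[[length(cols) + 1]] <- u^i * v^j * w^k
  }
  do.call(cbind, cols)
}

# Fit a low-order 3D polynomial to `values` observed at logical mask
# `fit_mask`, and evaluate it over `eval_mask` (default: everywhere).
poly3_fit <- function(values, fit_mask, dim, order = 3, eval_mask = NULL) {
  idx <- which(fit_mask)
  coords <- arrayInd(idx, dim)
  X <- poly3_design(coords, dim, order)
  beta <- qr.coef(qr(X), values[idx])
  beta[is.na(beta)] <- 0
  if (is.null(eval_mask)) eval_mask <- array(TRUE, dim)
  eidx <- which(eval_mask)
  Xe <- poly3_design(arrayInd(eidx, dim), dim, order)
  out <- array(NA_real_, dim)
  out[eidx] <- as.vector(Xe %*% beta)
  out
}

# Vectorised golden-section minimisation of fn(x) where x is a vector of
# per-element abscissae and fn is applied elementwise. lo/hi are vectors.
golden_min <- function(fn, lo, hi, iters = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  for (it in seq_len(iters)) {
    left <- f1 < f2                     # minimum bracketed in [a, x2]
    b <- ifelse(left, x2, b)
    a <- ifelse(left, a, x1)
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- fn(x1); f2 <- fn(x2)
  }
  (a + b) / 2
}

# Derive a bounded child seed from a base seed and a stream label.
child_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 31 + (as.numeric(p) %% 1e6)) %% 2147480000
  as.integer(h) + 1L
}
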