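test_that("dipole kernel takes its closed-form axis values", {
  D <- dipole_kernel(c(8, 8, 8))
  expect_equal(D[1, 1, 2], -2 / 3)   # k along B0
  expect_equal(D[2, 1, 1], 1 / 3)    # k transverse
  expect_equal(D[1, 2, 1], 1 / 3)
  expect_equal(D[1, 1, 1], 0)        # D(0) := 0
})

test_that("total field fitting inverts the complex signal model", {
  te <- seq(5.2, 36.9, length.out = 8)
  mk <- function(f, phi0 = 0.3, amp = 1) {
    sig <- amp * exp(1i * (phi0 + 2 * pi * f * te / 1000))
    image_series(array(rep(sig, each = 4), c(2, 2, 1, 8)), "te_ms", te)
  }
  ff <- fit_total_field(mk(10))
  expect_equal(unname(ff$field_hz[1, 1, 1]), 10, tolerance = 1e-9)
  expect_equal(unname(ff$phi0[1, 1, 1]), 0.3, tolerance = 1e-9)
  expect_lt(ff$noise_sd_hz[1, 1, 1], 1e-9)
  # all-zero voxel invalid
  z <- mk(10); z$data[1, 1, 1, ] <- 0
  ffz <- fit_total_field(z)
  expect_true(is.na(ffz$field_hz[1, 1, 1]))
})

test_that("inter-echo wrapping aliases the field by exactly 1/dTE", {
  te <- seq(5.2, 36.9, length.out = 8)
  dte <- mean(diff(te)) / 1000
  f_true <- 150  # wraps between echoes at this spacing
  sig <- 0.8 * exp(1i * (0.1 + 2 * pi * f_true * te / 1000))
  ser <- image_series(array(rep(sig, each = 1), c(1, 1, 1, 8)), "te_ms", te)
  ff <- fit_total_field(ser)
  fhat <- ff$field_hz[1, 1, 1]
  # the fit lands on a wrap-equivalent candidate with zero residual
  expect_equal((f_true - fhat) %% (1 / dte), 0, tolerance = 1e-6)
  # brute-force enumeration over wrap integers: every candidate f + k/dTE
  # fits the data equally; the fit's candidate attains the minimal residual
  rss <- vapply(-3:3, function(k) {
    f <- fhat + k / dte
    model <- exp(1i * 2 * pi * f * te / 1000)
    phi <- Arg(sum(sig * Conj(model)))
    sum(Mod(sig - 0.8 * exp(1i * phi) * model)^2)
  }, 0)
  expect_lt(min(rss), 1e-12)
  expect_equal(rss[4], min(rss), tolerance = 1e-12)
})

test_that("Laplacian unwrapping restores smooth and wrapped-ramp phases", {
  d <- c(32, 32, 32)
  m <- erode_k(array(TRUE, d), 4)
  ps <- multiqmap:::smooth_field(d, corr_len = 8, seed = 2)
  ps <- ps / max(abs(ps)) * 3   # smooth, amplitude below pi: no wraps
  u <- laplacian_unwrap(atan2(sin(ps), cos(ps)), mask = m)
  expect_lt(sqrt(mean((u[m] - ps[m])^2)), 1e-2)
  # a 6 pi linear ramp, wrapped, is recovered up to an additive constant
  ramp <- array(rep(seq(0, 6 * pi, length.out = 32), times = 32 * 32), d)
  uw <- laplacian_unwrap(atan2(sin(ramp), cos(ramp)))
  dc <- uw - ramp
  expect_lt(sqrt(mean((dc[m] - mean(dc[m]))^2)), 1e-2)
  expect_equal(laplacian_unwrap(array(0, d)), array(0, d))
})

test_that("PDF removes exterior-source fields and keeps interior structure", {
  d <- c(32, 32, 32)
  idx <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(idx, 2, 16.5)^2)
  mask <- array(r2 <= 13^2, d)
  me <- erode_k(mask, 2)
  # field generated solely by sources outside the mask
  chib <- array(0, d); chib[30:32, 12:20, 12:20] <- 5
  fb <- dipole_convolve(chib) * 127.7
  p1 <- suppressWarnings(pdf_remove_background(fb, mask))
  expect_lt(sum(p1$local_field_hz[me]^2) / sum(fb[me]^2), 0.05)
  # zero input gives zero output
  p0 <- pdf_remove_background(array(0, d), mask)
  expect_equal(p0$local_field_hz, array(0, d))
  # distributed sources strictly inside the mask are largely preserved
  interior <- array(r2 <= 10^2, d)
  chi <- multiqmap:::smooth_field(d, corr_len = 2, seed = 3) * 0.05
  chi[!interior] <- 0
  fi <- dipole_convolve(chi) * 127.7
  p2 <- suppressWarnings(pdf_remove_background(fi, mask))
  m3 <- erode_k(mask, 3)
  expect_lt(sqrt(sum((p2$local_field_hz[m3] - fi[m3])^2) / sum(fi[m3]^2)), 0.10)
})

test_that("Tikhonov inversion round-trips a susceptibility sphere", {
  d <- c(48, 48, 48)
  idx <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(idx, 2, 24.5)^2)
  chi <- array(0, d); chi[r2 <= 8^2] <- 0.1
  mask <- array(r2 <= 20^2, d)
  f_hz <- dipole_convolve(chi) * 42.577 * 3
  inv <- tikhonov_invert(f_hz, mask, alpha = 0.05)
  ref <- chi - mean(chi[mask])
  expect_lt(sqrt(mean((inv$data[mask] - ref[mask])^2)), 0.15 * 0.1)
  # in-mask mean referencing
  expect_equal(mean(inv$data[mask]), 0, tolerance = 1e-9)
  # linearity: doubling the field doubles chi
  inv2 <- tikhonov_invert(2 * f_hz, mask, alpha = 0.05)
  expect_equal(inv2$data[mask], 2 * inv$data[mask], tolerance = 1e-6)
})

test_that("stronger regularization shrinks the solution norm", {
  d <- c(24, 24, 24)
  idx <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(idx, 2, 12.5)^2)
  chi <- array(0, d); chi[r2 <= 4^2] <- 0.1
  mask <- array(r2 <= 10^2, d)
  f_hz <- dipole_convolve(chi) * 127.7
  nrm <- vapply(c(0.02, 0.05, 0.2, 0.8), function(a) {
    x <- tikhonov_invert(f_hz, mask, alpha = a, psf_correct = FALSE)
    sqrt(sum(x$data[mask]^2))
  }, 0)
  expect_true(all(diff(nrm) <= 1e-9))
})

test_that("noise-based erosion drops unreliable voxels plus one shell", {
  mask <- array(TRUE, c(8, 8, 8))
  ns <- array(1, c(8, 8, 8)); ns[4, 4, 4] <- 10
  out <- noise_erode_mask(mask, ns)
  expect_false(out[4, 4, 4])
  expect_false(any(out[1, , ]))  # boundary eroded
  expect_false(out[5, 4, 4])     # neighbour of the noisy voxel eroded too
})

test_that("rotation to the B0 frame pads, interpolates and inverts cleanly", {
  v <- multiqmap:::smooth_field(c(24, 24, 24), corr_len = 6, seed = 4)
  id <- rotate_to_b0(v, c(0, 0, 1))
  expect_identical(id$volumes[[1]], v)
  b0 <- c(0, sin(0.4), cos(0.4))
  r1 <- rotate_to_b0(v, b0)
  # padded grid retains all mass: nothing clipped at the faces
  vol <- r1$volumes[[1]]
  dd <- dim(vol)
  expect_true(all(dd >= 24))
  expect_lt(max(abs(vol[c(1, dd[1]), , ])), 1e-6)
  expect_lt(max(abs(vol[, c(1, dd[2]), ])), 1e-6)
  r2 <- rotate_to_b0(vol, b0, inverse = TRUE)
  off <- floor((dim(r2$volumes[[1]]) - c(24, 24, 24)) / 2)
  back <- r2$volumes[[1]][off[1] + 1:24, off[2] + 1:24, off[3] + 1:24]
  mm <- erode_k(array(TRUE, c(24, 24, 24)), 3)
  expect_lt(sqrt(mean((back[mm] - v[mm])^2)) / diff(range(v)), 0.02)
})

test_that("the full chain recovers ROI susceptibility at the phantom scale", {
  sub <- fix_subject()
  maps <- fix_maps()
  chi <- maps$QSM
  truth <- sub$truth$QSM
  csf_ok <- (sub$labels == 13) & chi$valid
  tr <- truth - mean(truth[csf_ok])
  errs <- vapply(1:12, function(id) {
    m <- (sub$labels == id) & chi$valid
    mean(chi$data[m]) - mean(tr[m])
  }, 0)
  expect_lt(max(abs(errs)), 0.08)
  # ordering of the extremes is preserved: pallidum is the most
  # paramagnetic ROI in the fit as in the truth
  fitted_means <- vapply(1:12, function(id) {
    mean(chi$data[(sub$labels == id) & chi$valid])
  }, 0)
  expect_equal(which.max(fitted_means), 4L)
})

test_that("scanner-integer phase rescales onto (-pi, pi]", {
  expect_equal(scanner_phase_to_radians(4096), pi)
  expect_equal(scanner_phase_to_radians(-4096), -pi)
  expect_equal(scanner_phase_to_radians(0), 0)
  expect_equal(scanner_phase_to_radians(2048), pi / 2)
})
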