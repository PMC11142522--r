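test_that("EPG train reduces to pure exponential decay at 180 degrees", {
  e <- epg_mese_curve(80, 1000, 1, 12, 6, 180)
  expect_equal(e, exp(-(1:6) * 12 / 80), tolerance = 1e-12)
  # no relaxation: every echo refocuses fully
  e2 <- epg_mese_curve(1e9, 1e9, 1, 12, 6, 180)
  expect_equal(e2, rep(1, 6), tolerance = 1e-6)
  expect_error(epg_mese_curve(-5, 1000, 1, 12, 6, 160), "positive")
})

test_that("EPG agrees with an isochromat Bloch simulation", {
  for (t2 in c(40, 60, 80)) {
    for (b1 in c(0.8, 1.0, 1.2)) {
      epg <- epg_mese_curve(t2, 1000, b1, 12, 12, 160)
      bloch <- bloch_mese_oracle(t2, 1000, b1, 12, 12, 160, n_iso = 201)
      expect_lt(max(abs(epg - bloch) / abs(bloch)), 1e-3)
    }
  }
  # the reference acquisition's white-matter-like voxel in particular
  epg <- epg_mese_curve(58.8, 1000, 1, 12, 12, 160)
  bloch <- bloch_mese_oracle(58.8, 1000, 1, 12, 12, 160)
  expect_lt(max(abs(epg - bloch) / abs(bloch)), 1e-3)
})

test_that("dictionary matching returns the generating grid point", {
  dict <- build_emc_dictionary(t2_grid_ms = c(30, 45, 58.8, 70, 90),
                               b1_grid = c(0.9, 1, 1.1))
  # a dictionary curve itself matches exactly
  k <- which(dict$atom_t2 == 58.8 & dict$atom_b1 == 1)
  dat <- array(rep(7 * dict$curves[, k], each = 4), c(2, 2, 1, 12))
  dat <- aperm(dat, c(1, 2, 3, 4))
  ser <- image_series(dat, "te_ms", seq(12, 144, 12))
  fit <- fit_t2_emc(ser, dict)
  expect_equal(unname(fit$t2$data[1, 1, 1]), 58.8)
  expect_equal(unname(fit$b1$data[1, 1, 1]), 1)
  # noiseless on-grid forward signal recovers the white-matter value
  sig <- epg_mese_curve(58.8, 1000, 1, 12, 12, 160)
  dat2 <- array(rep(sig, each = 1), c(1, 1, 1, 12))
  fit2 <- fit_t2_emc(image_series(dat2, "te_ms", seq(12, 144, 12)), dict)
  expect_equal(unname(fit2$t2$data[1, 1, 1]), 58.8)
  # all-zero voxel is invalid
  dat2[] <- 0
  fit3 <- fit_t2_emc(image_series(dat2, "te_ms", seq(12, 144, 12)), dict)
  expect_false(fit3$t2$valid[1, 1, 1])
  expect_error(fit_t2_emc(image_series(dat2[, , , 1:6, drop = FALSE], "te_ms",
                                       seq(12, 72, 12)), dict), "echo count")
})

test_that("dictionary matching equals a brute-force argmax", {
  dict <- build_emc_dictionary(t2_grid_ms = exp(seq(log(20), log(120), length.out = 40)),
                               b1_grid = seq(0.85, 1.15, 0.05))
  set.seed(42)
  n <- 20
  sig <- multiqmap:::epg_mese_curves(runif(n, 30, 100), 1000, runif(n, 0.9, 1.1),
                                     12, 12, 160)
  sig <- sig * rep(runif(n, 0.5, 2), each = 12)
  dat <- array(t(sig), c(n, 1, 1, 12))
  fit <- fit_t2_emc(image_series(dat, "te_ms", seq(12, 144, 12)), dict)
  for (i in seq_len(n)) {
    v <- sig[, i] / sqrt(sum(sig[, i]^2))
    scores <- as.vector(v %*% dict$curves)
    expect_equal(unname(fit$t2$data[i, 1, 1]), dict$atom_t2[which.max(scores)])
  }
})

test_that("T2* log-linear fit recovers noiseless decays and truncates correctly", {
  te <- seq(5.2, 36.9, length.out = 8)
  mk <- function(s) image_series(array(s, c(1, 1, 1, length(te))), "te_ms", te)
  f <- fit_t2star_loglinear(mk(3 * exp(-te / 49.2)))
  expect_equal(unname(f$data[1, 1, 1]), 49.2, tolerance = 1e-9)
  # T2* = 10 ms: the 10 percent rule retains exactly the echoes predicted
  # by evaluating the threshold directly
  s10 <- exp(-te / 10)
  retained <- sum(s10 >= 0.1 * s10[1])
  expect_equal(retained, 6)
  ols <- lm(log(s10[seq_len(retained)]) ~ te[seq_len(retained)])
  f10 <- fit_t2star_loglinear(mk(s10))
  expect_equal(unname(f10$data[1, 1, 1]), -1 / unname(coef(ols)[2]),
               tolerance = 1e-9)
  # constant signal has zero slope: invalid
  fc <- fit_t2star_loglinear(mk(rep(1, 8)))
  expect_false(fc$valid[1, 1, 1])
  # zero voxel invalid
  fz <- fit_t2star_loglinear(mk(rep(0, 8)))
  expect_false(fz$valid[1, 1, 1])
})

test_that("fitted T2* is strictly increasing in true T2*", {
  te <- seq(5.2, 36.9, length.out = 8)
  truths <- seq(10, 120, by = 5)
  fits <- vapply(truths, function(t2s) {
    s <- exp(-te / t2s)
    f <- fit_t2star_loglinear(image_series(array(s, c(1, 1, 1, 8)), "te_ms", te))
    f$data[1, 1, 1]
  }, 0)
  expect_true(all(diff(fits) > 0))
})

test_that("inversion-recovery T1 fit inverts its own model", {
  ti <- c(200, 400, 1200, 2400)
  # the signed model crosses zero at T1 ln 2
  expect_equal(1 - 2 * exp(-1000 * log(2) / 1000), 0)
  s <- abs(1 - 2 * exp(-ti / 1000))
  ser <- image_series(array(s, c(1, 1, 1, 4)), "ti_ms", ti)
  f <- fit_ir_t1(ser)
  expect_equal(unname(f$t1$data[1, 1, 1]), 1000, tolerance = 1e-6)
  expect_equal(unname(f$a[1, 1, 1]), 1, tolerance = 1e-5)
  expect_equal(unname(f$b[1, 1, 1]), -2, tolerance = 1e-5)
  # different polarity pattern (long T1): still recovered
  s2 <- abs(1 - 2 * exp(-ti / 2400))
  f2 <- fit_ir_t1(image_series(array(s2, c(1, 1, 1, 4)), "ti_ms", ti))
  expect_equal(unname(f2$t1$data[1, 1, 1]), 2400, tolerance = 1e-5)
  # no inversion contrast: unidentifiable
  f3 <- fit_ir_t1(image_series(array(rep(1, 4), c(1, 1, 1, 4)), "ti_ms", ti))
  expect_false(f3$t1$valid[1, 1, 1])
})

test_that("B1+ estimation recovers the flip-angle scale", {
  tr <- 26; t1 <- 1000
  E1 <- exp(-tr / t1)
  alpha <- c(5, 12, 27) * pi / 180
  mkser <- function(cvol) {
    d <- dim(cvol)
    dat <- array(0, c(d, 3))
    for (k in 1:3) dat[, , , k] <- multiqmap:::spgr_shape(cvol * alpha[k], E1)
    image_series(dat, "flip_deg", c(5, 12, 27), tr_ms = tr)
  }
  t1map <- quantitative_map(array(t1, c(8, 8, 8)), "T1")
  # c = 1 everywhere
  b1 <- estimate_b1_from_ir(mkser(array(1, c(8, 8, 8))), t1map)
  expect_equal(max(abs(b1$b1$data - 1)), 0, tolerance = 1e-6)
  # smooth field within [0.85, 1.15], polynomial-representable
  d <- c(16, 16, 16)
  u <- seq(-1, 1, length.out = 16)
  cf <- 1 + outer(u, u, function(a, b) 0.08 * a * b)
  cvol <- array(rep(cf, 16), d) + 0.05 * multiqmap:::kaxis(u, d, 3)^2
  t1m <- quantitative_map(array(t1, d), "T1")
  b1s <- estimate_b1_from_ir(mkser(cvol), t1m)
  expect_lt(max(abs(b1s$b1$data - cvol)), 0.01)
  # grid-search oracle on a two-voxel toy
  cv <- array(c(0.9, 1.1), c(2, 1, 1))
  t1m2 <- quantitative_map(array(t1, c(2, 1, 1)), "T1")
  fitc <- estimate_b1_from_ir(mkser(cv), t1m2, smooth = FALSE)
  grid <- seq(0.3, 1.7, by = 1e-3)
  for (i in 1:2) {
    s <- vapply(1:3, function(k) multiqmap:::spgr_shape(cv[i, 1, 1] * alpha[k], E1), 0)
    rss <- vapply(grid, function(cc) {
      g <- multiqmap:::spgr_shape(cc * alpha, E1)
      sum(s^2) - sum(s * g)^2 / sum(g^2)
    }, 0)
    expect_equal(unname(fitc$b1$data[i, 1, 1]), grid[which.min(rss)],
                 tolerance = 2e-3)
  }
})

test_that("variable-flip-angle T1 fit is exact and monotonic", {
  tr <- 26
  flips <- c(5, 12, 27)
  mk <- function(t1, b1 = 1, m0 = 1) {
    E1 <- exp(-tr / t1)
    s <- m0 * multiqmap:::spgr_shape(b1 * flips * pi / 180, E1)
    image_series(array(s, c(1, 1, 1, 3)), "flip_deg", flips, tr_ms = tr)
  }
  f <- fit_t1_vfa(mk(982))
  expect_equal(unname(f$t1$data[1, 1, 1]), 982, tolerance = 1e-9)
  # with a mis-set transmit field, supplying the correct B1 restores T1
  b1map <- quantitative_map(array(0.9, c(1, 1, 1)), "B1")
  f2 <- fit_t1_vfa(mk(982, b1 = 0.9), b1map)
  expect_equal(unname(f2$t1$data[1, 1, 1]), 982, tolerance = 1e-9)
  expect_equal(unname(f2$m0[1, 1, 1]), 1, tolerance = 1e-9)
  # single flip angle is underdetermined
  one <- image_series(array(0.1, c(1, 1, 1, 1)), "flip_deg", 12, tr_ms = tr)
  expect_error(fit_t1_vfa(one), "two flip angles")
  # monotonicity of fitted T1 in true T1
  fits <- vapply(seq(400, 2400, by = 100), function(t1) {
    fit_t1_vfa(mk(t1))$t1$data[1, 1, 1]
  }, 0)
  expect_true(all(diff(fits) > 0))
})

test_that("water fraction referencing removes a multiplicative bias", {
  d <- c(20, 20, 20)
  u <- seq(-1, 1, length.out = 20)
  X <- multiqmap:::kaxis(u, d, 1); Y <- multiqmap:::kaxis(u, d, 2)
  Z <- multiqmap:::kaxis(u, d, 3)
  csf <- (abs(X) > 0.8) | (abs(Y) > 0.8) | (X^2 + Y^2 + Z^2 < 0.1)
  brain <- array(TRUE, d)
  pd <- array(0.705, d); pd[csf] <- 1
  # uniform bias: exact tissue fractions
  wm0 <- compute_wf_mtvf(pd, csf, brain)
  expect_equal(mean(wm0$wf$data[!csf]), 70.5, tolerance = 1e-9)
  expect_equal(mean(wm0$mtvf$data[!csf]), 29.5, tolerance = 1e-9)
  # identity holds voxelwise
  ok <- wm0$wf$valid
  expect_equal(wm0$wf$data[ok] + wm0$mtvf$data[ok], rep(100, sum(ok)))
  # smooth quadratic bias is removed to within one percentage point
  bias <- exp(0.1 * X + 0.08 * Y^2 - 0.05 * X * Z)
  wm1 <- compute_wf_mtvf(pd * bias, csf, brain)
  expect_lt(max(abs(wm1$wf$data[!csf] - 70.5)), 1)
  expect_error(compute_wf_mtvf(pd, array(FALSE, d), brain), "empty")
})
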