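test_that("packaged gradient set parses with unit directions", {
  sch <- default_gradient_scheme()
  expect_length(sch$bvalues_s_mm2, 65)
  expect_equal(sum(sch$bvalues_s_mm2 == 0), 1)
  nz <- sch$bvalues_s_mm2 > 0
  expect_equal(unname(sqrt(rowSums(sch$directions[nz, ]^2))), rep(1, 64),
               tolerance = 1e-6)
  expect_error(gradient_scheme(c(0, 1000), matrix(0, 1, 3)), "count")
  expect_error(gradient_scheme(c(1000), matrix(0, 1, 3)), "direction")
})

sim_dwi <- function(tensor, scheme, s0 = 1, nvox = 1) {
  n <- length(scheme$bvalues_s_mm2)
  X <- multiqmap:::dti_design(scheme)
  lnS <- as.vector(X %*% c(log(s0), tensor))
  image_series(array(rep(exp(lnS), each = nvox), c(nvox, 1, 1, n)),
               "diffusion", list(bvalues = scheme$bvalues_s_mm2,
                                 directions = scheme$directions))
}

test_that("log-linear tensor fit is exact on noiseless data", {
  sch <- default_gradient_scheme()
  iso <- c(rep(0.8e-3, 3), 0, 0, 0)
  tf <- fit_dti_loglinear(sim_dwi(iso, sch))
  expect_equal(as.vector(tf$tensor[1, ]), iso, tolerance = 1e-9)
  # white-matter-like axially symmetric tensor from (MD, FA)
  ax <- axisym_tensor(7.37e-4, 0.41, c(1, 2, -1))
  tf2 <- fit_dti_loglinear(sim_dwi(ax, sch))
  tm <- tensor_metrics(tf2)
  expect_equal(unname(tm$md$data[1, 1, 1]), 7.37, tolerance = 1e-6)
  expect_equal(unname(tm$fa$data[1, 1, 1]), 0.41, tolerance = 1e-6)
})

test_that("the OLS solution equals an explicit normal-equations solve", {
  dirs <- rbind(c(0, 0, 0), diag(3), c(1, 1, 0) / sqrt(2),
                c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  sch <- gradient_scheme(c(0, rep(1000, 6)), dirs)
  ten <- axisym_tensor(1e-3, 0.3, c(0, 0, 1))
  ser <- sim_dwi(ten, sch, s0 = 2)
  tf <- fit_dti_loglinear(ser)
  X <- multiqmap:::dti_design(sch)
  beta <- solve(t(X) %*% X, t(X) %*% log(as.vector(ser$data[1, 1, 1, ])))
  expect_equal(as.vector(tf$tensor[1, ]), as.vector(beta[2:7]),
               tolerance = 1e-10)
  expect_equal(unname(tf$s0[1]), 2, tolerance = 1e-10)
})

test_that("voxels without enough usable measurements are invalid", {
  dirs <- rbind(c(0, 0, 0), diag(3), c(1, 1, 0) / sqrt(2),
                c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  sch <- gradient_scheme(c(0, rep(1000, 6)), dirs)
  ser <- sim_dwi(axisym_tensor(1e-3, 0.3, c(0, 0, 1)), sch)
  ser$data[1, 1, 1, 3] <- 0   # only 5 usable DW measurements remain
  tf <- fit_dti_loglinear(ser)
  expect_false(tf$valid[1, 1, 1])
})

test_that("scalar invariants match their closed forms", {
  expect_equal(md_from_eigenvalues(1e-3, 1e-3, 1e-3), 1e-3)
  expect_equal(fa_from_eigenvalues(1e-3, 1e-3, 1e-3), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  l <- c(1.5, 0.5, 0.5) * 1e-3
  md <- mean(l)
  fa_direct <- sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
  expect_equal(md_from_eigenvalues(l[1], l[2], l[3]), md)
  expect_equal(fa_from_eigenvalues(l[1], l[2], l[3]), fa_direct)
})

test_that("MD and FA are invariant under rotation of the gradient frame", {
  sch <- default_gradient_scheme()
  ten <- axisym_tensor(9e-4, 0.55, c(1, -1, 2))
  tm1 <- tensor_metrics(fit_dti_loglinear(sim_dwi(ten, sch)))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sch_rot <- gradient_scheme(sch$bvalues_s_mm2, sch$directions %*% t(R))
  # same physical tensor expressed in the rotated frame
  Tm <- matrix(c(ten[1], ten[4], ten[5],
                 ten[4], ten[2], ten[6],
                 ten[5], ten[6], ten[3]), 3, 3)
  Tr <- R %*% Tm %*% t(R)
  ten_rot <- c(Tr[1, 1], Tr[2, 2], Tr[3, 3], Tr[1, 2], Tr[1, 3], Tr[2, 3])
  tm2 <- tensor_metrics(fit_dti_loglinear(sim_dwi(ten_rot, sch_rot)))
  expect_equal(tm1$md$data[1, 1, 1], tm2$md$data[1, 1, 1], tolerance = 1e-10)
  expect_equal(tm1$fa$data[1, 1, 1], tm2$fa$data[1, 1, 1], tolerance = 1e-10)
})

test_that("negative eigenvalues are flagged, not silently clipped", {
  tf <- structure(list(tensor = matrix(c(1e-3, 1e-3, -2e-4, 0, 0, 0), 1, 6),
                       s0 = 1, valid = array(TRUE, c(1, 1, 1)),
                       dim = c(1, 1, 1)), class = "tensor_field")
  tm <- tensor_metrics(tf)
  expect_true(tm$negative_ev[1, 1, 1])
  expect_true(tm$fa$valid[1, 1, 1])
})

test_that("bval/bvec files round-trip through the FSL dialect", {
  sch <- default_gradient_scheme()
  bvec <- tempfile(); bval <- tempfile()
  writeLines(apply(format(t(sch$directions), trim = TRUE), 1, paste,
                   collapse = " "), bvec)
  writeLines(paste(sch$bvalues_s_mm2, collapse = " "), bval)
  sch2 <- read_gradient_scheme(bvec, bval)
  expect_equal(sch2$bvalues_s_mm2, sch$bvalues_s_mm2)
  expect_equal(sch2$directions, sch$directions, tolerance = 1e-6,
               ignore_attr = TRUE)
})
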