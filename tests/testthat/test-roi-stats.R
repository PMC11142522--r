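test_that("single-voxel erosion matches 6-neighbourhood enumeration", {
  lab <- array(0L, c(5, 5, 5))
  lab[2:4, 2:4, 2:4] <- 3L   # solid 3x3x3 cube
  m <- erode_roi(lab, 3)
  expect_equal(sum(m), 1)
  expect_true(m[3, 3, 3])
  # isolated voxel erodes away
  lab2 <- array(0L, c(5, 5, 5)); lab2[3, 3, 3] <- 1L
  expect_equal(sum(erode_roi(lab2, 1)), 0)
  expect_error(erode_roi(lab2, 9), "not present")
  # erosion output is a subset of the input for random shapes
  set.seed(5)
  for (i in 1:5) {
    lab3 <- array(as.integer(runif(6^3) < 0.6), c(6, 6, 6))
    m3 <- erode_roi(lab3, 1)
    expect_true(all(lab3[m3] == 1L))
  }
})

test_that("weak Chauvenet exclusion follows the 3 SD arithmetic", {
  v <- c(rep(1, 19), 10)
  # direct arithmetic: |10 - 1.45| = 8.55 exceeds 3 * 2.0125
  expect_gt(abs(10 - mean(v)), 3 * sd(v))
  cf <- chauvenet_filter(v)
  expect_equal(cf$n_excluded, 1)
  expect_equal(cf$values, rep(1, 19))
  # all-equal vector: nothing excluded
  cf2 <- chauvenet_filter(rep(4, 10))
  expect_equal(cf2$n_excluded, 0)
  # at most one value can sit beyond 3 sample SDs in a 3-element vector
  set.seed(9)
  for (i in 1:50) {
    cf3 <- chauvenet_filter(rnorm(3, sd = runif(1, 0.1, 10)))
    expect_lte(cf3$n_excluded, 1)
  }
})

test_that("Gaussian exclusion fraction is near 2 Phi(-3)", {
  set.seed(123)
  cf <- chauvenet_filter(rnorm(1e5))
  frac <- cf$n_excluded / 1e5
  expect_equal(frac, 2 * pnorm(-3), tolerance = 0.25)
})

test_that("ROI extraction applies zero-removal then outlier exclusion", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- 1L
  m <- erode_roi(lab, 1)            # 8 interior voxels
  vol <- array(0, c(6, 6, 6))
  vol[lab == 1L] <- 5
  rv <- roi_values(vol, lab, 1)
  expect_equal(mean(rv$values), 5)
  expect_equal(sd(rv$values), 0)
  expect_equal(rv$n_voxels, sum(m))
  # brute-force two-stage filter on a toy with zeros and one outlier
  vals <- c(rep(2, 20), 0, 0, 50)
  vol2 <- array(0, c(6, 6, 6))
  idx <- which(m)[1:8]
  vol3 <- array(0, c(8, 8, 8)); lab3 <- array(0L, c(8, 8, 8))
  lab3[2:7, 2:7, 2:7] <- 1L
  m3 <- erode_roi(lab3, 1)
  stopifnot(sum(m3) >= length(vals))
  vol3[which(m3)[seq_along(vals)]] <- vals
  rv3 <- roi_values(vol3, lab3, 1)
  nz <- vals[vals != 0]
  keep <- abs(nz - mean(nz)) <= 3 * sd(nz)
  expect_setequal(rv3$values, nz[keep])
  # voxel count is reported from the filtered map, not the label volume
  expect_equal(rv3$n_voxels, sum(keep))
  expect_lt(rv3$n_voxels, sum(m3))
})

test_that("cohort aggregation separates inter-subject and intra-ROI spread", {
  one <- data.frame(subject = 1, session = 1,
                    map = rep(c("T2", "MTR"), each = 2),
                    roi = rep(c("caudate", "putamen"), 2),
                    n_voxels = c(10, 12, 10, 12),
                    mean = c(50, 52, 14, 15), sd = c(4, 5, 1, 2))
  two <- one; two$subject <- 2
  tab <- summarize_cohort(rbind(one, two))
  expect_equal(tab$sd_inter, rep(0, 4))            # identical subjects
  expect_equal(tab$sd_intra[tab$map == "T2" & tab$roi == "caudate"], 4)
  three <- one; three$subject <- 3; three$mean <- three$mean + 2
  tab2 <- summarize_cohort(rbind(one, two, three))
  expect_equal(tab2$sd_inter[tab2$map == "T2" & tab2$roi == "caudate"],
               sd(c(50, 50, 52)))
  expect_error(summarize_cohort(one), "two subjects")
})

test_that("variability ratio averaging is invariant to grouping", {
  tab <- roi_reference_table()
  pooled <- variability_ratio(tab, by = "pooled")
  bymap <- variability_ratio(tab, by = "map")
  expect_equal(pooled$mean, bymap$mean, tolerance = 1e-12)
})

test_that("hemispheric regression matches its closed form and a permutation test", {
  x <- c(1, 2, 3, 4, 5)
  lr <- lr_regression(x, x)
  expect_equal(lr$slope, 1)
  expect_equal(lr$r, 1)
  expect_equal(lr$p_value, 0)
  expect_error(lr_regression(rep(1, 5), rep(2, 5)), "variance")
  # independent pairs: the t-based p matches a permutation distribution
  set.seed(77)
  n <- 308
  left <- rnorm(n); right <- rnorm(n)
  lr2 <- lr_regression(left, right)
  expect_lt(abs(lr2$r), 0.15)
  nperm <- 4000
  robs <- abs(cor(left, right))
  perm <- vapply(seq_len(nperm), function(i) {
    abs(cor(left, sample(right)))
  }, 0)
  p_perm <- mean(perm >= robs)
  expect_equal(lr2$p_value, p_perm, tolerance = 0.05)
})

test_that("left and right hemisphere means agree on a symmetric phantom", {
  sub <- fix_subject()
  hm <- hemisphere_means(sub$truth$T2, sub$labels, 6)
  expect_false(is.na(hm$left))
  expect_equal(hm$left, hm$right, tolerance = 1e-6)
})

test_that("Bland-Altman statistics follow the limits-of-agreement arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_upper, 0)
  expect_equal(ba0$loa_lower, 0)
  set.seed(3)
  s1 <- rnorm(40, 100, 10); s2 <- s1 + rnorm(40, -2, 3)
  ba <- bland_altman(s1, s2)
  d <- s1 - s2
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  fit <- lm(d ~ I((s1 + s2) / 2))
  expect_equal(ba$slope, unname(coef(fit)[2]))
  expect_error(bland_altman(1:2, 2:3), "3 pairs")
})
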