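test_that("cumulative DVH matches a brute-force sort-and-count oracle exactly", {
  set.seed(19)
  dims <- c(10, 10, 10)
  d <- toy_dose_grid(array(runif(prod(dims), 0, 14), dim = dims))
  mask <- array(runif(prod(dims)) < 0.6, dim = dims)
  mask[1, 1, 1] <- TRUE
  cv <- dvh(d, mask, bin_width = 0.05)
  voxvol <- prod(d$voxel_size) / 1000
  doses <- sort(d$dose[mask])
  oracle <- vapply(cv$curve$dose_gy, function(e) sum(doses >= e) * voxvol,
                   numeric(1))
  expect_identical(cv$curve$volume_cm3, oracle)
  expect_equal(cv$total_volume, sum(mask) * voxvol)
  # curve is non-increasing, starts at total volume
  expect_true(all(diff(cv$curve$volume_cm3) <= 0))
  expect_equal(cv$curve$volume_cm3[1], cv$total_volume)
  # differential form sums back to the total volume
  expect_equal(sum(differential_dvh(cv)$volume_cm3), cv$total_volume)
})

test_that("uniform dose structures have degenerate DVH metrics", {
  dims <- c(20, 20, 20)
  arr <- array(0, dim = dims)
  mask <- array(FALSE, dim = dims)
  mask[3:12, 3:12, 3:12] <- TRUE       # 1 cm^3 at 1 mm voxels... scaled below
  arr[mask] <- 7
  d <- toy_dose_grid(arr, voxel_size = c(2, 2, 2)) # structure = 8 cm^3
  cv <- dvh(d, mask)
  expect_equal(d_percent(cv, 90), 7, tolerance = 1e-12)
  expect_equal(d_percent(cv, 80), 7, tolerance = 1e-12)
  expect_equal(d_2cc(cv), 7, tolerance = 1e-12)
  expect_equal(volume_at_dose(cv, 7), 8, tolerance = 1e-9)
  expect_equal(volume_at_dose(cv, 7.02), 0)
})

test_that("two-voxel structure: V at intermediate dose is half the volume", {
  arr <- array(0, dim = c(2, 1, 1))
  arr[1, 1, 1] <- 4; arr[2, 1, 1] <- 8
  mask <- array(TRUE, dim = c(2, 1, 1))
  d <- toy_dose_grid(arr, voxel_size = c(10, 10, 10)) # 1 cm^3 voxels
  cv <- dvh(d, mask)
  expect_equal(volume_at_dose(cv, 5), 1)
})

test_that("Dx on a linear ramp matches the closed-form quantile", {
  # 1000 equal-volume voxels ramping 0 -> 10 Gy
  doses <- seq(0.005, 9.995, by = 0.01)
  d <- toy_dose_grid(array(doses, dim = c(10, 10, 10)))
  cv <- dvh(d, array(TRUE, dim = c(10, 10, 10)))
  expect_equal(d_percent(cv, 90), 1.0, tolerance = 1e-6)
  expect_equal(d_percent(cv, 80), 2.0, tolerance = 1e-6)
  # monotone: D80 >= D90 on random fields too
  set.seed(4)
  for (i in 1:5) {
    dr <- toy_dose_grid(array(rgamma(1000, 2, 0.5), dim = c(10, 10, 10)))
    cr <- dvh(dr, array(TRUE, dim = c(10, 10, 10)))
    expect_gte(d_percent(cr, 80), d_percent(cr, 90))
  }
})

test_that("D2cc counts absolute hot volume and guards small structures", {
  # 1 cm^3 at 10 Gy + 9 cm^3 at 2 Gy -> hottest 2 cm^3 min dose = 2 Gy
  arr <- array(2, dim = c(10, 1, 1))
  arr[1, 1, 1] <- 10
  d <- toy_dose_grid(arr, voxel_size = c(10, 10, 10))
  cv <- dvh(d, array(TRUE, dim = c(10, 1, 1)))
  expect_equal(d_2cc(cv), 2, tolerance = 1e-12)
  # shrinking the hot region below 2 cm^3 lowers D2cc vs a larger hot region
  arr2 <- arr; arr2[2, 1, 1] <- 10 # 2 cm^3 hot
  cv2 <- dvh(toy_dose_grid(arr2, voxel_size = c(10, 10, 10)),
             array(TRUE, dim = c(10, 1, 1)))
  expect_gt(d_2cc(cv2), d_2cc(cv))
  # structure below 2 cm^3 errors with guidance
  small <- toy_dose_grid(array(5, dim = c(1, 1, 1)), voxel_size = c(10, 10, 10))
  expect_error(d_2cc(dvh(small, array(TRUE, dim = c(1, 1, 1)))),
               "report D")
})

test_that("plan indices equal a brute-force voxel-count oracle", {
  set.seed(23)
  dims <- c(10, 10, 10)
  rx <- 7
  arr <- array(runif(prod(dims), 0, 16), dim = dims)
  ctv <- array(runif(prod(dims)) < 0.3, dim = dims)
  ctv[5, 5, 5] <- TRUE
  d <- toy_dose_grid(arr, rx = rx)
  idx <- plan_indices(d, ctv, rx = rx)
  # independent oracle by direct counting
  n100 <- sum(arr >= rx); n150 <- sum(arr >= 1.5 * rx); n200 <- sum(arr >= 2 * rx)
  nctv <- sum(ctv); n100c <- sum(arr >= rx & ctv)
  expect_identical(idx$ci, n100c / nctv)
  expect_identical(idx$coin, (n100c / nctv) * (n100c / n100))
  expect_identical(idx$dhi, (n100 - n150) / n100)
  expect_identical(idx$dnr, n150 / n100)
  expect_identical(idx$odi, n200 / nctv)
})

test_that("DHI + DNR = 1 identically over random dose fields", {
  set.seed(8)
  for (i in 1:100) {
    dims <- c(8, 8, 8)
    arr <- array(rgamma(prod(dims), shape = 2, rate = 0.3), dim = dims)
    ctv <- array(runif(prod(dims)) < 0.4, dim = dims)
    ctv[1, 1, 1] <- TRUE
    rx <- stats::quantile(arr, runif(1, 0.2, 0.8))
    idx <- plan_indices(toy_dose_grid(arr), ctv, rx = rx)
    expect_identical(idx$dhi + idx$dnr, 1)
    expect_true(idx$ci >= 0 && idx$ci <= 1)
    expect_true(idx$coin >= 0 && idx$coin <= 1)
    expect_gte(idx$odi, 0)
  }
})

test_that("perfectly conformal plans score CI = COIN = 1, DNR = ODI = 0", {
  dims <- c(10, 10, 10)
  ctv <- array(FALSE, dim = dims); ctv[4:7, 4:7, 4:7] <- TRUE
  arr <- array(0, dim = dims); arr[ctv] <- 7
  idx <- plan_indices(toy_dose_grid(arr), ctv, rx = 7)
  expect_equal(idx$ci, 1)
  expect_equal(idx$coin, 1)
  expect_equal(idx$dnr, 0)
  expect_equal(idx$odi, 0)
  # empty prescription isodose errors
  expect_error(plan_indices(toy_dose_grid(arr), ctv, rx = 20), "undefined")
})

test_that("dose scaling with rescaled rx leaves indices invariant", {
  set.seed(15)
  arr <- array(rgamma(1000, 2, 0.3), dim = c(10, 10, 10))
  ctv <- array(runif(1000) < 0.3, dim = c(10, 10, 10)); ctv[1, 1, 1] <- TRUE
  d <- toy_dose_grid(arr)
  k <- 1.37
  i1 <- plan_indices(d, ctv, rx = 6)
  i2 <- plan_indices(scale_dose(d, k), ctv, rx = 6 * k)
  for (f in c("ci", "coin", "dhi", "dnr", "odi")) {
    expect_identical(i1[[f]], i2[[f]])
  }
})

test_that("EQD2 follows the linear-quadratic closed form", {
  # 2 Gy fractions are the fixed point for any alpha/beta
  for (ab in c(0.5, 3, 10)) expect_equal(eqd2(40, 2, ab), 40)
  # oracle: D (d + ab) / (2 + ab)
  expect_equal(eqd2(45, 1.8, 3), 45 * (1.8 + 3) / (2 + 3))
  expect_equal(eqd2(45, 1.8, 3), 43.2, tolerance = 1e-12)
  expect_error(eqd2(45, 1.8, 0), "positive")
  expect_error(eqd2(45, 1.8, -3), "positive")
})

test_that("EQD2 accumulation audits the bladder/rectum constraints", {
  total <- accumulate_eqd2(list(
    list(total_dose = 45, dose_per_fraction = 1.8),
    list(total_dose = 4 * 5.40, dose_per_fraction = 5.40)), alpha_beta = 3)
  expect_equal(total, 43.2 + 21.6 * 8.4 / 5, tolerance = 1e-12)
  expect_lt(total, 80)
  audit <- eqd2_audit(c(bladder = 5.40, rectum = 4.82))
  expect_equal(audit$eqd2_gy[audit$organ == "bladder"], total, tolerance = 1e-12)
  expect_true(all(audit$within_limit))
  # a hot bladder breaches the 80 Gy limit
  hot <- eqd2_audit(c(bladder = 6.2))
  expect_false(hot$within_limit[1])
})

test_that("percent of prescription uses half-up rounding to one decimal", {
  expect_identical(percent_of_rx(7, 7), 100.0)
  expect_identical(percent_of_rx(6.97, 7), 99.6)
  expect_identical(percent_of_rx(5.73, 7), 81.9)
  # half-up at the boundary (banker's rounding would give 81.2)
  expect_identical(percent_of_rx(5.6875, 7), 81.3)
})
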