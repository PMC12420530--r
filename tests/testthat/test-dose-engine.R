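test_that("dose is linear in dwell times and superposes over dwell subsets", {
  ph <- coarse_phantom(voxel = c(5, 5, 5))
  src <- co60_source()
  plan <- brachy_plan(ph$applicator, dwell_times = rep(10, n_dwells(ph$applicator)))
  d1 <- compute_dose(plan, src, ph$structures)

  plan2 <- plan; plan2$dwell_times <- 2 * plan$dwell_times
  d2 <- compute_dose(plan2, src, ph$structures)
  expect_equal(d2$dose, 2 * d1$dose, tolerance = 1e-12)

  # zero dwell times give zero dose
  plan0 <- plan; plan0$dwell_times <- rep(0, n_dwells(ph$applicator))
  expect_true(all(compute_dose(plan0, src, ph$structures)$dose == 0))

  # superposition: dose(A union B) = dose(A) + dose(B)
  half <- seq_len(floor(n_dwells(ph$applicator) / 2))
  pa <- plan; pa$dwell_times[half] <- 0
  pb <- plan; pb$dwell_times[-half] <- 0
  da <- compute_dose(pa, src, ph$structures)
  db <- compute_dose(pb, src, ph$structures)
  expect_equal(da$dose + db$dose, d1$dose, tolerance = 1e-12)
})

test_that("single dwell in flat point mode obeys inverse square exactly", {
  src <- flat_point_source()
  app <- single_dwell_applicator(c(0, 0, 0))
  plan <- brachy_plan(app, dwell_times = 100, relative_loading = 1)
  d <- dose_at_points(plan, src, rbind(c(10, 0, 0), c(20, 0, 0)))
  expect_equal(d[1] / d[2], 4, tolerance = 1e-12)
})

test_that("Point A normalization hits the prescription and is idempotent", {
  ph <- coarse_phantom()
  src <- co60_source()
  plan <- normalize_to_point_a(brachy_plan(ph$applicator), src)
  pa <- manchester_points(plan$applicator)
  expect_equal(mean(dose_at_points(plan, src, pa)), 7, tolerance = 1e-9)
  plan_again <- normalize_to_point_a(plan, src)
  expect_equal(plan_again$dwell_times, plan$dwell_times, tolerance = 1e-12)
  # left/right Point A symmetry of the unperturbed applicator
  d_lr <- dose_at_points(plan, src, pa)
  expect_lt(abs(d_lr[1] / d_lr[2] - 1), 1e-6)
})

test_that("halving source strength doubles dwell times, dose delivered unchanged", {
  ph <- coarse_phantom()
  full <- co60_source(air_kerma_strength = 22700)
  half <- co60_source(air_kerma_strength = 11350)
  p_full <- normalize_to_point_a(brachy_plan(ph$applicator), full)
  p_half <- normalize_to_point_a(brachy_plan(ph$applicator), half)
  expect_equal(p_half$dwell_times, 2 * p_full$dwell_times, tolerance = 1e-12)
  pts <- rbind(c(0, 25, 20), c(0, -30, 10))
  expect_equal(dose_at_points(p_half, half, pts),
               dose_at_points(p_full, full, pts), tolerance = 1e-12)
})

test_that("scale_dose scales Dx metrics exactly and inverts cleanly", {
  set.seed(31)
  d <- toy_dose_grid(array(runif(8000, 0, 12), dim = c(20, 20, 20)))
  mask <- array(TRUE, dim = c(20, 20, 20))
  d90 <- d_percent(dvh(d, mask), 90)
  up <- scale_dose(d, 1.02)
  expect_equal(d_percent(dvh(up, mask), 90) / d90, 1.02, tolerance = 1e-9)
  back <- scale_dose(scale_dose(d, 0.98), 1 / 0.98)
  expect_equal(back$dose, d$dose, tolerance = 1e-12)
  expect_equal(scale_dose(d, 1)$dose, d$dose)
  expect_error(scale_dose(d, 0), "positive")
  expect_error(scale_dose(d, -1), "positive")
})

test_that("shifting applicator and grid together leaves dose untouched", {
  ph <- coarse_phantom(voxel = c(5, 5, 5))
  src <- flat_point_source(sk = 30000)
  plan <- brachy_plan(ph$applicator, dwell_times = rep(20, n_dwells(ph$applicator)))
  base <- compute_dose(plan, src, ph$structures)
  shift <- c(5, -10, 15)
  app2 <- transform_applicator(ph$applicator,
                               rigid_transform(translation = shift))
  ss2 <- ph$structures
  ss2$grid_origin <- ss2$grid_origin + shift
  plan2 <- brachy_plan(app2, dwell_times = plan$dwell_times)
  moved <- compute_dose(plan2, src, ss2)
  expect_equal(moved$dose, base$dose, tolerance = 1e-12)
})

test_that("voxels adjacent to dwells are flagged in-applicator", {
  ph <- coarse_phantom(voxel = c(2, 2, 2))
  src <- co60_source()
  plan <- normalize_to_point_a(brachy_plan(ph$applicator), src)
  dg <- compute_dose(plan, src, ph$structures)
  expect_gt(sum(dg$in_applicator), 0)
  # flagged voxels must lie within r_min of some dwell
  ax <- cobraplan:::grid_axes(dg)
  idx <- which(dg$in_applicator, arr.ind = TRUE)
  pts <- cbind(ax$x[idx[, 1]], ax$y[idx[, 2]], ax$z[idx[, 3]])
  dmin <- apply(pts, 1, function(p) {
    min(sqrt(colSums((t(plan$applicator$dwell_positions) - p)^2)))
  })
  expect_true(all(dmin < cobraplan:::mask_radius_cm(src) * 10))
})

test_that("plan constructor validates dwell times and loading", {
  app <- applicator_model()
  expect_error(brachy_plan(app, dwell_times = rep(0, n_dwells(app))),
               "at least one dwell")
  expect_error(brachy_plan(app, dwell_times = rep(-1, n_dwells(app))))
  expect_error(brachy_plan(app, prescription_dose = 0))
})

test_that("nnls dwell optimizer reproduces achievable target doses", {
  src <- flat_point_source(sk = 50000)
  app <- applicator_model(tandem_dwell_mm = c(10, 30, 50),
                          dwells_per_ovoid = 1)
  plan <- brachy_plan(app)
  targets <- rbind(c(20, 0, 10), c(20, 0, 30), c(-20, 0, 30), c(0, 20, 50))
  want <- c(7, 7, 7, 7)
  opt <- optimize_dwells(plan, src, targets, want)
  got <- dose_at_points(opt, src, targets)
  expect_true(all(opt$dwell_times >= 0))
  expect_lt(max(abs(got - want)), 0.5)
})
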