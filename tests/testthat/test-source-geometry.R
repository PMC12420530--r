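test_that("dose rate at the TG-43 reference point equals Sk * Lambda", {
  src <- co60_source()
  rate <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(10, 0, 0))
  expect_equal(rate, src$air_kerma_strength * src$dose_rate_constant,
               tolerance = 1e-12)
})

test_that("point mode with flat tables is pure inverse square", {
  src <- flat_point_source()
  r1 <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(10, 0, 0))
  r2 <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(20, 0, 0))
  expect_equal(r1 / r2, 4, tolerance = 1e-12)
})

test_that("line-source geometry factor matches segment-integration oracle", {
  # brute force: 200 point sub-sources along the 3.5 mm active length
  L <- 0.35
  oracle_G <- function(r_cm, theta_deg) {
    th <- theta_deg * pi / 180
    x <- r_cm * sin(th); z <- r_cm * cos(th)
    zs <- seq(-L / 2 + L / 400, L / 2 - L / 400, length.out = 200)
    mean(1 / (x^2 + (z - zs)^2))
  }
  ratio_oracle <- oracle_G(2, 90) / oracle_G(1, 90)
  gf <- cobraplan:::geometry_factor
  ratio <- gf(2, 90, L, "line") / gf(1, 90, L, "line")
  expect_lt(abs(ratio / ratio_oracle - 1), 1e-3)
  # and off-axis angles
  for (th in c(30, 60, 120)) {
    expect_lt(abs(gf(1.5, th, L, "line") / oracle_G(1.5, th) /
                    (gf(1, 90, L, "line") / oracle_G(1, 90)) - 1), 1e-3)
  }
})

test_that("line-source kernel anisotropy behaves as expected over theta", {
  # the bare geometry factor is smallest in the transverse plane (field
  # points are farthest from the source ends there) and symmetric
  gf <- cobraplan:::geometry_factor
  th <- seq(5, 175, by = 5)
  g <- gf(rep(1.5, length(th)), th, 0.35, "line")
  expect_equal(th[which.min(g)], 90)
  expect_equal(g, rev(g), tolerance = 1e-12)
  # with the shipped anisotropy table the full dose rate at clinical
  # radii peaks in the transverse plane (F dominates the mild G increase)
  src <- co60_source()
  rate <- vapply(th, function(t) {
    a <- t * pi / 180
    dose_rate_at(src, c(0, 0, 0), c(0, 0, 1),
                 15 * c(sin(a), 0, cos(a)))
  }, numeric(1))
  expect_equal(th[which.max(rate)], 90)
})

test_that("table normalization enforces g(1cm) = 1 and F(r, 90) = 1", {
  rd <- data.frame(r_cm = c(0.5, 1, 2, 5), g = c(1.99, 2.0, 1.98, 1.9))
  an <- expand.grid(r_cm = c(0.5, 1, 5), theta_deg = c(0, 45, 90, 135, 180))
  an$F <- 0.5 * (1 - 0.1 * cos(an$theta_deg * pi / 180)^2)
  src <- source_model(1000, 1.087, 3.5, rd, an)
  expect_equal(cobraplan:::radial_dose_g(src, 1), 1)
  expect_equal(unname(cobraplan:::anisotropy_F(src, c(0.5, 1, 5), rep(90, 3))),
               rep(1, 3))
})

test_that("dose rate errors on bad inputs", {
  src <- co60_source()
  expect_error(dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(0.5, 0, 0)),
               "too close to source")
  expect_error(dose_rate_at(src, c(0, 0, 0), c(0, 0, 2), c(10, 0, 0)),
               "unit vector")
  expect_error(source_model(1000, 1.087, 3.5,
                            data.frame(r_cm = c(1, 1), g = c(1, 1)),
                            expand.grid(r_cm = 1, theta_deg = c(0, 90, 180),
                                        F = 1)),
               "strictly increasing")
})

test_that("rigid transforms: identity, inverse pair, closed-form rotation", {
  pts <- rbind(c(100, 0, 0), c(1, 2, 3))
  expect_equal(apply_transform(rigid_transform(), pts), pts)

  fwd <- rigid_transform(translation = c(1, 0, 0))
  back <- rigid_transform(translation = c(-1, 0, 0))
  expect_equal(apply_transform(back, apply_transform(fwd, pts)), pts)

  # 2 degrees about z, pivot at origin: closed-form cosine/sine
  rot <- rigid_transform(rotation_deg = c(0, 0, 2))
  p <- apply_transform(rot, c(100, 0, 0))
  expect_equal(p, c(100 * cos(2 * pi / 180), 100 * sin(2 * pi / 180), 0),
               tolerance = 1e-12)
  expect_equal(round(p, 3), c(99.939, 3.490, 0))
})

test_that("rotations preserve pairwise distances; inverse composes to identity", {
  set.seed(42)
  pts <- matrix(runif(30, -50, 50), ncol = 3)
  t1 <- rigid_transform(rotation_deg = c(10, -20, 35), pivot = c(5, -3, 2))
  moved <- apply_transform(t1, pts)
  expect_equal(as.vector(stats::dist(moved)), as.vector(stats::dist(pts)),
               tolerance = 1e-12)
  t2 <- rigid_transform(translation = c(4, -7, 1),
                        rotation_deg = c(-5, 12, -40), pivot = c(1, 1, 1))
  roundtrip <- apply_transform(invert_transform(t2), apply_transform(t2, pts))
  expect_lt(max(abs(roundtrip - pts)), 1e-9)
})

test_that("concatenated transforms equal the composed homogeneous matrix", {
  set.seed(7)
  pts <- matrix(runif(15, -40, 40), ncol = 3)
  t1 <- rigid_transform(c(1, -2, 3), c(5, -10, 15), pivot = c(2, 0, -1))
  t2 <- rigid_transform(c(-4, 0, 2), c(-20, 5, 8), pivot = c(0, 3, 1))
  seq_applied <- apply_transform(t2, apply_transform(t1, pts))
  M <- transform_matrix(t2) %*% transform_matrix(t1)
  hom <- cbind(pts, 1) %*% t(M)
  expect_lt(max(abs(seq_applied - hom[, 1:3])), 1e-9)
})

test_that("Manchester Point A pair matches its definition and is equivariant", {
  app <- applicator_model()
  pa <- manchester_points(app)
  expect_equal(pa["A_left", ], c(-20, 0, 20), ignore_attr = TRUE)
  expect_equal(pa["A_right", ], c(20, 0, 20), ignore_attr = TRUE)

  # rotating the applicator rotates Point A identically
  rot <- rigid_transform(rotation_deg = c(0, 0, 90))
  pa_rot <- manchester_points(transform_applicator(app, rot))
  expect_equal(pa_rot, apply_transform(rot, pa), tolerance = 1e-12)

  # arbitrary pose: Point A sits 20*sqrt(2) mm from the os
  t3 <- rigid_transform(c(5, 8, -2), c(12, -7, 31), pivot = c(0, 0, 0))
  app3 <- transform_applicator(app, t3)
  pa3 <- manchester_points(app3)
  d <- sqrt(rowSums(sweep(pa3, 2, app3$os_position)^2))
  expect_equal(unname(d), rep(20 * sqrt(2), 2), tolerance = 1e-9)
})

test_that("applicator validates degenerate axes and keeps ovoid mirror symmetry", {
  expect_error(applicator_model(tandem_axis = c(0, 0, 0)), "degenerate")
  expect_error(applicator_model(lateral_axis = c(0, 0, 1)), "parallel")
  app <- applicator_model(dwells_per_ovoid = 3)
  left <- app$dwell_positions[app$dwell_labels == "ovoid_left", ]
  right <- app$dwell_positions[app$dwell_labels == "ovoid_right", ]
  mirrored <- right; mirrored[, 1] <- -mirrored[, 1]
  expect_equal(left, mirrored, tolerance = 1e-9)
  # tandem dwells colinear with the axis
  tand <- app$dwell_positions[app$dwell_labels == "tandem", ]
  off_axis <- sweep(tand, 2, app$os_position)
  cross_norm <- apply(off_axis, 1, function(v) {
    cx <- c(v[2] * app$tandem_axis[3] - v[3] * app$tandem_axis[2],
            v[3] * app$tandem_axis[1] - v[1] * app$tandem_axis[3],
            v[1] * app$tandem_axis[2] - v[2] * app$tandem_axis[1])
    sqrt(sum(cx^2))
  })
  expect_lt(max(cross_norm), 1e-6)
})
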