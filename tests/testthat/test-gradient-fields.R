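test_that("finite-difference gradient is exact for linear fields", {
  n <- 7
  h <- 0.01
  x <- (seq_len(n) - 1) * h
  X <- array(rep(x, n * n), c(n, n, n))
  Y <- array(rep(rep(x, each = n), n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  vel <- array(0, c(n, n, n, 3))
  vel[, , , 1] <- 2 * X
  vel[, , , 2] <- -3 * Y
  vel[, , , 3] <- 1 * Z
  f <- grid_velocity_field(vel, rep(h, 3))
  gf <- compute_gradient(f)
  # exact everywhere, including one-sided boundaries
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) c(2, -3, 1)[i] else 0
    expect_equal(range(gf$gradient[, , , i, j]), rep(expected, 2),
                 tolerance = 1e-12)
  }

  # plane shear u = (k y, 0, 0)
  f <- make_field("couette", n = 7, params = list(k = 12.5))
  gf <- compute_gradient(f)
  expect_equal(range(gf$gradient[, , , 1, 2]), c(12.5, 12.5),
               tolerance = 1e-12)
  expect_lt(max(abs(gf$gradient[, , , -1, ])), 1e-12)
})

test_that("gradients refuse thin grids and respect the mask stencil rule", {
  vel <- array(0, c(2, 5, 5, 3))
  expect_error(compute_gradient(grid_velocity_field(vel, c(1, 1, 1))),
               "at least 3")

  f <- make_field("couette", n = 9, params = list(k = 100))
  mask <- array(TRUE, f$dims)
  mask[5, 5, 5] <- FALSE           # one interior wall node
  fm <- grid_velocity_field(f$velocity, f$spacing, f$origin, mask = mask)
  gf <- compute_gradient(fm)
  # grid boundary nodes have no full stencil inside a masked grid
  expect_true(all(is.na(gf$gradient[1, , , 1, 2])))
  # the wall node and its 6-neighbourhood are undefined
  expect_false(gf$defined[5, 5, 5])
  expect_false(gf$defined[4, 5, 5])
  expect_false(gf$defined[5, 6, 5])
  expect_true(gf$defined[4, 4, 5])  # diagonal neighbour keeps its stencil
  expect_true(all(is.na(gf$gradient[5, 5, 5, , ])))
  expect_equal(gf$gradient[4, 4, 5, 1, 2], 100, tolerance = 1e-12)

  # mask monotonicity: shrinking the mask never changes surviving values
  mask2 <- mask
  mask2[2:3, 2:3, 2:3] <- FALSE
  gf2 <- compute_gradient(grid_velocity_field(f$velocity, f$spacing, f$origin,
                                              mask = mask2))
  both <- gf2$defined & gf$defined
  expect_true(any(both))
  expect_identical(gf2$gradient[rep(both, 9)], gf$gradient[rep(both, 9)])
})

test_that("gradient and modality fields converge at second order", {
  errs_g <- errs_m <- c()
  for (n in c(17, 33)) {
    f <- make_field("lamb_oseen", n = n)
    gf <- compute_gradient(f)
    m <- decompose_field(gf)
    interior <- array(FALSE, f$dims)
    interior[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
    errs_g <- c(errs_g, mean(abs(gf$gradient - f$exact_gradient)[rep(interior, 9)]))
    idx <- which(interior)
    n3 <- prod(f$dims)
    exact <- triple_magnitudes(vapply(0:8, function(k)
      f$exact_gradient[idx + k * n3], numeric(length(idx))))
    got <- cbind(m$strain[idx], m$rotation[idx], m$shear[idx], m$sss[idx])
    errs_m <- c(errs_m, mean(abs(got - exact)))
  }
  expect_gt(log2(errs_g[1] / errs_g[2]), 1.8)
  expect_gt(log2(errs_m[1] / errs_m[2]), 1.8)
})

test_that("canonical fixtures decompose to their known modality fields", {
  # Couette: pure shear at rate k everywhere
  m <- decompose_field(make_field("couette", n = 9, params = list(k = 100)))
  expect_equal(range(m$shear), c(100, 100), tolerance = 1e-10)
  expect_lt(max(m$rotation), 1e-9)
  expect_lt(max(m$strain), 1e-9)
  expect_equal(range(m$sss), c(100, 100), tolerance = 1e-10)

  # solid-body rotation: rotation sqrt(2) * omega, nothing else
  m <- decompose_field(make_field("solid_rotation", n = 9,
                                  params = list(omega = 50)))
  expect_equal(range(m$rotation), rep(50 * sqrt(2), 2), tolerance = 1e-10)
  expect_lt(max(m$shear), 1e-9)
  expect_lt(max(m$strain), 1e-9)

  # trace-free extensional flow: strain only
  m <- decompose_field(make_field("extensional", n = 9,
                                  params = list(a = 1, b = 2)))
  expect_equal(range(m$strain), rep(sqrt(1 + 4 + 9), 2), tolerance = 1e-9)
  expect_lt(max(m$rotation), 1e-10)
  expect_lt(max(m$shear), 1e-9)

  # round jet: no rotation on the centerline, shear peaks near r = R
  n <- 33
  f <- make_field("round_jet", n = n, params = list(u = 1, r_jet = 0.01,
                                                    delta = 0.002))
  m <- decompose_field(f)
  mid <- (n + 1) / 2
  expect_lt(max(m$rotation[mid, mid, 2:(n - 1)]), 0.05 * max(m$shear, na.rm = TRUE))
  x <- f$origin[1] + (seq_len(n) - 1) * f$spacing[1]
  shear_line <- m$shear[, mid, mid]
  r_at_max <- abs(x[which.max(shear_line)])
  expect_lt(abs(r_at_max - 0.01), 2 * f$spacing[1])
})

test_that("modality magnitudes are homogeneous of degree one in velocity", {
  f <- make_field("lamb_oseen", n = 9)
  f3 <- grid_velocity_field(3 * f$velocity, f$spacing, f$origin, time = f$time)
  m1 <- decompose_field(f)
  m3x <- decompose_field(f3)
  for (nm in c("strain", "rotation", "shear", "sss")) {
    expect_equal(m3x[[nm]], 3 * m1[[nm]], tolerance = 1e-12)
  }
})

test_that("spatial averaging is a volume-weighted mean over defined nodes", {
  # constant field: mean equals the constant regardless of weights
  vals <- array(7.5, c(5, 6, 4))
  expect_equal(spatial_average(fake_modalities(vals))$mean_shear, 7.5)

  # half the domain at c, half at zero, split symmetric in x: mean c/2
  vals <- array(0, c(4, 4, 4))
  vals[1:2, , ] <- 10
  expect_equal(spatial_average(fake_modalities(vals))$mean_strain, 5)

  # seeded random values against a brute-force weight oracle
  set.seed(17)
  d <- c(5, 4, 6)
  vals <- array(runif(prod(d)), d)
  defined <- array(runif(prod(d)) > 0.3, d)
  vals[!defined] <- NA
  got <- spatial_average(fake_modalities(vals, spacing = c(0.1, 0.2, 0.3),
                                         defined = defined))
  w1 <- function(n) c(0.5, rep(1, n - 2), 0.5)
  w <- outer(outer(w1(5), w1(4)), w1(6)) * 0.1 * 0.2 * 0.3
  expect_equal(got$mean_rotation,
               sum(vals[defined] * w[defined]) / sum(w[defined]),
               tolerance = 1e-12)

  empty <- fake_modalities(array(NA_real_, c(3, 3, 3)),
                           defined = array(FALSE, c(3, 3, 3)))
  expect_error(spatial_average(empty), "no defined nodes")
})

test_that("structure extraction labels 26-connected superthreshold blobs", {
  vals <- array(0, c(10, 10, 10))
  vals[2:3, 2:3, 2:3] <- 100          # 8 voxels
  vals[7:9, 7:9, 7:9] <- 100          # 27 voxels
  m <- fake_modalities(vals, spacing = c(1, 1, 1))
  comps <- extract_structures(m, "rotation", 50)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$voxels, c(27, 8))
  expect_equal(comps$centroid_x[1], 7)   # 0-based coords of indices 7:9
  expect_equal(comps$centroid_x[2], 1.5)
  expect_equal(attr(comps, "connectivity"), 26L)

  # threshold above the global maximum: empty table, header columns intact
  expect_equal(nrow(extract_structures(m, "rotation", 1e6)), 0)
  expect_error(extract_structures(m, "vorticity", 1), "unknown modality")
  expect_error(extract_structures(m, "rotation", -1), "non-negative")

  # seeded random binarization against the naive flood-fill oracle
  set.seed(123)
  vals <- array(runif(8^3), c(8, 8, 8))
  m <- fake_modalities(vals)
  comps <- extract_structures(m, "shear", 0.6)
  oracle <- flood_fill_oracle(vals > 0.6)
  expect_equal(nrow(comps), max(oracle))
  expect_equal(comps$voxels, sort(tabulate(oracle[oracle > 0]),
                                  decreasing = TRUE))

  # single rotation core inside quiescent surroundings
  f <- make_field("lamb_oseen", n = 17)
  mm <- decompose_field(f)
  core <- extract_structures(mm, "rotation", 0.5 * max(mm$rotation, na.rm = TRUE))
  expect_equal(nrow(core), 1)
  expect_lt(abs(core$centroid_x[1]), 1e-9)  # centred on the vortex axis
})

test_that("time series assembles per-frame averages in time order", {
  f1 <- make_field("couette", n = 7, params = list(k = 50), time = 0.1)
  ts1 <- time_series(list(f1))
  expect_equal(nrow(ts1), 1)
  expect_equal(ts1$mean_shear, 50, tolerance = 1e-10)

  f2 <- make_field("couette", n = 7, params = list(k = 50), time = 0.2)
  ts2 <- time_series(list(f1, f2))
  expect_equal(ts2$mean_shear, c(50, 50), tolerance = 1e-10)
  expect_equal(ts2$time, c(0.1, 0.2))

  # amplitude ramp: means scale linearly with the ramp
  frames <- lapply(1:4, function(i)
    make_field("round_jet", n = 9, params = list(u = 0.25 * i),
               time = 0.1 * i))
  ts <- time_series(frames)
  expect_true(all(diff(ts$mean_shear) > 0))
  expect_equal(ts$mean_shear, ts$mean_shear[1] * (1:4), tolerance = 1e-9)

  expect_error(time_series(list(f2, f1)), "strictly increasing")
  f3 <- make_field("couette", n = 9, time = 0.3)
  expect_error(time_series(list(f1, f3)), "geometry")
})
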