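test_that("double decomposition splits symmetric and skew parts exactly", {
  g_sym <- diag(c(1, 2, 3))
  d <- double_decompose(g_sym)
  expect_identical(d$spin, matrix(0, 3, 3))
  expect_identical(d$strain_rate, g_sym)

  g_skew <- m3(0, -7, 0, 7, 0, 0, 0, 0, 0)
  d <- double_decompose(g_skew)
  expect_identical(d$strain_rate, matrix(0, 3, 3))
  expect_identical(d$spin, g_skew)

  set.seed(42)
  for (i in 1:20) {
    g <- matrix(rnorm(9, sd = 100), 3, 3)
    d <- double_decompose(g)
    expect_identical(d$strain_rate, t(d$strain_rate))
    expect_identical(d$spin, -t(d$spin))
    expect_equal(d$strain_rate + d$spin, g, tolerance = 1e-15)
  }

  expect_error(double_decompose(m3(0, NA, 0, 0, 0, 0, 0, 0, 0)), "finite")
  expect_error(double_decompose(m3(Inf, 0, 0, 0, 0, 0, 0, 0, 0)), "finite")
  expect_error(double_decompose(matrix(0, 2, 2)), "3x3")
})

test_that("standardized Schur form honours block ordering and sign conventions", {
  # rigid rotation: block already standardized, lambda = 0
  sf <- schur_standardized(m3(0, -3, 0, 3, 0, 0, 0, 0, 0))
  expect_true(sf$has_complex_pair)
  expect_equal(sf$lam, 0, tolerance = 1e-14)
  expect_equal(sf$alpha, 0, tolerance = 1e-14)
  expect_equal(abs(sf$beta), 3, tolerance = 1e-12)
  expect_equal(abs(sf$gamma), 3, tolerance = 1e-12)

  # swap normalization: hand Schur gives block {1, -4}; |beta| >= |gamma|
  # forces beta = -4, gamma = 1
  sf <- schur_standardized(m3(0, 1, 0, -4, 0, 0, 0, 0, 0))
  expect_true(sf$has_complex_pair)
  expect_equal(sf$beta, -4, tolerance = 1e-12)
  expect_equal(sf$gamma, 1, tolerance = 1e-12)
  expect_equal(sf$lam, 0, tolerance = 1e-14)

  # already-triangular real-spectrum input: t recovers g up to ordering,
  # q is a signed permutation
  g <- m3(3, 1, 2, 0, 1, 5, 0, 0, -2)
  sf <- schur_standardized(g)
  expect_false(sf$has_complex_pair)
  expect_equal(sort(diag(sf$t)), sort(diag(g)), tolerance = 1e-12)
  expect_equal(abs(det(sf$q)), 1, tolerance = 1e-12)
  expect_true(all(abs(abs(sf$q)[abs(sf$q) > 1e-10] - 1) < 1e-10))

  # structural invariants over generic tensors
  G <- random_gradient_tensors(200, seed = 7)
  for (i in seq_len(nrow(G))) {
    g <- matrix(G[i, ], 3, 3)
    sf <- schur_standardized(g)
    expect_lt(max(abs(sf$q %*% t(sf$q) - diag(3))), 1e-12)
    expect_lt(max(abs(sf$q %*% sf$t %*% t(sf$q) - g)) / max(abs(g)), 1e-12)
    if (sf$has_complex_pair) {
      expect_identical(sf$t[2, 1], 0)
      expect_identical(sf$t[3, 1], 0)
      expect_equal(sf$t[2, 2], sf$t[3, 3], tolerance = 1e-14)
      expect_gte(abs(sf$beta), abs(sf$gamma))
      expect_gte(sf$gamma, 0)
    } else {
      expect_identical(sf$t[lower.tri(sf$t)], rep(0, 3))
    }
  }
})

test_that("triple decomposition reproduces the canonical closed forms", {
  mags <- function(g) {
    d <- triple_decompose(g)
    c(d$el_mag, d$rr_mag, d$sh_mag)
  }
  # pure single-plane shear
  expect_equal(mags(m3(0, 2, 0, 0, 0, 0, 0, 0, 0)), c(0, 0, 2),
               tolerance = 1e-13)
  # rigid rotation at 3 rad/s
  expect_equal(mags(m3(0, -3, 0, 3, 0, 0, 0, 0, 0)), c(0, 3 * sqrt(2), 0),
               tolerance = 1e-13)
  # trace-free irrotational strain
  expect_equal(mags(diag(c(1, 2, -3))), c(sqrt(14), 0, 0), tolerance = 1e-13)
  # mixed case with real eigenvalues +-2: hand Schur gives t = [[2,3],[0,-2]]
  expect_equal(mags(m3(0, 4, 0, 1, 0, 0, 0, 0, 0)), c(2 * sqrt(2), 0, 3),
               tolerance = 1e-12)
  # mixed rotation + shear from the standardized block beta=-4, gamma=1
  expect_equal(mags(m3(0, 1, 0, -4, 0, 0, 0, 0, 0)), c(0, sqrt(2), 3),
               tolerance = 1e-12)
})

test_that("triple decomposition parts have the prescribed structure", {
  G <- random_gradient_tensors(300, seed = 13)
  for (i in seq_len(nrow(G))) {
    g <- matrix(G[i, ], 3, 3)
    d <- triple_decompose(g)
    # el diagonal, rr only in the (2,3)/(3,2) plane, sh strictly upper
    expect_identical(d$el[upper.tri(d$el) | lower.tri(d$el)], rep(0, 6))
    expect_identical(d$rr + t(d$rr), matrix(0, 3, 3))
    expect_identical(c(d$rr[1, 2], d$rr[1, 3]), c(0, 0))
    expect_identical(d$sh[lower.tri(d$sh, diag = TRUE)], rep(0, 6))
    # parts sum to the Schur form (exact up to one rounding in beta+gamma)
    expect_equal(d$el + d$rr + d$sh, d$schur$t, tolerance = 1e-15)
    if (d$schur$has_complex_pair) {
      expect_equal(d$rr_mag, sqrt(2) * abs(d$schur$gamma), tolerance = 1e-15)
      # el magnitude against independently computed eigenvalues
      ev <- eigen(g, only.values = TRUE)$values
      lam <- Re(ev[abs(Im(ev)) < 1e-9 * max(abs(ev), 1e-300)][1])
      alpha <- Re(ev[which.max(abs(Im(ev)))])
      expect_equal(d$el_mag^2, lam^2 + 2 * alpha^2,
                   tolerance = 1e-9)
    } else {
      expect_identical(d$rr_mag, 0)
    }
  }
})

test_that("reconstruction and frame invariance hold for generic tensors", {
  G <- random_gradient_tensors(500, seed = 99)
  set.seed(31)
  for (i in seq_len(nrow(G))) {
    g <- matrix(G[i, ], 3, 3)
    d <- triple_decompose(g)
    parts <- rotate_to_original_frame(d)
    rec <- parts$el + parts$rr + parts$sh
    expect_lt(max(abs(rec - g)) / max(abs(g)), 1e-10)
    # rotated parts keep their algebraic character and norms
    expect_lt(max(abs(parts$el - t(parts$el))), 1e-10 * max(abs(g)))
    expect_lt(max(abs(parts$rr + t(parts$rr))), 1e-10 * max(abs(g)))
    expect_equal(fro(parts$el), d$el_mag, tolerance = 1e-10)
    expect_equal(fro(parts$rr), d$rr_mag, tolerance = 1e-10)
    expect_equal(fro(parts$sh), d$sh_mag, tolerance = 1e-10)
  }
  # magnitudes invariant under a global orthogonal change of frame
  for (i in 1:100) {
    g <- matrix(G[i, ], 3, 3)
    q <- random_orthogonal()
    d1 <- triple_decompose(g)
    d2 <- triple_decompose(q %*% g %*% t(q))
    expect_equal(c(d1$el_mag, d1$rr_mag, d1$sh_mag),
                 c(d2$el_mag, d2$rr_mag, d2$sh_mag),
                 tolerance = 1e-9)
  }
})

test_that("shear magnitude is ordering-invariant for real-spectrum tensors", {
  # for all-real eigenvalues, sh_mag^2 = ||g||_F^2 - sum(lambda_i^2)
  # regardless of how the Schur form orders the eigenvalues
  set.seed(55)
  for (i in 1:50) {
    r <- matrix(0, 3, 3)
    r[upper.tri(r, diag = TRUE)] <- rnorm(6, sd = 10)
    q <- random_orthogonal()
    g <- q %*% r %*% t(q)
    d <- triple_decompose(g)
    expect_false(d$schur$has_complex_pair)
    expect_equal(d$sh_mag^2, sum(g^2) - sum(diag(r)^2), tolerance = 1e-9)
  }
})

test_that("SSS conflates strain with shear exactly as the closed forms say", {
  # equals the triple shear magnitude for single-plane pure shear
  for (k in c(2, -5, 0.3)) {
    g <- m3(0, k, 0, 0, 0, 0, 0, 0, 0)
    expect_equal(sss(g), abs(k), tolerance = 1e-14)
    expect_equal(sss(g), triple_decompose(g)$sh_mag, tolerance = 1e-12)
  }
  # zero for every skew-symmetric tensor
  set.seed(8)
  for (i in 1:20) {
    a <- matrix(rnorm(9), 3, 3)
    expect_equal(sss(a - t(a)), 0, tolerance = 1e-14)
  }
  # strain contamination: pure strain has sh_mag 0 but SSS sqrt(28)
  g <- diag(c(1, 2, -3))
  expect_equal(sss(g), sqrt(28), tolerance = 1e-14)
  expect_equal(triple_decompose(g)$sh_mag, 0, tolerance = 1e-13)
  # non-negative in general
  G <- random_gradient_tensors(200, seed = 3)
  expect_true(all(apply(G, 1, function(r) sss(matrix(r, 3, 3))) >= 0))
})

test_that("batch magnitudes agree with the scalar route", {
  G <- random_gradient_tensors(250, seed = 21)
  batch <- triple_magnitudes(G)
  for (i in seq_len(nrow(G))) {
    g <- matrix(G[i, ], 3, 3)
    d <- triple_decompose(g)
    expect_equal(unname(batch[i, ]),
                 c(d$el_mag, d$rr_mag, d$sh_mag, sss(g)),
                 tolerance = 1e-12)
  }
  expect_error(triple_magnitudes(matrix(NA_real_, 1, 9)), "finite")
})

test_that("fluid properties validate and default to blood", {
  fl <- fluid_properties()
  expect_equal(fl$density, 1060)
  expect_equal(fl$dynamic_viscosity, 0.0027)
  expect_error(fluid_properties(density = -1), "positive")
  expect_error(fluid_properties(dynamic_viscosity = 0), "positive")
})
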