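test_that("static shift projection reproduces principal values along principal axes", {
  t15 <- csa_tensor(64, 77, 217)
  f <- diag(3)
  expect_equal(static_shift(t15, f, c(0, 0, 1)), 217)
  expect_equal(static_shift(t15, f, c(1, 0, 0)), 64)
  expect_equal(static_shift(t15, f, c(0, 1, 0)), 77)
  expect_error(static_shift(t15, f, c(1, 1, 0)), "unit")
})

test_that("powder averages recover the isotropic shift and zero coupling", {
  t15 <- csa_tensor()
  f <- diag(3)
  # midpoint product quadrature over the sphere, uniform in (cos theta, phi)
  g <- sphere_grid(128)
  shifts <- vapply(seq_len(nrow(g)), function(i) static_shift(t15, f, g[i, ]), numeric(1))
  expect_lt(abs(mean(shifts) - t15$iso), 0.1)
  thetas <- acos(g[, 3]) * 180 / pi
  expect_lt(abs(mean(static_coupling(10.52, thetas))), 0.1)
})

test_that("dipolar coupling follows the second Legendre law", {
  expect_equal(static_coupling(10.52, 0), 10.52)
  expect_equal(static_coupling(10.52, 90), -10.52 / 2)
  expect_lt(abs(static_coupling(10.52, 54.7356)), 1e-4)
  expect_error(static_coupling(-1, 0), "positive")
})

test_that("bicelle scaling has the right limits and reproduces the hand value", {
  expect_equal(observe(217, 119.3, bicelle_model(1, "flipped")), 217)
  expect_equal(observe(217, 119.3, bicelle_model(0, "unflipped")), 119.3)
  # S = 0.85 unflipped: 119.3 - 0.425 * 97.7
  expect_equal(observe(217, 119.3, bicelle_model(0.85, "unflipped")), 77.7775)
  expect_equal(observe(5, 0, bicelle_model(0.8, "unflipped")), -2)
})

test_that("closed-form PISA frequencies match the rotation-matrix brute force", {
  h <- tm_helix()
  t15 <- csa_tensor()
  withr::with_seed(7, {
    for (i in 1:100) {
      tau <- runif(1, 0, 45)
      rho <- runif(1, 0, 360)
      s <- runif(1, 0.5, 1)
      flip <- sample(c("unflipped", "flipped"), 1)
      b <- bicelle_model(s, flip)
      got <- pisa_wheel(h, t15, wheel_params(tau, rho), b)
      want <- oracle_wheel(h, t15, tau, rho, 10.52, s, b$f)
      expect_equal(got$shift_ppm, want[, 1], tolerance = 1e-9)
      expect_equal(got$coupling_khz, want[, 2], tolerance = 1e-9)
    }
  })
})

test_that("an untilted helix collapses to a single wheel point", {
  h <- tm_helix()
  w <- pisa_wheel(h, csa_tensor(), wheel_params(0, 123), bicelle_model())
  expect_lt(diff(range(w$shift_ppm)), 1e-6)
  expect_lt(diff(range(w$coupling_khz)), 1e-6)
  l <- wheel_locus(h, csa_tensor(), wheel_params(0), bicelle_model(), n_points = 24)
  expect_lt(diff(range(l$shift_ppm)), 1e-6)
})

test_that("S = 0 sends every observed frequency to its isotropic value", {
  h <- tm_helix()
  t15 <- csa_tensor()
  w <- pisa_wheel(h, t15, wheel_params(16, 50), bicelle_model(0))
  expect_true(all(abs(w$shift_ppm - t15$iso) < 1e-9))
  expect_true(all(w$coupling_khz < 1e-9))
})

test_that("transmembrane tilts keep all couplings inside the 2-4.5 kHz band", {
  h <- tm_helix()
  b <- bicelle_model(0.85, "unflipped")
  for (tau in c(6, 16)) {
    for (rho in seq(0, 355, by = 5)) {
      w <- pisa_wheel(h, csa_tensor(), wheel_params(tau, rho, 10.52), b)
      expect_true(all(w$coupling_khz >= 2))
      expect_true(all(w$coupling_khz <= 4.5))
    }
  }
})

test_that("per-residue peaks lie exactly on the continuous wheel locus", {
  h <- tm_helix()
  t15 <- csa_tensor()
  b <- bicelle_model()
  wp <- wheel_params(12, 77)
  peaks <- pisa_wheel(h, t15, wp, b)
  ref <- max(2L, floor(h$n_residues / 2))
  az <- function(i) atan2(h$nh[i, 2], h$nh[i, 1]) * 180 / pi
  for (i in peaks$residue) {
    delta <- az(i) - az(ref)
    # locus of the reference residue evaluated at the matching azimuth
    pt <- wheel_locus(
      h, t15, wheel_params(12, 77 + delta), b,
      n_points = 3, reference_residue = ref
    )[1, ]
    k <- which(peaks$residue == i)
    d <- sqrt((pt$shift_ppm - peaks$shift_ppm[k])^2 + (pt$coupling_khz - peaks$coupling_khz[k])^2)
    expect_lt(d, 1e-6)
  }
})

test_that("the wheel locus is closed, periodic and continuous", {
  h <- tm_helix()
  wp <- wheel_params(16, 0)
  l1 <- wheel_locus(h, csa_tensor(), wp, bicelle_model(), n_points = 200)
  # periodicity: rho and rho + 360 coincide (first point vs wrap-around step)
  gaps <- sqrt(diff(c(l1$shift_ppm, l1$shift_ppm[1]))^2 +
    diff(c(l1$coupling_khz, l1$coupling_khz[1]))^2)
  l2 <- wheel_locus(h, csa_tensor(), wp, bicelle_model(), n_points = 800)
  gaps2 <- sqrt(diff(c(l2$shift_ppm, l2$shift_ppm[1]))^2 +
    diff(c(l2$coupling_khz, l2$coupling_khz[1]))^2)
  # denser sampling shrinks the largest jump: continuity
  expect_lt(max(gaps2), max(gaps) / 2)
})

test_that("wheel radius in the coupling dimension grows with tilt on [0, 20]", {
  h <- tm_helix()
  radii <- vapply(seq(0, 20, by = 2), function(tau) {
    w <- pisa_wheel(h, csa_tensor(), wheel_params(tau, 0), bicelle_model())
    diff(range(w$coupling_khz))
  }, numeric(1))
  expect_true(all(diff(radii) >= -1e-9))
})

test_that("1D shift classification applies the stated convention with its tie rule", {
  out <- classify_1d(c(70, 130))
  expect_identical(as.character(out$region), c("surface", "transmembrane"))
  expect_identical(as.character(classify_1d(120)$region), "transmembrane")
  expect_identical(nrow(classify_1d(numeric(0))), 0L)
  # the physics-direction convention is selectable
  rev <- classify_1d(c(70, 130), surface_is = "above")
  expect_identical(as.character(rev$region), c("transmembrane", "surface"))
  expect_match(attr(out, "convention_note"), "opposite")
})
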