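test_that("generators are deterministic under a fixed seed", {
  cons <- sdc4_construct()
  spec <- synth_spec(seed = 13, perturbations = list(`47` = c(0.1, 0.5)))
  expect_identical(gen_hsqc_pair(cons, spec), gen_hsqc_pair(cons, spec))
  h <- tm_helix()
  expect_identical(
    gen_slf(h, csa_tensor(), wheel_params(6), bicelle_model(), spec),
    gen_slf(h, csa_tensor(), wheel_params(6), bicelle_model(), spec)
  )
  expect_identical(
    gen_dimer_slf(h, csa_tensor(), wheel_params(6), wheel_params(16),
      bicelle_model(), spec),
    gen_dimer_slf(h, csa_tensor(), wheel_params(6), wheel_params(16),
      bicelle_model(), spec)
  )
})

test_that("zero noise and no perturbation give identical free and bound lists", {
  cons <- sdc4_construct()
  pair <- gen_hsqc_pair(cons, synth_spec(seed = 1, noise_h = 0, noise_n = 0))
  expect_identical(pair$free, pair$bound)
})

test_that("zero-noise SLF output equals the forward simulation exactly", {
  h <- tm_helix()
  spec <- synth_spec(seed = 5, noise_shift = 0, noise_coupling = 0)
  got <- gen_slf(h, csa_tensor(), wheel_params(9, 33), bicelle_model(), spec)
  want <- pisa_wheel(h, csa_tensor(), wheel_params(9, 33), bicelle_model())
  expect_peaks_equal(got, want, tol = 1e-12)
})

test_that("a zero-noise perturbation propagates exactly through the CSP chain", {
  cons <- sdc4_construct()
  pair <- gen_hsqc_pair(
    cons,
    synth_spec(seed = 1, noise_h = 0, noise_n = 0, perturbations = list(`47` = c(0.1, 0.5)))
  )
  r <- compute_csp(pair$free, pair$bound, alpha = 0.14)
  expect_equal(
    r$scores$csp[r$scores$residue == 47],
    sqrt(0.01 + 0.14 * 0.25),
    tolerance = 1e-12
  )
  expect_true(all(r$scores$csp[r$scores$residue != 47] == 0))
})

test_that("injected noise has the stated spread and is mean-zero", {
  h <- csa_frames(build_helix(-69, -42, 40))
  clean <- pisa_wheel(h, csa_tensor(), wheel_params(12), bicelle_model())
  devs_s <- devs_c <- c()
  for (seed in 1:30) {
    spec <- synth_spec(seed = seed, noise_shift = 0.5, noise_coupling = 0.1)
    noisy <- gen_slf(h, csa_tensor(), wheel_params(12), bicelle_model(), spec)
    devs_s <- c(devs_s, noisy$shift_ppm - clean$shift_ppm)
    devs_c <- c(devs_c, noisy$coupling_khz - clean$coupling_khz)
  }
  n <- length(devs_s)
  expect_equal(sd(devs_s), 0.5, tolerance = 0.1)
  expect_lt(abs(mean(devs_s)), 3 * 0.5 / sqrt(n))
  # couplings are clipped at zero; here all clean values are far from zero
  expect_equal(sd(devs_c), 0.1, tolerance = 0.1)
  expect_lt(abs(mean(devs_c)), 3 * 0.1 / sqrt(n))
})

test_that("perturbations on amide-less residues are rejected", {
  cons <- sdc4_construct()
  expect_error(
    gen_hsqc_pair(cons, synth_spec(perturbations = list(`45` = c(0.1, 0.1)))),
    "proline|amide"
  )
  expect_error(
    gen_hsqc_pair(cons, synth_spec(perturbations = list(`1` = c(0.1, 0.1)))),
    "amide"
  )
})

test_that("identical dimer components double every peak", {
  h <- tm_helix()
  spec <- synth_spec(seed = 8, noise_shift = 0, noise_coupling = 0)
  d <- gen_dimer_slf(
    h, csa_tensor(), wheel_params(10, 20), wheel_params(10, 20),
    bicelle_model(), spec
  )
  expect_identical(nrow(d), 48L)
  a <- d[d$component == 1, c("residue", "shift_ppm", "coupling_khz")]
  b <- d[d$component == 2, c("residue", "shift_ppm", "coupling_khz")]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("label stripping yields unassigned peaks", {
  h <- tm_helix()
  out <- gen_slf(h, csa_tensor(), wheel_params(6), bicelle_model(),
    synth_spec(seed = 2), keep_labels = FALSE)
  expect_true(all(is.na(out$residue)))
})
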