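make_hn <- function(residue, h, n) tibble::tibble(residue = residue, h_ppm = h, n_ppm = n)

test_that("identical peak lists give all-zero CSP", {
  free <- make_hn(2:10, rep(8, 9), rep(120, 9))
  r <- compute_csp(free, free)
  expect_true(all(r$scores$csp == 0))
})

test_that("the standard hand value is reproduced exactly", {
  free <- make_hn(1:2, c(8, 8), c(120, 120))
  bound <- make_hn(1:2, c(8.1, 8), c(120.5, 120))
  r <- compute_csp(free, bound, alpha = 0.14)
  expect_equal(r$scores$csp[1], sqrt(0.01 + 0.14 * 0.25), tolerance = 1e-12)
  expect_equal(round(r$scores$csp[1], 4), 0.2121)
  expect_equal(r$scores$csp[2], 0)
  # the literal no-radical form is selectable
  r2 <- compute_csp(free, bound, alpha = 0.14, sqrt_form = FALSE)
  expect_equal(r2$scores$csp[1], 0.045, tolerance = 1e-12)
})

test_that("CSP is symmetric in the two states and scales linearly", {
  withr::with_seed(9, {
    free <- make_hn(1:10, runif(10, 7.5, 9), runif(10, 105, 130))
    bound <- make_hn(1:10, free$h_ppm + rnorm(10, 0, 0.05), free$n_ppm + rnorm(10, 0, 0.2))
  })
  a <- compute_csp(free, bound)
  b <- compute_csp(bound, free)
  expect_equal(a$scores$csp, b$scores$csp, tolerance = 1e-12)
  # scaling every shift difference by c scales every CSP by c
  bound3 <- make_hn(1:10, free$h_ppm + 3 * (bound$h_ppm - free$h_ppm),
    free$n_ppm + 3 * (bound$n_ppm - free$n_ppm))
  expect_equal(compute_csp(free, bound3)$scores$csp, 3 * a$scores$csp, tolerance = 1e-12)
})

test_that("residues present in only one list are unmatched, not scored", {
  free <- make_hn(1:5, rep(8, 5), rep(120, 5))
  bound <- make_hn(3:7, rep(8, 5), rep(120, 5))
  r <- compute_csp(free, bound)
  expect_identical(r$scores$residue, 3:5)
  expect_identical(r$unmatched_free, 1:2)
  expect_identical(r$unmatched_bound, 6:7)
})

test_that("duplicate assignments and disjoint lists are rejected", {
  free <- make_hn(c(1, 1, 2), rep(8, 3), rep(120, 3))
  good <- make_hn(1:3, rep(8, 3), rep(120, 3))
  expect_error(compute_csp(free, good), "duplicate")
  expect_error(
    compute_csp(make_hn(1:2, c(8, 8), c(120, 120)), make_hn(3:4, c(8, 8), c(120, 120))),
    "no common"
  )
})

test_that("flagging rules behave at their degenerate limits", {
  free <- make_hn(1:6, rep(8, 6), rep(120, 6))
  bound <- make_hn(1:6, rep(8.2, 6), rep(120, 6))
  r <- compute_csp(free, bound)
  # all CSP equal: mean + sd flags nothing
  expect_length(flag_perturbed(r, "mean_plus_sd")$flagged, 0)
  # fixed threshold 0 flags every nonzero residue
  expect_length(flag_perturbed(r, "fixed", value = 0)$flagged, 6)
  expect_error(flag_perturbed(r, "fixed"), "required")
})

test_that("an injected perturbation well above noise is the unique flagged residue", {
  cons <- sdc4_construct()
  hits <- vapply(1:20, function(seed) {
    pair <- gen_hsqc_pair(
      cons,
      synth_spec(seed = seed, perturbations = list(`47` = c(0.1, 0.5)))
    )
    r <- flag_perturbed(compute_csp(pair$free, pair$bound), k = 3)
    identical(r$flagged, 47L)
  }, logical(1))
  expect_identical(sum(hits), 20L)
})

test_that("tidy and glance summarise a CSP result", {
  cons <- sdc4_construct()
  pair <- gen_hsqc_pair(cons, synth_spec(seed = 1, perturbations = list(`47` = c(0.1, 0.5))))
  r <- flag_perturbed(compute_csp(pair$free, pair$bound), k = 3)
  td <- tidy(r, construct = cons)
  expect_true(all(c("residue", "full_number", "label", "csp", "flagged") %in% names(td)))
  # construct position 47 carries full-length number 188 under offset 142
  expect_identical(td$full_number[td$residue == 47], 188L)
  gl <- glance(r)
  expect_identical(gl$n_flagged, 1L)
  expect_identical(gl$n_scored, 54L)
})
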