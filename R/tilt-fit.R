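# precompute per-residue axis matrices for fast repeated wheel evaluation
wheel_precompute <- function(helix, tensor, bicelle, nu_parallel_khz, residues) {
  k <- length(residues)
  E1 <- E2 <- E3 <- NH <- matrix(NA_real_, k, 3)
  for (j in seq_len(k)) {
    i <- residues[j]
    E1[j, ] <- helix$frames[, 1, i]
    E2[j, ] <- helix$frames[, 2, i]
    E3[j, ] <- helix$frames[, 3, i]
    NH[j, ] <- helix$nh[i, ]
  }
  list(
    E1 = E1, E2 = E2, E3 = E3, NH = NH,
    sigma = tensor$sigma, iso = tensor$iso,
    sf = bicelle$s * bicelle$f, nu = nu_parallel_khz,
    residues = residues
  )
}

# peak positions (shift, |coupling|) for all precomputed residues at (tau, rho0)
wheel_eval <- function(pre, tilt_deg, rho0_deg) {
  d <- normal_in_helix_frame(tilt_deg, rho0_deg)
  c1 <- as.vector(pre$E1 %*% d)
  c2 <- as.vector(pre$E2 %*% d)
  c3 <- as.vector(pre$E3 %*% d)
  stat_shift <- pre$sigma[1] * c1^2 + pre$sigma[2] * c2^2 + pre$sigma[3] * c3^2
  stat_coup <- pre$nu * p2(as.vector(pre$NH %*% d))
  cbind(
    shift = pre$iso + pre$sf * (stat_shift - pre$iso),
    coupling = abs(pre$sf * stat_coup)
  )
}

# default normalisation spans: full anisotropy breadth of each axis after
# bicelle scaling, so shift and coupling errors contribute comparably
default_scale <- function(tensor, bicelle, nu_parallel_khz) {
  sfa <- bicelle$s * abs(bicelle$f)
  c(
    ppm_span = (tensor$sigma[3] - tensor$sigma[1]) * sfa,
    khz_span = nu_parallel_khz * sfa
  )
}

check_peaks <- function(x, what) {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame of peaks", what))
  need <- c("shift_ppm", "coupling_khz")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) abort(sprintf("`%s` is empty", what))
  invisible(x)
}

has_labels <- function(x) "residue" %in% names(x) && !anyNA(x$residue)

#' Match simulated to observed SLF peaks
#'
#' Computes the minimum-total-cost one-to-one matching between two peak
#' lists in normalised spectral units: each axis is divided by its span so
#' distances are dimensionless and the two axes contribute comparably. When
#' both lists carry residue labels, matching is constrained to equal labels;
#' otherwise the optimal free assignment over min(n, m) pairs is used.
#'
#' @param simulated,observed Data frames with `shift_ppm`, `coupling_khz`
#'   and optionally `residue`.
#' @param scale Length-2 numeric `c(ppm_span, khz_span)`, both positive.
#' @return A list with `assignment` (tibble: `sim_index`, `obs_index`,
#'   `residue` if labelled, `distance`) and `rmsd` (root-mean-square
#'   normalised distance over matched pairs).
#' @export
match_peaks <- function(simulated, observed, scale) {
  check_peaks(simulated, "simulated")
  check_peaks(observed, "observed")
  if (length(scale) != 2 || any(!is.finite(scale)) || any(scale <= 0)) {
    abort("`scale` must be two positive spans c(ppm_span, khz_span)")
  }
  s_xy <- cbind(simulated$shift_ppm / scale[1], simulated$coupling_khz / scale[2])
  o_xy <- cbind(observed$shift_ppm / scale[1], observed$coupling_khz / scale[2])

  if (has_labels(simulated) && has_labels(observed)) {
    common <- intersect(simulated$residue, observed$residue)
    if (length(common) == 0) abort("no common residue labels to match on")
    si <- match(common, simulated$residue)
    oi <- match(common, observed$residue)
    d <- sqrt(rowSums((s_xy[si, , drop = FALSE] - o_xy[oi, , drop = FALSE])^2))
    assignment <- tibble(
      sim_index = si, obs_index = oi, residue = common, distance = d
    )
  } else {
    cost <- outer(seq_len(nrow(s_xy)), seq_len(nrow(o_xy)), function(i, j) {
      (s_xy[i, 1] - o_xy[j, 1])^2 + (s_xy[i, 2] - o_xy[j, 2])^2
    })
    m <- solve_assignment(cost)
    si <- which(!is.na(m))
    oi <- m[si]
    d <- sqrt(cost[cbind(si, oi)])
    assignment <- tibble(sim_index = si, obs_index = oi, distance = d)
    if (has_labels(simulated)) assignment$residue <- simulated$residue[si]
  }
  list(assignment = assignment, rmsd = sqrt(mean(assignment$distance^2)))
}

# objective rmsd at (tau, rho0) against fixed observed peaks
wheel_objective <- function(pre, observed, scale, labelled) {
  o_xy <- cbind(observed$shift_ppm / scale[1], observed$coupling_khz / scale[2])
  if (labelled) {
    oi <- match(pre$residues, observed$residue)
    keep <- !is.na(oi)
    o_xy <- o_xy[oi[keep], , drop = FALSE]
    keep_idx <- which(keep)
    function(tau, rho) {
      sim <- wheel_eval(pre, tau, rho)
      dx <- sim[keep_idx, 1] / scale[1] - o_xy[, 1]
      dy <- sim[keep_idx, 2] / scale[2] - o_xy[, 2]
      sqrt(mean(dx^2 + dy^2))
    }
  } else {
    function(tau, rho) {
      sim <- wheel_eval(pre, tau, rho)
      s_xy <- cbind(sim[, 1] / scale[1], sim[, 2] / scale[2])
      cost <- outer(seq_len(nrow(s_xy)), seq_len(nrow(o_xy)), function(i, j) {
        (s_xy[i, 1] - o_xy[j, 1])^2 + (s_xy[i, 2] - o_xy[j, 2])^2
      })
      m <- solve_assignment(cost)
      si <- which(!is.na(m))
      sqrt(mean(cost[cbind(si, m[si])]))
    }
  }
}

golden_section <- function(f, lo, hi, tol = 1e-4, max_iter = 80) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  x <- if (f1 <= f2) c1 else c2
  list(x = x, f = min(f1, f2))
}

#' Fit helix tilt and rotation from an SLF peak list
#'
#' Grid search of the PISA forward model over tilt tau and azimuthal
#' rotation rho0, scoring each candidate wheel by the root-mean-square
#' normalised distance of the optimal peak matching ([match_peaks()]),
#' followed by deterministic golden-section refinement about the grid
#' optimum. When the observed peaks are residue-labelled, label-constrained
#' matching is used; otherwise the free minimum-cost assignment.
#'
#' @param observed Data frame of observed peaks (`shift_ppm`,
#'   `coupling_khz`, optional `residue` labels).
#' @param helix A `helix_geometry` (frames attached automatically).
#' @param tensor 15N [csa_tensor()].
#' @param bicelle [bicelle_model()].
#' @param nu_parallel_khz Maximal dipolar coupling, kHz.
#' @param tau_grid,rho_grid Search grids in degrees.
#' @param residues Helix residues to simulate; defaults to the labels of
#'   `observed` when present, otherwise every amide residue.
#' @param scale Normalisation spans `c(ppm_span, khz_span)`; defaults to the
#'   bicelle-scaled anisotropy breadths of the two axes.
#' @param refine Golden-section refinement after the grid search.
#' @return A `tilt_fit` object; see [tidy.tilt_fit()] and
#'   [glance.tilt_fit()].
#' @examples
#' h <- csa_frames(build_helix(-69, -42, 25))
#' obs <- pisa_wheel(h, csa_tensor(), wheel_params(10, 40), bicelle_model())
#' fit <- fit_tilt(obs, h, tau_grid = seq(0, 30, 1))
#' glance(fit)
#' @export
fit_tilt <- function(observed, helix, tensor = csa_tensor(),
                     bicelle = bicelle_model(), nu_parallel_khz = 10.52,
                     tau_grid = seq(0, 30, by = 0.5),
                     rho_grid = seq(0, 355, by = 5),
                     residues = NULL, scale = NULL, refine = TRUE) {
  check_peaks(observed, "observed")
  check_helix(helix)
  if (is.null(helix$frames)) helix <- csa_frames(helix)
  if (length(tau_grid) == 0 || length(rho_grid) == 0) abort("empty search grid")

  labelled <- has_labels(observed)
  if (is.null(residues)) {
    residues <- if (labelled) {
      intersect(2:helix$n_residues, observed$residue)
    } else {
      2:helix$n_residues
    }
  }
  if (length(residues) == 0) abort("no residues to simulate")
  if (is.null(scale)) scale <- default_scale(tensor, bicelle, nu_parallel_khz)

  pre <- wheel_precompute(helix, tensor, bicelle, nu_parallel_khz, residues)
  obj <- wheel_objective(pre, observed, scale, labelled)

  grid <- expand.grid(tau = tau_grid, rho0 = rho_grid)
  grid$rmsd <- mapply(obj, grid$tau, grid$rho0)
  best <- which.min(grid$rmsd)
  tau_hat <- grid$tau[best]
  rho_hat <- grid$rho0[best]
  rmsd_hat <- grid$rmsd[best]

  profile <- as_tibble(grid)
  if (refine) {
    dtau <- if (length(tau_grid) > 1) max(diff(sort(tau_grid))) else 1
    drho <- if (length(rho_grid) > 1) max(diff(sort(rho_grid))) else 5
    for (pass in 1:2) {
      r1 <- golden_section(
        function(t) obj(t, rho_hat),
        max(0, tau_hat - dtau), min(90, tau_hat + dtau)
      )
      tau_hat <- r1$x
      r2 <- golden_section(
        function(r) obj(tau_hat, r),
        rho_hat - drho, rho_hat + drho
      )
      rho_hat <- r2$x
      rmsd_hat <- r2$f
    }
    rho_hat <- rho_hat %% 360
    profile <- dplyr::bind_rows(
      profile,
      tibble(tau = tau_hat, rho0 = rho_hat, rmsd = rmsd_hat)
    )
  }

  sim <- wheel_eval(pre, tau_hat, rho_hat)
  sim_df <- tibble(
    residue = residues, shift_ppm = sim[, 1], coupling_khz = sim[, 2]
  )
  final_match <- match_peaks(
    if (labelled) sim_df else sim_df[, c("shift_ppm", "coupling_khz")],
    observed, scale
  )

  structure(
    list(
      tilt_deg = tau_hat, rho0_deg = rho_hat, rmsd = rmsd_hat,
      profile = profile, assignment = final_match$assignment,
      observed = as_tibble(observed), simulated = sim_df,
      labelled = labelled, scale = scale, n_peaks = nrow(observed),
      helix = helix, tensor = tensor, bicelle = bicelle,
      nu_parallel_khz = nu_parallel_khz
    ),
    class = "tilt_fit"
  )
}

#' @export
print.tilt_fit <- function(x, ...) {
  cat(sprintf(
    "<tilt_fit> tilt = %.2f deg, rho0 = %.1f deg, rmsd = %.4g (%d peaks, %s matching)\n",
    x$tilt_deg, x$rho0_deg, x$rmsd, x$n_peaks,
    if (x$labelled) "label-constrained" else "free"
  ))
  invisible(x)
}

#' Tidy a single-wheel tilt fit
#'
#' @param x A `tilt_fit`.
#' @param ... Unused.
#' @return One-row tibble: `tilt_deg`, `rho0_deg`, `rmsd`, `n_peaks`.
#' @export
tidy.tilt_fit <- function(x, ...) {
  tibble(
    tilt_deg = x$tilt_deg, rho0_deg = x$rho0_deg,
    rmsd = x$rmsd, n_peaks = x$n_peaks
  )
}

#' @rdname tidy.tilt_fit
#' @return For `glance()`: a one-row tibble with fit-quality summaries.
#' @export
glance.tilt_fit <- function(x, ...) {
  tibble(
    tilt_deg = x$tilt_deg, rho0_deg = x$rho0_deg, rmsd = x$rmsd,
    n_peaks = x$n_peaks, n_evaluations = nrow(x$profile),
    labelled = x$labelled
  )
}

#' Fit a two-wheel (dimer) mixture to an SLF peak list
#'
#' Models the observed peaks as the union of two PISA wheels, as expected
#' for a GXXXG-mediated helix dimer whose monomers sit at different tilts.
#' A coarse joint grid search over both (tau, rho0) pairs assigns each
#' observed peak to the nearer wheel; each component is then refined by a
#' local [fit_tilt()] on its assigned peaks, with one reassignment round.
#' Components are returned ordered by tilt.
#'
#' @inheritParams fit_tilt
#' @param coarse_tau,coarse_rho Coarse joint-search grids (degrees).
#' @param refine_span_tau,refine_span_rho Half-widths of the local
#'   refinement grids around each coarse component (degrees).
#' @return A `dimer_fit` object: `fits` (list of two `tilt_fit`),
#'   `assignment` (component index per observed peak), `rmsd`, and an
#'   `empty_component` flag when one wheel captures no peaks.
#' @export
fit_two_wheels <- function(observed, helix, tensor = csa_tensor(),
                           bicelle = bicelle_model(), nu_parallel_khz = 10.52,
                           coarse_tau = seq(0, 30, by = 2),
                           coarse_rho = seq(0, 340, by = 20),
                           refine_span_tau = 3, refine_span_rho = 30,
                           residues = NULL, scale = NULL) {
  check_peaks(observed, "observed")
  if (nrow(observed) < 4) abort("two-wheel fit needs at least 4 peaks")
  check_helix(helix)
  if (is.null(helix$frames)) helix <- csa_frames(helix)
  if (is.null(scale)) scale <- default_scale(tensor, bicelle, nu_parallel_khz)

  labelled <- has_labels(observed)
  sim_residues <- residues
  if (is.null(sim_residues)) {
    sim_residues <- if (labelled) {
      sort(unique(intersect(2:helix$n_residues, observed$residue)))
    } else {
      2:helix$n_residues
    }
  }
  pre <- wheel_precompute(helix, tensor, bicelle, nu_parallel_khz, sim_residues)
  o_xy <- cbind(observed$shift_ppm / scale[1], observed$coupling_khz / scale[2])
  n_obs <- nrow(observed)

  # squared distance from every observed peak to every candidate wheel
  cand <- expand.grid(tau = coarse_tau, rho0 = coarse_rho)
  D2 <- matrix(NA_real_, nrow(cand), n_obs)
  for (w in seq_len(nrow(cand))) {
    sim <- wheel_eval(pre, cand$tau[w], cand$rho0[w])
    s_xy <- cbind(sim[, 1] / scale[1], sim[, 2] / scale[2])
    if (labelled) {
      idx <- match(observed$residue, pre$residues)
      D2[w, ] <- (s_xy[idx, 1] - o_xy[, 1])^2 + (s_xy[idx, 2] - o_xy[, 2])^2
    } else {
      for (i in seq_len(n_obs)) {
        D2[w, i] <- min((s_xy[, 1] - o_xy[i, 1])^2 + (s_xy[, 2] - o_xy[i, 2])^2)
      }
    }
  }

  best_cost <- Inf
  best_pair <- c(1L, 1L)
  for (w1 in seq_len(nrow(cand))) {
    m <- pmin(t(D2), D2[w1, ]) # n_obs x n_cand
    costs <- colSums(m)
    w2 <- which.min(costs)
    if (costs[w2] < best_cost) {
      best_cost <- costs[w2]
      best_pair <- c(w1, w2)
    }
  }

  comp_params <- lapply(best_pair, function(w) c(cand$tau[w], cand$rho0[w]))
  assignment <- apply(rbind(D2[best_pair[1], ], D2[best_pair[2], ]), 2, which.min)

  fits <- vector("list", 2)
  for (round in 1:2) {
    for (k in 1:2) {
      idx <- which(assignment == k)
      if (length(idx) == 0) next
      p <- comp_params[[k]]
      fits[[k]] <- fit_tilt(
        observed[idx, , drop = FALSE], helix, tensor, bicelle, nu_parallel_khz,
        tau_grid = seq(
          max(0, p[1] - refine_span_tau), min(90, p[1] + refine_span_tau),
          by = 0.5
        ),
        rho_grid = seq(p[2] - refine_span_rho, p[2] + refine_span_rho, by = 2.5),
        residues = if (labelled) NULL else sim_residues,
        scale = scale
      )
      comp_params[[k]] <- c(fits[[k]]$tilt_deg, fits[[k]]$rho0_deg)
    }
    # reassign to the nearer refined wheel
    d2k <- matrix(Inf, 2, n_obs)
    for (k in 1:2) {
      if (is.null(fits[[k]])) next
      sim <- wheel_eval(pre, comp_params[[k]][1], comp_params[[k]][2])
      s_xy <- cbind(sim[, 1] / scale[1], sim[, 2] / scale[2])
      if (labelled) {
        idx <- match(observed$residue, pre$residues)
        d2k[k, ] <- (s_xy[idx, 1] - o_xy[, 1])^2 + (s_xy[idx, 2] - o_xy[, 2])^2
      } else {
        for (i in seq_len(n_obs)) {
          d2k[k, i] <- min((s_xy[, 1] - o_xy[i, 1])^2 + (s_xy[, 2] - o_xy[i, 2])^2)
        }
      }
    }
    assignment <- apply(d2k, 2, which.min)
  }

  empty <- vapply(fits, is.null, logical(1)) | tabulate(assignment, 2) == 0
  # order components by fitted tilt
  tilts <- vapply(seq_len(2), function(k) {
    if (is.null(fits[[k]])) Inf else fits[[k]]$tilt_deg
  }, numeric(1))
  ord <- order(tilts)
  fits <- fits[ord]
  empty <- empty[ord]
  assignment <- match(assignment, ord)
  rmsd <- sqrt(mean(pmin(d2k[ord[1], ], d2k[ord[2], ])))

  structure(
    list(
      fits = fits, assignment = assignment, rmsd = rmsd,
      empty_component = empty, observed = as_tibble(observed),
      n_peaks = n_obs
    ),
    class = "dimer_fit"
  )
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat(sprintf("<dimer_fit> %d peaks, overall rmsd = %.4g\n", x$n_peaks, x$rmsd))
  for (k in 1:2) {
    if (is.null(x$fits[[k]]) || x$empty_component[k]) {
      cat(sprintf("  component %d: empty\n", k))
    } else {
      cat(sprintf(
        "  component %d: tilt = %.2f deg, rho0 = %.1f deg (%d peaks)\n",
        k, x$fits[[k]]$tilt_deg, x$fits[[k]]$rho0_deg, sum(x$assignment == k)
      ))
    }
  }
  invisible(x)
}

#' Tidy a two-wheel dimer fit
#'
#' @param x A `dimer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `tilt_deg`,
#'   `rho0_deg`, `rmsd`, `n_peaks`, `empty`.
#' @export
tidy.dimer_fit <- function(x, ...) {
  purrr::map_dfr(1:2, function(k) {
    f <- x$fits[[k]]
    tibble(
      component = k,
      tilt_deg = if (is.null(f)) NA_real_ else f$tilt_deg,
      rho0_deg = if (is.null(f)) NA_real_ else f$rho0_deg,
      rmsd = if (is.null(f)) NA_real_ else f$rmsd,
      n_peaks = sum(x$assignment == k),
      empty = x$empty_component[k]
    )
  })
}

#' @rdname tidy.dimer_fit
#' @export
glance.dimer_fit <- function(x, ...) {
  tibble(
    tilt_1 = if (is.null(x$fits[[1]])) NA_real_ else x$fits[[1]]$tilt_deg,
    tilt_2 = if (is.null(x$fits[[2]])) NA_real_ else x$fits[[2]]$tilt_deg,
    rmsd = x$rmsd, n_peaks = x$n_peaks,
    any_empty = any(x$empty_component)
  )
}
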