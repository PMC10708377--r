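# Shared fixtures and independent oracles for the test suite.

tm_helix <- function(n = 25) csa_frames(build_helix(-69, -42, n))

# --- independent rotation matrices (defined here, not taken from the package)
o_rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
o_rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Brute-force PISA oracle: build the full molecule-to-lab rotation, rotate
# every tensor axis and N-H vector into the lab frame, project onto lab z,
# then bicelle-scale. Independent of the closed-form path in the package.
oracle_wheel <- function(helix, tensor, tilt_deg, rho0_deg, nu_khz, s, f,
                         residues = 2:helix$n_residues) {
  R <- o_rot_y(tilt_deg) %*% o_rot_z(rho0_deg)
  z <- c(0, 0, 1)
  iso <- tensor$iso
  out <- matrix(NA_real_, length(residues), 2)
  for (k in seq_along(residues)) {
    i <- residues[k]
    stat_shift <- 0
    for (ax in 1:3) {
      e_lab <- R %*% helix$frames[, ax, i]
      stat_shift <- stat_shift + tensor$sigma[ax] * sum(e_lab * z)^2
    }
    nh_lab <- R %*% helix$nh[i, ]
    ct <- sum(nh_lab * z)
    stat_coup <- nu_khz * (3 * ct^2 - 1) / 2
    out[k, 1] <- iso + s * f * (stat_shift - iso)
    out[k, 2] <- abs(s * f * stat_coup)
  }
  out
}

# Independent screw-axis oracle: per-pair Kabsch superposition of residue i
# onto i + 1 (N/CA/C atoms), returning per-step twist and rise.
oracle_screw_steps <- function(helix) {
  kab <- function(P, Q) {
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    list(R = R, t = cq - as.vector(R %*% cp))
  }
  n <- helix$n_residues
  t(vapply(seq_len(n - 1), function(i) {
    P <- rbind(helix$n[i, ], helix$ca[i, ], helix$c[i, ])
    Q <- rbind(helix$n[i + 1, ], helix$ca[i + 1, ], helix$c[i + 1, ])
    k <- kab(P, Q)
    ang <- acos(max(-1, min(1, (sum(diag(k$R)) - 1) / 2)))
    ax <- c(
      k$R[3, 2] - k$R[2, 3], k$R[1, 3] - k$R[3, 1], k$R[2, 1] - k$R[1, 2]
    ) / (2 * sin(ang))
    c(twist = ang * 180 / pi, rise = abs(sum(k$t * ax)))
  }, numeric(2)))
}

# Brute-force minimum-cost matching oracle: enumerate all permutations
# (n <= 7), cost = total squared normalised distance over matched pairs.
oracle_match_cost <- function(s_xy, o_xy) {
  ns <- nrow(s_xy); no <- nrow(o_xy)
  stopifnot(max(ns, no) <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  if (ns <= no) {
    for (p in perms(seq_len(no))) {
      sel <- p[seq_len(ns)]
      cost <- sum((s_xy[, 1] - o_xy[sel, 1])^2 + (s_xy[, 2] - o_xy[sel, 2])^2)
      best <- min(best, cost)
    }
  } else {
    for (p in perms(seq_len(ns))) {
      sel <- p[seq_len(no)]
      cost <- sum((s_xy[sel, 1] - o_xy[, 1])^2 + (s_xy[sel, 2] - o_xy[, 2])^2)
      best <- min(best, cost)
    }
  }
  best
}

# equal-area product grid on the unit sphere: midpoints in cos(theta) x phi
sphere_grid <- function(n) {
  u <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
  phi <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] + pi / n
  g <- expand.grid(u = u, phi = phi)
  st <- sqrt(1 - g$u^2)
  cbind(st * cos(g$phi), st * sin(g$phi), g$u)
}

expect_peaks_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$shift_ppm, b$shift_ppm, tolerance = tol)
  expect_equal(a$coupling_khz, b$coupling_khz, tolerance = tol)
}
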