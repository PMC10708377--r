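# Standard backbone geometry (lengths in angstrom, angles in degrees).
# PISA observables depend only weakly on these; they are fixed constants
# except for the N-H length, which is exposed because it sets the dipolar
# coupling scale in some conventions.
BACKBONE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.5
)

# place atom D given A-B-C with bond |C-D|, angle(B,C,D) and torsion(A,B,C,D)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal helix from backbone torsion angles
#'
#' Generates an ideal polyalanine-like backbone (N, C-alpha, C', O, amide H)
#' by iterating standard peptide geometry with fixed torsions, then rigidly
#' transforms the coordinates so the helical screw axis is +z through the
#' origin, with the chain running towards +z. The amide hydrogen is placed in
#' the peptide plane, anti to the carbonyl oxygen of the preceding residue
#' (so residue 1, which has no preceding carbonyl, carries no N-H vector).
#'
#' @param phi,psi Backbone torsion angles in degrees. The syndecan-4
#'   transmembrane helix uses phi = -69, psi = -42.
#' @param n_residues Number of residues (>= 2).
#' @param omega Peptide-bond torsion in degrees; 180 for trans peptide bonds.
#' @param nh_length N-H bond length in angstrom.
#' @return A `helix_geometry` object: coordinate matrices `n`, `ca`, `c`,
#'   `o`, `h` (rows = residues), unit N-H vectors `nh`, the helical `twist`
#'   and `rise` per residue, and `axis = c(0, 0, 1)`.
#' @examples
#' h <- build_helix(-69, -42, 25)
#' h$rise
#' nh_axis_angle(h)
#' @export
build_helix <- function(phi, psi, n_residues, omega = 180, nh_length = 1.02) {
  stop_if_not_number(phi, "phi")
  stop_if_not_number(psi, "psi")
  if (!is_scalar_number(n_residues) || n_residues < 2) {
    abort("`n_residues` must be at least 2")
  }
  n_res <- as.integer(n_residues)
  g <- BACKBONE_GEOM

  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n_res) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n, g$a_ca_c_n, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca, g$a_c_n_ca, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c, g$a_n_ca_c, phi)
  }
  # carbonyl O of residue i: in the peptide plane, anti to N(i+1)
  # (torsion N(i)-CA(i)-C(i)-O = psi + 180)
  for (i in seq_len(n_res)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
  }

  screw <- screw_transform(N, CA, C)
  if (abs(screw$rise) < 1e-6) {
    abort("torsion angles produce a degenerate (zero-rise) trace, not a helix")
  }

  to_canonical <- function(m) sweep(m %*% t(screw$rot), 2, screw$shift, "+")
  N <- to_canonical(N); CA <- to_canonical(CA)
  C <- to_canonical(C); O <- to_canonical(O)

  # amide H: N-H anti to the preceding carbonyl C=O, length nh_length
  H <- matrix(NA_real_, n_res, 3)
  NH <- matrix(NA_real_, n_res, 3)
  for (i in 2:n_res) {
    v <- unit(C[i - 1, ] - O[i - 1, ])
    NH[i, ] <- v
    H[i, ] <- N[i, ] + nh_length * v
  }

  structure(
    list(
      n_residues = n_res, phi = phi, psi = psi, omega = omega,
      nh_length = nh_length,
      n = N, ca = CA, c = C, o = O, h = H, nh = NH,
      axis = c(0, 0, 1),
      twist = screw$twist, rise = screw$rise,
      frames = NULL, beta_deg = NULL
    ),
    class = "helix_geometry"
  )
}

# screw transform superposing residues 1..n-1 onto 2..n (Kabsch over the
# N/CA/C blocks); returns the per-residue twist and rise, plus the rigid
# transform that maps the helix axis onto +z through the origin, axis
# pointing from residue 1 towards residue n.
screw_transform <- function(N, CA, C) {
  n <- nrow(N)
  P <- rbind(N[1:(n - 1), , drop = FALSE], CA[1:(n - 1), , drop = FALSE], C[1:(n - 1), , drop = FALSE])
  Q <- rbind(N[2:n, , drop = FALSE], CA[2:n, , drop = FALSE], C[2:n, , drop = FALSE])
  k <- kabsch(P, Q)
  tr <- (sum(diag(k$R)) - 1) / 2
  ang <- acos(max(-1, min(1, tr)))
  if (sin(ang) < 1e-6) {
    # twist near 0 or 180 deg: the antisymmetric-part formula is singular;
    # take the rotation axis as the null vector of R - I
    s <- svd(k$R - diag(3))
    axis <- s$v[, 3]
    if (ang < 1e-6) {
      if (vnorm(k$t) < 1e-9) return(list(twist = 0, rise = 0))
      axis <- unit(k$t)
    }
  } else {
    axis <- c(
      k$R[3, 2] - k$R[2, 3],
      k$R[1, 3] - k$R[3, 1],
      k$R[2, 1] - k$R[1, 2]
    ) / (2 * sin(ang))
  }
  rise <- sum(k$t * axis)
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
  }
  # point on the axis: component of t perpendicular to the axis satisfies
  # (I - R) p = t_perp for p on the axis
  t_perp <- k$t - rise * axis
  A <- diag(3) - k$R
  p_axis <- tryCatch(
    qr.solve(A + tcrossprod(axis), t_perp),
    error = function(e) c(0, 0, 0)
  )

  # rotation taking the axis to +z
  z <- c(0, 0, 1)
  v <- cross3(axis, z)
  s <- vnorm(v)
  if (s < 1e-12) {
    R_align <- if (sum(axis * z) > 0) diag(3) else rot_x(180)
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R_align <- diag(3) + vx + vx %*% vx * ((1 - sum(axis * z)) / s^2)
  }
  list(
    twist = rad2deg(ang), rise = rise, axis = axis,
    rot = R_align, shift = -as.vector(R_align %*% p_axis)
  )
}

# optimal rotation/translation mapping P onto Q (least squares)
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf(
    "<helix_geometry> %d residues, phi = %g, psi = %g\n  twist %.3f deg/residue, rise %.3f A/residue\n",
    x$n_residues, x$phi, x$psi, x$twist, x$rise
  ))
  if (!is.null(x$frames)) {
    cat(sprintf("  15N CSA frames set (beta = %g deg)\n", x$beta_deg))
  }
  invisible(x)
}

#' Per-residue geometry table for a helix
#'
#' @param x A `helix_geometry`.
#' @param ... Unused.
#' @return A tibble with one row per residue: C-alpha coordinates, the N-H
#'   unit-vector components (NA for residue 1) and the N-H/axis angle.
#' @export
tidy.helix_geometry <- function(x, ...) {
  ang <- rep(NA_real_, x$n_residues)
  for (i in 2:x$n_residues) ang[i] <- fold_angle(vec_angle(x$nh[i, ], x$axis))
  tibble(
    residue = seq_len(x$n_residues),
    ca_x = x$ca[, 1], ca_y = x$ca[, 2], ca_z = x$ca[, 3],
    nh_x = x$nh[, 1], nh_y = x$nh[, 2], nh_z = x$nh[, 3],
    nh_axis_deg = ang
  )
}

#' Angle between the N-H bond and the helical axis
#'
#' For an ideal helix this angle is identical for every interior residue; the
#' mean over interior residues (2 to n-1) is returned. It is the single
#' geometric quantity that sets the size of a PISA wheel: the dipolar
#' coupling of every residue oscillates about the value this angle dictates.
#'
#' @param helix A `helix_geometry`.
#' @return Angle in degrees, folded into \[0, 90\].
#' @export
nh_axis_angle <- function(helix) {
  check_helix(helix)
  idx <- 2:max(2, helix$n_residues - 1L)
  mean(vapply(
    idx,
    function(i) fold_angle(vec_angle(helix$nh[i, ], helix$axis)),
    numeric(1)
  ))
}

#' Attach 15N chemical-shift-tensor frames to a helix
#'
#' Places the per-residue principal-axis frame of the amide 15N chemical
#' shift tensor using the standard orientation convention: the sigma33
#' (least-shielded) axis lies in the peptide plane at `beta_deg` from the
#' N-H bond, rotated towards the N-C' direction; sigma22 is perpendicular to
#' the peptide plane; sigma11 completes the right-handed triad.
#'
#' @param helix A `helix_geometry`.
#' @param beta_deg Angle between the sigma33 axis and the N-H bond (degrees,
#'   0 <= beta < 90). 17 degrees is the common amide value.
#' @return The helix with `frames` populated: a 3 x 3 x n array whose columns
#'   per residue are the sigma11, sigma22, sigma33 axes.
#' @export
csa_frames <- function(helix, beta_deg = 17) {
  check_helix(helix)
  stop_if_not_number(beta_deg, "beta_deg")
  if (beta_deg < 0 || beta_deg >= 90) abort("`beta_deg` must be in [0, 90)")
  n <- helix$n_residues
  frames <- array(NA_real_, c(3, 3, n))
  b <- deg2rad(beta_deg)
  for (i in 2:n) {
    nh <- helix$nh[i, ]
    to_c <- unit(helix$c[i - 1, ] - helix$n[i, ]) # N -> C' of the peptide plane
    normal <- unit(cross3(nh, to_c)) # peptide-plane normal
    in_plane <- unit(to_c - sum(to_c * nh) * nh) # in-plane, perpendicular to N-H
    e33 <- unit(cos(b) * nh + sin(b) * in_plane)
    e22 <- normal
    e11 <- cross3(e22, e33)
    frames[, , i] <- cbind(e11, e22, e33)
  }
  helix$frames <- frames
  helix$beta_deg <- beta_deg
  helix
}

check_helix <- function(x, need_frames = FALSE) {
  if (!inherits(x, "helix_geometry")) abort("expected a `helix_geometry` object")
  if (need_frames && is.null(x$frames)) {
    abort("helix has no CSA frames; call `csa_frames()` first")
  }
  invisible(x)
}

#' Write a helix backbone as a PDB file (for visual inspection)
#'
#' @param helix A `helix_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(helix, path) {
  check_helix(helix)
  lines <- character(0)
  serial <- 0L
  fmt <- "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  for (i in seq_len(helix$n_residues)) {
    atoms <- list(
      c(" N", "N"), c(" CA", "C"), c(" C", "C"), c(" O", "O"), c(" H", "H")
    )
    coords <- list(helix$n[i, ], helix$ca[i, ], helix$c[i, ], helix$o[i, ], helix$h[i, ])
    for (k in seq_along(atoms)) {
      if (anyNA(coords[[k]])) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        fmt, serial, atoms[[k]][1], i,
        coords[[k]][1], coords[[k]][2], coords[[k]][3], atoms[[k]][2]
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
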