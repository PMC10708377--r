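#' Chemical shift anisotropy tensor
#'
#' Holds the three principal values of a CSA tensor in ppm, canonically
#' ordered sigma11 <= sigma22 <= sigma33, with the isotropic shift derived as
#' their mean.
#'
#' The default is the amide 15N tensor used for syndecan-4 PISA-wheel
#' simulation: sigma11 = 64 ppm, sigma22 = 77 ppm (88 ppm is the common
#' alternative), and sigma33 = 217 ppm, a standard literature amide value.
#' The amide 1H tensor (3, 8, 17 ppm) can be represented with the same
#' constructor.
#'
#' @param sigma11,sigma22,sigma33 Principal values in ppm. Reordered to the
#'   canonical sigma11 <= sigma22 <= sigma33 if given otherwise.
#' @return A `csa_tensor` object with fields `sigma` (length-3 vector) and
#'   `iso`.
#' @examples
#' csa_tensor() # 15N amide default
#' csa_tensor(3, 8, 17) # 1H amide
#' @export
csa_tensor <- function(sigma11 = 64, sigma22 = 77, sigma33 = 217) {
  for (v in list(sigma11, sigma22, sigma33)) stop_if_not_number(v, "sigma")
  sigma <- sort(c(sigma11, sigma22, sigma33))
  structure(
    list(sigma = sigma, iso = mean(sigma)),
    class = "csa_tensor"
  )
}

#' @export
print.csa_tensor <- function(x, ...) {
  cat(sprintf(
    "<csa_tensor> sigma = (%g, %g, %g) ppm, iso = %.4g ppm\n",
    x$sigma[1], x$sigma[2], x$sigma[3], x$iso
  ))
  invisible(x)
}

#' Magnetically aligned bicelle model
#'
#' A bicelle aligned in the magnet scales every anisotropic frequency
#' deviation by the product of its order parameter S and an alignment factor
#' f. An unflipped bicelle (bilayer normal perpendicular to the field, the
#' spontaneous alignment of DMPC/DHPC-type mixtures) gives f = -1/2 from
#' fast rotational diffusion about the field; a flipped bicelle (normal
#' parallel to the field, e.g. lanthanide-doped) gives f = +1.
#'
#' @param order_parameter S in \[0, 1\]; 0.85 is the upper end of the range
#'   typical for q ~ 3 bicelles.
#' @param flip `"unflipped"` or `"flipped"`.
#' @return A `bicelle_model` with fields `s` and `f`.
#' @export
bicelle_model <- function(order_parameter = 0.85, flip = c("unflipped", "flipped")) {
  stop_if_not_number(order_parameter, "order_parameter")
  if (order_parameter < 0 || order_parameter > 1) {
    abort("`order_parameter` must be in [0, 1]")
  }
  flip <- match.arg(flip)
  structure(
    list(
      s = order_parameter,
      flip = flip,
      f = if (flip == "flipped") 1 else -0.5
    ),
    class = "bicelle_model"
  )
}

#' @export
print.bicelle_model <- function(x, ...) {
  cat(sprintf("<bicelle_model> S = %g, %s (f = %g)\n", x$s, x$flip, x$f))
  invisible(x)
}

#' PISA-wheel parameters
#'
#' Orientation of a helix in the bilayer and the dipolar-coupling scale.
#'
#' @param tilt_deg Tilt tau of the helix axis from the bilayer normal,
#'   degrees in \[0, 90\].
#' @param rho0_deg Azimuthal rotation rho0 of the helix about its own axis,
#'   degrees in \[0, 360).
#' @param nu_parallel_khz Maximal static 1H-15N dipolar coupling in kHz;
#'   10.52 kHz corresponds to an effective N-H distance of 1.066 angstrom.
#' @return A `wheel_params` object.
#' @export
wheel_params <- function(tilt_deg, rho0_deg = 0, nu_parallel_khz = 10.52) {
  stop_if_not_number(tilt_deg, "tilt_deg")
  stop_if_not_number(rho0_deg, "rho0_deg")
  stop_if_not_number(nu_parallel_khz, "nu_parallel_khz")
  if (tilt_deg < 0 || tilt_deg > 90) abort("`tilt_deg` must be in [0, 90]")
  if (nu_parallel_khz <= 0) abort("`nu_parallel_khz` must be positive")
  structure(
    list(
      tilt_deg = tilt_deg,
      rho0_deg = rho0_deg %% 360,
      nu_parallel_khz = nu_parallel_khz
    ),
    class = "wheel_params"
  )
}

#' @export
print.wheel_params <- function(x, ...) {
  cat(sprintf(
    "<wheel_params> tilt = %g deg, rho0 = %g deg, nu_par = %g kHz\n",
    x$tilt_deg, x$rho0_deg, x$nu_parallel_khz
  ))
  invisible(x)
}

check_tensor <- function(x) {
  if (!inherits(x, "csa_tensor")) abort("expected a `csa_tensor` object")
  invisible(x)
}

check_bicelle <- function(x) {
  if (!inherits(x, "bicelle_model")) abort("expected a `bicelle_model` object")
  invisible(x)
}

check_wheel <- function(x) {
  if (!inherits(x, "wheel_params")) abort("expected a `wheel_params` object")
  invisible(x)
}
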