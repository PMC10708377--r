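#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif rnorm sd setNames
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# angle between two vectors in degrees, in [0, 180]
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# fold an axis/vector angle into [0, 90] (axes have no sign)
fold_angle <- function(theta_deg) pmin(theta_deg, 180 - theta_deg)

rot_x <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

rot_y <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# second Legendre polynomial of cos(theta)
p2 <- function(cos_theta) (3 * cos_theta^2 - 1) / 2

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, what) {
  if (!is_scalar_number(x)) abort(sprintf("`%s` must be a single finite number", what))
  invisible(x)
}
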