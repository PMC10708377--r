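#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_col
#'   geom_hline geom_segment scale_x_reverse labs theme_minimal
NULL

#' Plot a CSP profile
#'
#' Per-residue chemical-shift-perturbation bar plot with the flagging
#' threshold; flagged residues are highlighted.
#'
#' @param object A `csp_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csp_result <- function(object, ...) {
  df <- object$scores
  df$flagged <- if ("flagged" %in% names(df)) df$flagged else FALSE
  p <- ggplot(df, aes(x = .data$residue, y = .data$csp, fill = .data$flagged)) +
    geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(
      x = "construct residue", y = "CSP (ppm)",
      title = "Chemical shift perturbation"
    ) +
    theme_minimal()
  if (!is.na(object$threshold_value)) {
    p <- p + geom_hline(
      yintercept = object$threshold_value,
      linetype = "dashed", colour = "grey30"
    )
  }
  p
}

#' Plot a tilt fit as a PISA-wheel overlay
#'
#' Observed peaks, the fitted continuous wheel locus, and the fitted
#' per-residue peak positions, on conventional NMR axes (15N shift
#' decreasing to the right).
#'
#' @param object A `tilt_fit`.
#' @param n_points Locus sampling density.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tilt_fit <- function(object, n_points = 360, ...) {
  locus <- wheel_locus(
    object$helix, object$tensor,
    wheel_params(object$tilt_deg, object$rho0_deg, object$nu_parallel_khz),
    object$bicelle,
    n_points = n_points
  )
  ggplot(mapping = aes(x = .data$shift_ppm, y = .data$coupling_khz)) +
    geom_path(data = locus, colour = "steelblue") +
    geom_point(data = object$simulated, colour = "steelblue", size = 1.5) +
    geom_point(data = object$observed, shape = 4, colour = "black") +
    scale_x_reverse() +
    labs(
      x = "15N chemical shift (ppm)", y = "|1H-15N dipolar coupling| (kHz)",
      title = sprintf(
        "PISA wheel fit: tilt %.1f deg, rho0 %.0f deg",
        object$tilt_deg, object$rho0_deg
      )
    ) +
    theme_minimal()
}

#' Plot a two-wheel dimer fit
#'
#' @param object A `dimer_fit`.
#' @param helix,tensor,bicelle,nu_parallel_khz Model used for the loci;
#'   defaults are taken from the component fits.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dimer_fit <- function(object, helix = NULL, tensor = NULL,
                               bicelle = NULL, nu_parallel_khz = NULL, ...) {
  f1 <- object$fits[[1]]
  loci <- purrr::map_dfr(1:2, function(k) {
    f <- object$fits[[k]]
    if (is.null(f)) return(NULL)
    l <- wheel_locus(
      helix %||% f$helix, tensor %||% f$tensor,
      wheel_params(
        f$tilt_deg, f$rho0_deg,
        nu_parallel_khz %||% f$nu_parallel_khz
      ),
      bicelle %||% f$bicelle
    )
    l$component <- factor(k)
    l
  })
  obs <- object$observed
  obs$component <- factor(object$assignment)
  ggplot(mapping = aes(x = .data$shift_ppm, y = .data$coupling_khz)) +
    geom_path(data = loci, aes(colour = .data$component)) +
    geom_point(data = obs, aes(colour = .data$component), shape = 4) +
    scale_x_reverse() +
    labs(
      x = "15N chemical shift (ppm)", y = "|1H-15N dipolar coupling| (kHz)",
      title = "Two-wheel dimer fit"
    ) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
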