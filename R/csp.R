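check_hn_peaks <- function(x, what) {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame of H-N peaks", what))
  need <- c("residue", "h_ppm", "n_ppm")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (anyNA(x$residue)) abort(sprintf("`%s` must be residue-assigned (no NA labels)", what))
  dup <- x$residue[duplicated(x$residue)]
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate residue assignment(s) in `%s`: %s",
      what, paste(unique(dup), collapse = ", ")
    ))
  }
  if (any(!is.finite(x$h_ppm)) || any(!is.finite(x$n_ppm))) {
    abort(sprintf("`%s` contains non-finite shifts", what))
  }
  if (any(x$h_ppm < 5 | x$h_ppm > 12) || any(x$n_ppm < 100 | x$n_ppm > 135)) {
    warn(sprintf(
      "`%s` has shifts outside the typical amide windows (1H 5-12, 15N 100-135 ppm)",
      what
    ))
  }
  invisible(x)
}

#' Chemical shift perturbation between two HSQC peak lists
#'
#' For every residue assigned in both lists, computes the combined
#' perturbation CSP_i = sqrt(dH_i^2 + alpha * dN_i^2), where dH and dN are
#' the 1H and 15N shift changes between the free and ligand-bound states and
#' alpha down-weights the wider nitrogen scale. Residues present in only one
#' list are reported as unmatched, not scored.
#'
#' @param free,bound Data frames with `residue`, `h_ppm`, `n_ppm`; both
#'   must be residue-assigned with no duplicates.
#' @param alpha Nitrogen weighting constant (> 0); 0.14 is the
#'   field-standard value for backbone amides.
#' @param sqrt_form Apply the square root (the standard CSP definition).
#'   `FALSE` returns the bare quadratic form dH^2 + alpha dN^2 for
#'   comparison with sources that print the formula without a radical.
#' @return A `csp_result`: per-residue tibble (`residue`, `d_h`, `d_n`,
#'   `csp`), the unmatched residues of each list, and `alpha`. Flags are
#'   added by [flag_perturbed()].
#' @examples
#' free <- tibble::tibble(residue = 1:3, h_ppm = c(8, 8.2, 7.9), n_ppm = c(120, 118, 122))
#' bound <- dplyr::mutate(free, h_ppm = h_ppm + c(0, 0.1, 0), n_ppm = n_ppm + c(0, 0.5, 0))
#' compute_csp(free, bound)
#' @export
compute_csp <- function(free, bound, alpha = 0.14, sqrt_form = TRUE) {
  check_hn_peaks(free, "free")
  check_hn_peaks(bound, "bound")
  stop_if_not_number(alpha, "alpha")
  if (alpha <= 0) abort("`alpha` must be positive")

  common <- intersect(free$residue, bound$residue)
  if (length(common) == 0) abort("no common residues between the two lists")
  fi <- match(common, free$residue)
  bi <- match(common, bound$residue)
  d_h <- bound$h_ppm[bi] - free$h_ppm[fi]
  d_n <- bound$n_ppm[bi] - free$n_ppm[fi]
  q <- d_h^2 + alpha * d_n^2
  csp <- if (sqrt_form) sqrt(q) else q

  scores <- tibble(residue = common, d_h = d_h, d_n = d_n, csp = csp) |>
    dplyr::arrange(.data$residue)

  structure(
    list(
      scores = scores,
      unmatched_free = setdiff(free$residue, common),
      unmatched_bound = setdiff(bound$residue, common),
      alpha = alpha, sqrt_form = sqrt_form,
      rule = NULL, threshold_value = NA_real_, flagged = integer(0)
    ),
    class = "csp_result"
  )
}

#' Flag significantly perturbed residues
#'
#' @param result A `csp_result` from [compute_csp()].
#' @param rule `"mean_plus_sd"` flags residues with CSP above
#'   mean + k * sd over all scored residues (the usual practice when no
#'   absolute threshold is calibrated); `"fixed"` flags CSP above `value`.
#' @param k Multiplier for the standard deviation (mean_plus_sd rule).
#' @param value Absolute CSP threshold in ppm (fixed rule).
#' @return The `csp_result` with `threshold_value`, `rule` and `flagged`
#'   populated (and a `flagged` column in its score table).
#' @export
flag_perturbed <- function(result, rule = c("mean_plus_sd", "fixed"), k = 1, value = NULL) {
  if (!inherits(result, "csp_result")) abort("expected a `csp_result`")
  rule <- match.arg(rule)
  if (nrow(result$scores) == 0) abort("no CSP values to flag")
  if (rule == "mean_plus_sd") {
    stop_if_not_number(k, "k")
    thr <- mean(result$scores$csp) + k * sd(result$scores$csp)
    if (is.na(thr)) thr <- mean(result$scores$csp) # single residue: sd undefined
  } else {
    if (is.null(value)) abort("`value` is required for the fixed rule")
    stop_if_not_number(value, "value")
    thr <- value
  }
  result$rule <- rule
  result$threshold_value <- thr
  result$flagged <- result$scores$residue[result$scores$csp > thr]
  result$scores$flagged <- result$scores$csp > thr
  result
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf(
    "<csp_result> %d residues scored (alpha = %g%s), %d unmatched\n",
    nrow(x$scores), x$alpha,
    if (x$sqrt_form) "" else ", no-sqrt form",
    length(x$unmatched_free) + length(x$unmatched_bound)
  ))
  if (!is.null(x$rule)) {
    cat(sprintf(
      "  %s threshold %.4g ppm: %d residue(s) flagged%s\n",
      x$rule, x$threshold_value, length(x$flagged),
      if (length(x$flagged) > 0) {
        paste0(" (", paste(x$flagged, collapse = ", "), ")")
      } else ""
    ))
  }
  invisible(x)
}

#' Per-residue CSP table
#'
#' @param x A `csp_result`.
#' @param construct Optional `nmr_construct` used to add full-length residue
#'   numbers and labels.
#' @param ... Unused.
#' @return Tibble with `residue`, `d_h`, `d_n`, `csp` (and `flagged` after
#'   [flag_perturbed()]; `full_number`/`label` when a construct is given).
#' @export
tidy.csp_result <- function(x, construct = NULL, ...) {
  out <- x$scores
  if (!is.null(construct)) {
    m <- map_residue(construct, out$residue)
    out <- dplyr::left_join(out, m, by = "residue") |>
      dplyr::relocate("aa", "full_number", "label", .after = "residue")
  }
  out
}

#' @rdname tidy.csp_result
#' @export
glance.csp_result <- function(x, ...) {
  tibble(
    n_scored = nrow(x$scores),
    n_unmatched = length(x$unmatched_free) + length(x$unmatched_bound),
    mean_csp = mean(x$scores$csp),
    sd_csp = sd(x$scores$csp),
    max_csp = max(x$scores$csp),
    alpha = x$alpha,
    threshold_value = x$threshold_value,
    n_flagged = length(x$flagged)
  )
}
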