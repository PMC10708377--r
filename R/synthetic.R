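#' Specification for synthetic peak-list generation
#'
#' Bundles the random seed, per-axis Gaussian noise levels and localised
#' perturbations used by the synthetic generators. The defaults emulate the
#' measurement precision of the experiments the generators stand in for:
#' HSQC peak positions are reproducible to roughly 0.01 ppm (1H) and
#' 0.05 ppm (15N), while oriented-sample SLF peaks carry far larger
#' uncertainties (0.5 ppm in the 15N shift, 0.1 kHz in the coupling) from
#' linewidth and mosaic spread.
#'
#' @param seed Integer seed; the same spec always generates identical lists.
#' @param noise_h,noise_n Gaussian sd (ppm) for the HSQC 1H and 15N axes.
#' @param noise_shift,noise_coupling Gaussian sd for the SLF axes
#'   (ppm, kHz).
#' @param perturbations Named list mapping construct residue index (as a
#'   name, e.g. `"47"`) to `c(d_h, d_n)` shift changes in ppm applied to the
#'   bound state.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(seed = 1L, noise_h = 0.01, noise_n = 0.05,
                       noise_shift = 0.5, noise_coupling = 0.1,
                       perturbations = list()) {
  for (v in list(noise_h, noise_n, noise_shift, noise_coupling)) {
    stop_if_not_number(v, "noise sd")
    if (v < 0) abort("noise sds must be >= 0")
  }
  if (!is_scalar_number(seed) || seed != round(seed)) abort("`seed` must be an integer")
  if (length(perturbations) > 0) {
    if (is.null(names(perturbations)) || any(!nzchar(names(perturbations)))) {
      abort("`perturbations` must be named by residue index")
    }
    for (p in perturbations) {
      if (length(p) != 2 || any(!is.finite(p))) {
        abort("each perturbation must be c(d_h, d_n)")
      }
    }
  }
  structure(
    list(
      seed = as.integer(seed), noise_h = noise_h, noise_n = noise_n,
      noise_shift = noise_shift, noise_coupling = noise_coupling,
      perturbations = perturbations
    ),
    class = "synth_spec"
  )
}

check_spec <- function(x) {
  if (!inherits(x, "synth_spec")) abort("expected a `synth_spec` object")
  invisible(x)
}

# base (unperturbed) HSQC position for one residue: drawn once from uniform
# amide windows, seeded by the residue index alone so the base spectrum is
# a fixed property of the construct, independent of the noise seed
base_hn_shift <- function(residue) {
  withr::with_seed(1000003L + residue, {
    c(h = runif(1, 7.5, 9.0), n = runif(1, 105, 130))
  })
}

#' Generate a free/bound pair of synthetic HSQC peak lists
#'
#' One amide cross-peak per residue (residue 1 and prolines carry no
#' backbone amide H-N pair and are skipped). The bound list equals the free
#' list plus the stated perturbations, and each list receives independent
#' Gaussian noise on both axes. Identical specs give identical output.
#'
#' @param construct An `nmr_construct`.
#' @param spec A [synth_spec()]; perturbation names are construct residue
#'   indices and must refer to amide-bearing residues.
#' @return A list with tibbles `free` and `bound` (`residue`, `aa`,
#'   `h_ppm`, `n_ppm`).
#' @examples
#' pair <- gen_hsqc_pair(sdc4_construct(), synth_spec(seed = 7))
#' head(pair$free)
#' @export
gen_hsqc_pair <- function(construct, spec = synth_spec()) {
  check_construct(construct)
  check_spec(spec)
  amide <- amide_positions(construct)
  pert_res <- as.integer(names(spec$perturbations))
  bad <- setdiff(pert_res, amide)
  if (length(bad) > 0) {
    abort(sprintf(
      "perturbation on residue(s) without a backbone amide (proline or position 1): %s",
      paste(bad, collapse = ", ")
    ))
  }

  base <- t(vapply(amide, base_hn_shift, numeric(2)))
  d_h <- d_n <- numeric(length(amide))
  if (length(pert_res) > 0) {
    idx <- match(pert_res, amide)
    d_h[idx] <- vapply(spec$perturbations, `[`, numeric(1), 1)
    d_n[idx] <- vapply(spec$perturbations, `[`, numeric(1), 2)
  }

  withr::with_seed(spec$seed, {
    n <- length(amide)
    free <- tibble(
      residue = amide,
      aa = construct$residues[amide],
      h_ppm = base[, 1] + rnorm(n, 0, spec$noise_h),
      n_ppm = base[, 2] + rnorm(n, 0, spec$noise_n)
    )
    bound <- tibble(
      residue = amide,
      aa = construct$residues[amide],
      h_ppm = base[, 1] + d_h + rnorm(n, 0, spec$noise_h),
      n_ppm = base[, 2] + d_n + rnorm(n, 0, spec$noise_n)
    )
  })
  list(free = free, bound = bound)
}

#' Generate a synthetic SLF peak list from the PISA forward model
#'
#' [pisa_wheel()] output plus independent Gaussian noise on each axis.
#' With zero noise the output equals the forward simulation exactly.
#'
#' @inheritParams pisa_wheel
#' @param spec A [synth_spec()] (uses `noise_shift`, `noise_coupling`,
#'   `seed`).
#' @param keep_labels Keep residue labels (`TRUE`) or strip them to emulate
#'   an unassigned spectrum.
#' @return Tibble of peaks (`residue` if kept, `shift_ppm`, `coupling_khz`).
#' @export
gen_slf <- function(helix, tensor = csa_tensor(), wheel, bicelle = bicelle_model(),
                    spec = synth_spec(), residues = NULL, keep_labels = TRUE) {
  check_spec(spec)
  clean <- pisa_wheel(helix, tensor, wheel, bicelle, residues = residues)
  withr::with_seed(spec$seed, {
    out <- clean |>
      dplyr::mutate(
        shift_ppm = .data$shift_ppm + rnorm(dplyr::n(), 0, spec$noise_shift),
        coupling_khz = pmax(
          0, .data$coupling_khz + rnorm(dplyr::n(), 0, spec$noise_coupling)
        )
      ) |>
      dplyr::select(-"coupling_sign")
  })
  if (!keep_labels) out$residue <- NA_integer_
  out
}

#' Generate a synthetic two-wheel (dimer) SLF peak list
#'
#' Union of two [gen_slf()] outputs for two monomer orientations, over
#' disjoint or identical residue spans. Emulates the spectrum of a
#' GXXXG-mediated dimer whose monomers sit at different tilts.
#'
#' @inheritParams gen_slf
#' @param wheel_a,wheel_b [wheel_params()] of the two components.
#' @param residues_a,residues_b Helix residues simulated for each component
#'   (default: all amide residues for both).
#' @param keep_component Keep a `component` column (1/2).
#' @return Tibble of peaks.
#' @export
gen_dimer_slf <- function(helix, tensor = csa_tensor(), wheel_a, wheel_b,
                          bicelle = bicelle_model(), spec = synth_spec(),
                          residues_a = NULL, residues_b = NULL,
                          keep_labels = TRUE, keep_component = TRUE) {
  check_spec(spec)
  spec_b <- spec
  spec_b$seed <- spec$seed + 1L
  a <- gen_slf(helix, tensor, wheel_a, bicelle, spec, residues_a, keep_labels)
  b <- gen_slf(helix, tensor, wheel_b, bicelle, spec_b, residues_b, keep_labels)
  a$component <- 1L
  b$component <- 2L
  out <- dplyr::bind_rows(a, b)
  if (!keep_component) out$component <- NULL
  out
}
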