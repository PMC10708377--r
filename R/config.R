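#' Default pipeline configuration
#'
#' Every tunable constant of the pipeline in one declarative structure.
#' Defaults are the values used throughout the package: the syndecan-4
#' construct with numbering offset 142, transmembrane torsions
#' phi = -69 / psi = -42, the amide 15N tensor (64, 77, 217 ppm) with
#' beta = 17 degrees, an unflipped bicelle at S = 0.85, nu_parallel =
#' 10.52 kHz, CSP weighting alpha = 0.14 with the mean + 1 sd flagging
#' rule, and the standard tilt-fit grids.
#'
#' @param ... Named overrides of any default, nested lists merged by name.
#'   Unknown keys are rejected.
#' @return A `pipeline_config` (nested named list).
#' @export
pipeline_config <- function(...) {
  defaults <- default_config()
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) && is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "pipeline_config")
}

default_config <- function() {
  list(
    version = 1L,
    construct = list(
      sequence = sdc4_construct()$sequence,
      first_full_number = 142L,
      domain_spans = list(
        ecto = c(1, 4), tm = c(5, 29), cyto = c(30, 57),
        c1 = c(30, 39), v = c(40, 52), c2 = c(53, 57)
      )
    ),
    helix = list(phi = -69, psi = -42, omega = 180, nh_length = 1.02),
    tensor = list(sigma11 = 64, sigma22 = 77, sigma33 = 217, beta_deg = 17),
    bicelle = list(order_parameter = 0.85, flip = "unflipped"),
    nu_parallel_khz = 10.52,
    classify = list(threshold_ppm = 120, surface_is = "below"),
    csp = list(alpha = 0.14, sqrt_form = TRUE, rule = "mean_plus_sd", k = 1),
    fit = list(
      tau_min = 0, tau_max = 30, tau_step = 0.5,
      rho_min = 0, rho_max = 355, rho_step = 5
    ),
    synth = list(
      seed = 1L, noise_h = 0.01, noise_n = 0.05,
      noise_shift = 0.5, noise_coupling = 0.1,
      perturbations = list(),
      dimer_tilts = c(6, 16), dimer_rho0 = c(0, 90)
    )
  )
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort(sprintf("config overrides at '%s' must be named", path))
  }
  for (key in nm) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      abort(sprintf("unknown config key: '%s'", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
      key != "perturbations" && key != "domain_spans") {
      if (!is.list(overrides[[key]])) {
        abort(sprintf("config key '%s' must be a named list", full))
      }
      base[[key]] <- merge_config(base[[key]], overrides[[key]], full)
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are rejected
#' before any computation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  pipeline_config(raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# materialise model objects from a config
config_objects <- function(cfg) {
  construct <- make_construct(
    cfg$construct$sequence,
    first_full_number = cfg$construct$first_full_number,
    domain_spans = cfg$construct$domain_spans
  )
  tm <- cfg$construct$domain_spans$tm
  tm_len <- if (is.null(tm)) length(construct) else tm[2] - tm[1] + 1
  helix <- csa_frames(
    build_helix(
      cfg$helix$phi, cfg$helix$psi, tm_len,
      omega = cfg$helix$omega, nh_length = cfg$helix$nh_length
    ),
    beta_deg = cfg$tensor$beta_deg
  )
  list(
    construct = construct,
    helix = helix,
    tensor = csa_tensor(cfg$tensor$sigma11, cfg$tensor$sigma22, cfg$tensor$sigma33),
    bicelle = bicelle_model(cfg$bicelle$order_parameter, cfg$bicelle$flip),
    tau_grid = seq(cfg$fit$tau_min, cfg$fit$tau_max, by = cfg$fit$tau_step),
    rho_grid = seq(cfg$fit$rho_min, cfg$fit$rho_max, by = cfg$fit$rho_step)
  )
}
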