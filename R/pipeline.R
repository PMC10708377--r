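#' Run the full analysis pipeline on synthetic or supplied peak lists
#'
#' Ties the stages together: construct annotation and GXXXG scan, synthetic
#' HSQC pair generation (or user-supplied lists) followed by CSP scoring and
#' flagging, and synthetic dimer SLF generation (or a supplied list)
#' followed by the two-wheel tilt fit. Deterministic for a given config:
#' rerunning with the same config and seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param hsqc_free,hsqc_bound Optional H-N peak data frames; when `NULL`,
#'   synthetic lists are generated from `config$synth`.
#' @param slf_peaks Optional SLF peak data frame; when `NULL`, a synthetic
#'   dimer list is generated at `config$synth$dimer_tilts`.
#' @param out_dir Optional directory; when given, peak lists, result tables,
#'   a JSON summary and a run log of every effective parameter are written
#'   there.
#' @return A list: `construct`, `gxxxg`, `csp` (`csp_result`), `dimer_fit`,
#'   `effective_config`.
#' @export
run_pipeline <- function(config = pipeline_config(), hsqc_free = NULL,
                         hsqc_bound = NULL, slf_peaks = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) abort("expected a `pipeline_config`")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  obj <- stage("config", config_objects(config))
  gxxxg <- stage("construct", find_gxxxg(obj$construct))

  spec <- stage("synth_spec", synth_spec(
    seed = config$synth$seed,
    noise_h = config$synth$noise_h, noise_n = config$synth$noise_n,
    noise_shift = config$synth$noise_shift,
    noise_coupling = config$synth$noise_coupling,
    perturbations = config$synth$perturbations
  ))

  if (is.null(hsqc_free) || is.null(hsqc_bound)) {
    pair <- stage("gen_hsqc", gen_hsqc_pair(obj$construct, spec))
    hsqc_free <- pair$free
    hsqc_bound <- pair$bound
  }
  csp <- stage("csp", {
    r <- compute_csp(
      hsqc_free, hsqc_bound,
      alpha = config$csp$alpha, sqrt_form = config$csp$sqrt_form
    )
    flag_perturbed(r, rule = config$csp$rule, k = config$csp$k)
  })

  if (is.null(slf_peaks)) {
    tm <- config$construct$domain_spans$tm
    n_amide <- obj$helix$n_residues
    half <- 2:ceiling(n_amide / 2)
    rest <- setdiff(2:n_amide, half)
    slf_peaks <- stage("gen_slf", gen_dimer_slf(
      obj$helix, obj$tensor,
      wheel_params(config$synth$dimer_tilts[1], config$synth$dimer_rho0[1],
        nu_parallel_khz = config$nu_parallel_khz
      ),
      wheel_params(config$synth$dimer_tilts[2], config$synth$dimer_rho0[2],
        nu_parallel_khz = config$nu_parallel_khz
      ),
      obj$bicelle, spec,
      residues_a = half, residues_b = rest, keep_component = FALSE
    ))
  }
  dimer <- stage("fit_two_wheels", fit_two_wheels(
    slf_peaks, obj$helix, obj$tensor, obj$bicelle, config$nu_parallel_khz
  ))

  result <- list(
    construct = obj$construct,
    gxxxg = gxxxg,
    csp = csp,
    dimer_fit = dimer,
    hsqc_free = as_tibble(hsqc_free),
    hsqc_bound = as_tibble(hsqc_bound),
    slf_peaks = as_tibble(slf_peaks),
    effective_config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peaklist(hsqc_free, file.path(out_dir, "hsqc_free.tsv"))
    write_peaklist(hsqc_bound, file.path(out_dir, "hsqc_bound.tsv"))
    write_peaklist(slf_peaks, file.path(out_dir, "slf_peaks.tsv"))
    write_peaklist(
      tidy(csp, construct = obj$construct),
      file.path(out_dir, "csp.tsv")
    )
    write_peaklist(tidy(dimer), file.path(out_dir, "dimer_fit.tsv"))
    summary <- list(
      csp = as.list(glance(csp)),
      dimer_fit = as.list(glance(dimer)),
      gxxxg = lapply(seq_len(nrow(gxxxg)), function(i) as.list(gxxxg[i, ]))
    )
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        summary, file.path(out_dir, "summary.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    # run log: every effective parameter, defaults included
    writeLines(
      c(
        "# pisawheel run log: effective parameters",
        yaml::as.yaml(unclass(config))
      ),
      file.path(out_dir, "run_log.yml")
    )
  }
  result
}
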