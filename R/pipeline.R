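# Pipeline orchestration: validated run configurations and the three
# end-to-end stages (spectrum, tuning ledger, kinetics), each writing
# deterministic CSV/JSON outputs with a provenance block.  A thin command
# line wrapper over these functions ships in inst/scripts/.

input_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("frl_input_error", "error", "condition")))
}

#' Read and validate a run configuration
#'
#' YAML file of paths, unit declarations, model label, seed and output
#' directory.  All referenced paths must exist at validation time; unit
#' declarations must be one of `eV`, `cm-1`, `nm`.  Validation failures
#' signal a condition of class `frl_input_error` (mapped to exit code 2 by
#' the command-line wrapper).
#'
#' @param path YAML configuration path.
#' @return Named list (the configuration) with class `frl_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) input_error("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("site_energy_table", "coupling_table", "vee_table",
                "network_spec", "structure")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      input_error("config field '%s' references a missing path: %s",
                  key, cfg[[key]])
    }
  }
  for (key in grep("_unit$", names(cfg), value = TRUE)) {
    if (!cfg[[key]] %in% c("eV", "cm-1", "nm")) {
      input_error("config field '%s': unit must be eV, cm-1 or nm (got '%s')",
                  key, cfg[[key]])
    }
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  structure(cfg, class = c("frl_run_config", "list"))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

provenance_block <- function(cfg, seed = NULL) {
  list(package = "frlpsii",
       version = as.character(utils::packageVersion("frlpsii")),
       constants_version = frl_constants$constants_version,
       config_hash = config_hash(cfg),
       seed = seed)
}

#' Spectrum pipeline stage
#'
#' Builds the exciton system from the configured site-energy table (plus a
#' coupling table or a structure with a selection map), diagonalizes it,
#' synthesizes the (optionally disorder-averaged) absorption spectrum, and
#' optionally aligns it to a reference wavelength.  Writes `spectrum.csv`
#' (with JSON metadata sidecar) and `summary.json` (exciton energies in eV
#' and nm, oscillator strengths, participation ratios, alignment shift,
#' provenance) into the output directory.
#'
#' Configuration fields: `site_energy_table` (required), `coupling_table`,
#' `model_label`, `fwhm_eV` (default 0.06), `disorder_sigma_eV` (default 0),
#' `n_ensemble` (default 1), `seed` (required when disorder is on),
#' `align_to_nm` (e.g. 674), `output_dir`.
#'
#' @param cfg `frl_run_config` (or plain list with the same fields).
#' @return List with `spectrum`, `states`, `paths`, invisibly.
#' @export
pipeline_spectrum <- function(cfg) {
  if (is.null(cfg$site_energy_table)) {
    input_error("spectrum stage: config lacks 'site_energy_table'")
  }
  se <- read_site_energy_table(cfg$site_energy_table)
  coup <- if (!is.null(cfg$coupling_table)) read_coupling_table(cfg$coupling_table)
  pigments <- NULL
  if (is.null(coup) && !is.null(cfg$structure)) {
    if (is.null(cfg$selection_map)) {
      input_error("spectrum stage: 'structure' given without 'selection_map'")
    }
    pigments <- read_pigments(cfg$structure, cfg$selection_map)
  }
  sys <- tryCatch(
    build_system(se, coup, pigments = pigments,
                 screening_f = cfg$screening_f %||% 0.72,
                 model_label = cfg$model_label %||% ""),
    error = function(e) input_error("spectrum stage: %s", conditionMessage(e)))

  st <- diagonalize(sys)
  fwhm <- cfg$fwhm_eV %||% 0.06
  sigma <- cfg$disorder_sigma_eV %||% 0
  n_ens <- cfg$n_ensemble %||% 1L
  f <- st$oscillator_strengths
  if (anyNA(f)) f <- rep(1, length(st$energies))
  spec <- if (sigma > 0 && n_ens > 1) {
    if (is.null(cfg$seed)) input_error("spectrum stage: disorder requires a 'seed'")
    ensemble_spectrum(sys, sigma, n_ens, seed = cfg$seed, fwhm = fwhm)
  } else {
    broaden(st$energies, f, fwhm = fwhm)
  }
  if (!is.null(cfg$align_to_nm)) {
    spec <- align_to_reference(spec, nm_to_ev(cfg$align_to_nm))
  }

  dir.create(cfg$output_dir %||% ".", showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$output_dir %||% ".", "spectrum.csv")
  json_path <- file.path(cfg$output_dir %||% ".", "summary.json")
  write_spectrum_csv(spec, csv_path)
  summary <- list(
    model_label = sys$model_label,
    states = lapply(seq_along(st$energies), function(k) {
      list(index = k,
           energy_eV = signif(st$energies[k], 6),
           energy_ev_3dp = report_ev(st$energies[k]),
           wavelength_nm = report_nm(st$energies[k]),
           oscillator_strength = if (is.na(st$oscillator_strengths[k])) NULL
                                 else signif(st$oscillator_strengths[k], 6),
           dark = if (is.na(st$oscillator_strengths[k])) NULL
                  else st$oscillator_strengths[k] < 1e-4,
           participation_ratio = signif(st$participation_ratios[k], 6))
    }),
    alignment_shift_eV = signif(spec$metadata$alignment_shift, 6),
    n_ensemble = spec$metadata$n_ensemble,
    provenance = provenance_block(cfg, seed = cfg$seed)
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(spectrum = spec, states = st,
                 paths = c(spectrum = csv_path, summary = json_path)))
}

#' Tuning-ledger pipeline stage
#'
#' Decomposes every VEE quadruple of the configured table into
#' strain/electrostatic/coupling components with red/blue classification.
#' Writes `ledger.tsv` and `ledger.json`.  When `alignment_shift_eV` is
#' supplied, the aligned totals (total + shift) are reported alongside.
#'
#' @param cfg `frl_run_config` with `vee_table` and optionally
#'   `alignment_shift_eV`, `output_dir`.
#' @return List with `ledgers` and `paths`, invisibly.
#' @export
pipeline_ledger <- function(cfg) {
  if (is.null(cfg$vee_table)) input_error("ledger stage: config lacks 'vee_table'")
  sets <- tryCatch(read_vee_table(cfg$vee_table),
                   error = function(e) input_error("ledger stage: %s",
                                                   conditionMessage(e)))
  ledgers <- lapply(sets, decompose)
  tab <- do.call(rbind, lapply(ledgers, as.data.frame))
  if (!is.null(cfg$alignment_shift_eV)) {
    tab$total_aligned <- tab$total + cfg$alignment_shift_eV
  }
  dir.create(cfg$output_dir %||% ".", showWarnings = FALSE, recursive = TRUE)
  tsv_path <- file.path(cfg$output_dir %||% ".", "ledger.tsv")
  json_path <- file.path(cfg$output_dir %||% ".", "ledger.json")
  utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sign_convention = "negative = redshifting",
                            ledger = tab,
                            provenance = provenance_block(cfg)),
                       json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ledgers = ledgers, paths = c(table = tsv_path, json = json_path)))
}

#' Kinetics pipeline stage
#'
#' Builds the kinetic network (from a YAML network specification or from a
#' built-in model label), propagates it on the log time grid, and writes
#' `populations.csv` plus `halftimes.json` (formation halftimes with mode
#' annotation and provenance).
#'
#' @param cfg `frl_run_config` with either `network_spec` (YAML path) or
#'   `model` (`"FRL_chl_d"` / `"WL"`); optional `t_min_s`, `t_max_s`,
#'   `n_times`, `output_dir`.
#' @return List with `result` and `paths`, invisibly.
#' @export
pipeline_kinetics <- function(cfg) {
  net <- if (!is.null(cfg$network_spec)) {
    tryCatch(read_network_spec(cfg$network_spec),
             error = function(e) input_error("kinetics stage: %s",
                                             conditionMessage(e)))
  } else if (!is.null(cfg$model)) {
    tryCatch(build_default_network(cfg$model),
             error = function(e) input_error("kinetics stage: %s",
                                             conditionMessage(e)))
  } else {
    input_error("kinetics stage: config needs 'network_spec' or 'model'")
  }
  grid <- default_time_grid(cfg$t_min_s %||% 1e-13, cfg$t_max_s %||% 1e-1,
                            cfg$n_times %||% 400)
  result <- propagate(net, grid)
  dir.create(cfg$output_dir %||% ".", showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$output_dir %||% ".", "populations.csv")
  json_path <- file.path(cfg$output_dir %||% ".", "halftimes.json")
  write_kinetics_results(result, csv_path, json_path)
  # re-write halftimes with provenance attached
  halts <- jsonlite::read_json(json_path)
  jsonlite::write_json(list(halftimes = halts,
                            provenance = provenance_block(cfg)),
                       json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(result = result, paths = c(populations = csv_path,
                                            halftimes = json_path)))
}
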