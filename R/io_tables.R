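# Readers and writers for the delimited-table and YAML interfaces: site
# energies, couplings, VEE quadruples, spectra (CSV + JSON sidecar) and
# kinetic network specifications.  All tables carry explicit unit columns;
# nothing is unit-guessed.

read_delim_table <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop(sprintf("table %s lacks required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  }
  tab
}

#' Read / write a site-energy table
#'
#' Tab-delimited with header columns `pigment_id`, `value`, `unit`
#' (unit `eV`).
#'
#' @param path File path.
#' @return data.frame suitable for [build_system()].
#' @export
read_site_energy_table <- function(path) {
  read_delim_table(path, c("pigment_id", "value", "unit"))
}

#' @rdname read_site_energy_table
#' @param tab data.frame with the table columns.
#' @export
write_site_energy_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a coupling table
#'
#' Tab-delimited with header columns `pigment_i`, `pigment_j`, `value`,
#' `unit` (unit `cm-1` or `eV`).
#'
#' @param path File path.
#' @return data.frame suitable for [build_system()].
#' @export
read_coupling_table <- function(path) {
  read_delim_table(path, c("pigment_i", "pigment_j", "value", "unit"))
}

#' @rdname read_coupling_table
#' @param tab data.frame with the table columns.
#' @export
write_coupling_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a VEE table
#'
#' Tab-delimited, one row per pigment, with columns `pigment_id`,
#' `vee_gas_at_gas_geom`, `vee_gas_at_protein_geom`, `vee_protein_monomer`,
#' `vee_multimer`, `unit` (unit `eV`).
#'
#' @param path File path.
#' @return List of `frl_vee_set`, named by pigment id.
#' @export
read_vee_table <- function(path) {
  tab <- read_delim_table(path, c("pigment_id", "vee_gas_at_gas_geom",
                                  "vee_gas_at_protein_geom",
                                  "vee_protein_monomer", "vee_multimer",
                                  "unit"))
  if (nrow(tab) == 0) stop(sprintf("VEE table %s is empty", basename(path)))
  if (any(tab$unit != "eV")) stop("VEE table: unit must be eV")
  out <- lapply(seq_len(nrow(tab)), function(r) {
    vee_set(tab$pigment_id[r], tab$vee_gas_at_gas_geom[r],
            tab$vee_gas_at_protein_geom[r], tab$vee_protein_monomer[r],
            tab$vee_multimer[r])
  })
  stats::setNames(out, tab$pigment_id)
}

#' Write / read a spectrum as CSV with a JSON metadata sidecar
#'
#' Two columns (`energy_eV` or `wavelength_nm`, and `intensity`); the
#' metadata (fwhm, alignment shift, ensemble size, ...) goes to
#' `<path>.meta.json`.
#'
#' @param spec `frl_spectrum`.
#' @param path CSV output path.
#' @param unit `"energy_eV"` or `"wavelength_nm"`.
#' @return The CSV path, invisibly.
#' @export
write_spectrum_csv <- function(spec, path, unit = c("energy_eV", "wavelength_nm")) {
  unit <- match.arg(unit)
  x <- if (unit == "energy_eV") spec$energy_grid else ev_to_nm(spec$energy_grid)
  df <- data.frame(x = signif(x, 6), intensity = signif(spec$intensity, 6))
  names(df)[1] <- unit
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- spec$metadata
  meta$lowest_energies <- NULL  # large per-realization vector stays in-memory only
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  unit <- names(df)[1]
  grid <- if (unit == "wavelength_nm") rev(nm_to_ev(df[[1]])) else df[[1]]
  intensity <- if (unit == "wavelength_nm") rev(df$intensity) else df$intensity
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  new_spectrum(grid, intensity,
               fwhm = meta$fwhm %||% NA_real_,
               alignment_shift = meta$alignment_shift %||% 0,
               n_ensemble = meta$n_ensemble %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a kinetic network specification
#'
#' YAML file with fields:
#' \preformatted{
#' temperature_K: 298.15
#' states:
#'   - {label: S1, energy_eV: 1.72}
#'   - ...
#' edges:
#'   - {from: S1, to: "ChlD1+ PheoD1-", k_forward_s1: 3.0e11}
#'   - {from: A, to: B, marcus: {lambda_eV: 0.7, V_eV: 0.01}}
#' reversible: true
#' }
#' Edges give either an explicit forward rate or Marcus parameters (the
#' driving force is taken from the state energies); backward rates are added
#' by detailed balance when `reversible` is true.
#'
#' @param path YAML file path.
#' @return `frl_kinetic_network`.
#' @export
read_network_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  spec <- yaml::read_yaml(path)
  network_from_spec(spec)
}

#' Build a kinetic network from a specification list
#'
#' @param spec List with `states`, `edges`, optional `temperature_K`
#'   (default 298.15) and `reversible` (default TRUE); see
#'   [read_network_spec()].
#' @return `frl_kinetic_network`.
#' @export
network_from_spec <- function(spec) {
  if (is.null(spec$states) || length(spec$states) < 2) {
    stop("network spec: need at least two states")
  }
  temperature <- spec$temperature_K %||% 298.15
  reversible <- spec$reversible %||% TRUE
  labels <- vapply(spec$states, function(s) s$label, character(1))
  energies <- vapply(spec$states, function(s) as.numeric(s$energy_eV), numeric(1))
  n <- length(labels)
  G <- matrix(0, n, n)
  for (e in spec$edges) {
    i <- match(e$from, labels)
    j <- match(e$to, labels)
    if (is.na(i) || is.na(j)) {
      stop(sprintf("network spec: edge references unknown state '%s'",
                   if (is.na(i)) e$from else e$to))
    }
    dg <- energies[j] - energies[i]
    kf <- if (!is.null(e$k_forward_s1)) {
      as.numeric(e$k_forward_s1)
    } else if (!is.null(e$marcus)) {
      marcus_rate(dg, as.numeric(e$marcus$lambda_eV),
                  as.numeric(e$marcus$V_eV), temperature)
    } else {
      stop(sprintf("network spec: edge %s -> %s gives neither k_forward_s1 nor marcus parameters",
                   e$from, e$to))
    }
    if (!is.finite(kf) || kf < 0) {
      stop(sprintf("network spec: invalid forward rate for edge %s -> %s",
                   e$from, e$to))
    }
    G[j, i] <- G[j, i] + kf
    if (reversible) {
      G[i, j] <- G[i, j] + detailed_balance_backward(kf, dg, temperature)
    }
  }
  diag(G) <- 0
  diag(G) <- -colSums(G)
  states <- mapply(ct_state, labels, pmax(energies, 0), SIMPLIFY = FALSE)
  init <- spec$initial_populations
  if (!is.null(init)) init <- as.numeric(init)
  kinetic_network(states, G, initial_populations = init,
                  temperature = temperature)
}

#' Write kinetics results as CSV + JSON halftime summary
#'
#' @param result `frl_kinetics_result`.
#' @param csv_path Per-time populations CSV (`time_s` + one column per state).
#' @param json_path Halftime summary JSON; formation halftimes for every
#'   state that becomes populated, with the extraction mode annotated.
#' @return `csv_path`, invisibly.
#' @export
write_kinetics_results <- function(result, csv_path, json_path) {
  df <- data.frame(time_s = signif(result$time_grid, 6),
                   signif(result$populations, 6), check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  halts <- lapply(colnames(result$populations), function(lab) {
    t_half <- tryCatch(halftime(result, lab, "formation"),
                       error = function(e) NA_real_)
    list(state = lab, mode = "formation",
         halftime_s = if (is.na(t_half)) NULL else signif(t_half, 6))
  })
  jsonlite::write_json(halts, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}
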