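# Spectral-tuning ledger: exact bookkeeping that decomposes the shift of a
# pigment's vertical excitation energy (VEE) between the gas phase and the
# coupled pigment cluster into strain, electrostatic, and
# coupling/polarization components.

#' Construct a VEE set
#'
#' The four vertical excitation energies that define the tuning
#' decomposition for one pigment: the isolated pigment at its gas-phase
#' geometry, the isolated pigment at its in-protein geometry, the monomeric
#' pigment inside the protein electrostatics, and the pigment within the
#' coupled multimer.
#'
#' @param pigment_id Identifier.
#' @param vee_gas_at_gas_geom,vee_gas_at_protein_geom,vee_protein_monomer,vee_multimer
#'   The four VEEs in eV, each within (0.5, 4.0).
#' @return Object of class `frl_vee_set`.
#' @export
vee_set <- function(pigment_id, vee_gas_at_gas_geom, vee_gas_at_protein_geom,
                    vee_protein_monomer, vee_multimer) {
  vals <- c(vee_gas_at_gas_geom, vee_gas_at_protein_geom,
            vee_protein_monomer, vee_multimer)
  if (any(!is.finite(vals)) || any(vals <= 0.5 | vals >= 4.0)) {
    stop("vee_set(): all VEEs must lie in the (0.5, 4.0) eV sanity window")
  }
  structure(list(pigment_id = pigment_id,
                 vee_gas_at_gas_geom = vee_gas_at_gas_geom,
                 vee_gas_at_protein_geom = vee_gas_at_protein_geom,
                 vee_protein_monomer = vee_protein_monomer,
                 vee_multimer = vee_multimer),
            class = "frl_vee_set")
}

#' Decompose a VEE set into tuning components
#'
#' Exact telescoping bookkeeping of the shift from the gas-phase pigment to
#' the coupled multimer:
#' \itemize{
#'   \item strain = VEE(gas phase, protein geometry) - VEE(gas phase, gas geometry)
#'   \item electrostatic = VEE(protein monomer) - VEE(gas phase, protein geometry)
#'   \item coupling/polarization = VEE(multimer) - VEE(protein monomer)
#' }
#' The three components sum exactly to the total shift
#' VEE(multimer) - VEE(gas phase, gas geometry).  Sign convention: negative
#' means redshifting (lower excitation energy), positive blueshifting.
#'
#' @param v `frl_vee_set`.
#' @return Object of class `frl_shift_ledger` with fields `strain`,
#'   `electrostatic`, `coupling_polarization`, `total` (all eV).
#' @examples
#' v <- make_vee_set("chl_d", baseline = 1.910, strain = -0.006,
#'                   electrostatic = -0.003, coupling_polarization = -0.032)
#' decompose(v)
#' @export
decompose <- function(v) {
  stopifnot(inherits(v, "frl_vee_set"))
  strain <- v$vee_gas_at_protein_geom - v$vee_gas_at_gas_geom
  elec <- v$vee_protein_monomer - v$vee_gas_at_protein_geom
  cp <- v$vee_multimer - v$vee_protein_monomer
  structure(list(pigment_id = v$pigment_id,
                 strain = strain,
                 electrostatic = elec,
                 coupling_polarization = cp,
                 total = v$vee_multimer - v$vee_gas_at_gas_geom),
            class = "frl_shift_ledger")
}

#' @export
print.frl_shift_ledger <- function(x, ...) {
  cat(sprintf("<shift ledger %s> (negative = redshifting)\n", x$pigment_id))
  for (comp in c("strain", "electrostatic", "coupling_polarization", "total")) {
    cat(sprintf("  %-22s %+.4f eV (%s)\n", comp, x[[comp]],
                classify_shift(x[[comp]])))
  }
  invisible(x)
}

#' Classify a spectral shift as red/blue/neutral
#'
#' Negative shifts (lower energy) are redshifting, positive blueshifting;
#' magnitudes below the 0.001 eV neutrality threshold (under the reporting
#' precision of the tabulated components) are neutral.
#'
#' @param delta_ev Shift in eV.
#' @return `"redshifting"`, `"blueshifting"`, or `"neutral"`.
#' @export
classify_shift <- function(delta_ev) {
  ifelse(abs(delta_ev) < 0.001, "neutral",
         ifelse(delta_ev < 0, "redshifting", "blueshifting"))
}

#' Compare two shift ledgers component-wise
#'
#' @param a,b `frl_shift_ledger` objects.
#' @return data.frame with one row per component: the two values, their exact
#'   difference (a - b), and the sign classification of each.
#' @export
compare_ledgers <- function(a, b) {
  comps <- c("strain", "electrostatic", "coupling_polarization", "total")
  data.frame(
    component = comps,
    a = vapply(comps, function(k) a[[k]], numeric(1)),
    b = vapply(comps, function(k) b[[k]], numeric(1)),
    difference = vapply(comps, function(k) a[[k]] - b[[k]], numeric(1)),
    class_a = vapply(comps, function(k) classify_shift(a[[k]]), character(1)),
    class_b = vapply(comps, function(k) classify_shift(b[[k]]), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Shift ledger as a one-row data frame
#' @param x `frl_shift_ledger`.
#' @param ... unused.
#' @return data.frame row with components, total, and classifications.
#' @export
as.data.frame.frl_shift_ledger <- function(x, ...) {
  data.frame(pigment_id = x$pigment_id,
             strain = x$strain,
             electrostatic = x$electrostatic,
             coupling_polarization = x$coupling_polarization,
             total = x$total,
             strain_class = classify_shift(x$strain),
             electrostatic_class = classify_shift(x$electrostatic),
             coupling_polarization_class = classify_shift(x$coupling_polarization),
             total_class = classify_shift(x$total),
             stringsAsFactors = FALSE)
}
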