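# Synthetic generators for every input class the pipeline consumes:
# idealized pigment clusters with PDB output, VEE quadruples with known
# components, and kinetic chain networks with known rates.  These stand in
# for the upstream quantum-chemistry and molecular-dynamics outputs so the
# full pipeline is testable offline.

#' Generator configuration
#'
#' @param seed Integer seed; required, so every generated object is
#'   bit-reproducible (a single RNG stream per generator call, no global
#'   state consumed).
#' @param n_pigments Number of pigments in a cluster.
#' @param ring_radius Radius of the idealized macrocycle carbon circle, A.
#' @param inter_pigment_spacing Centre-to-centre spacing, A; must exceed 3 A
#'   (clash limit).
#' @param disorder_sigma Site-energy static disorder, eV.
#' @param site_energy_means Mean Qy site energies, eV (recycled to
#'   `n_pigments`).
#' @return Object of class `frl_generator_config`.
#' @export
generator_config <- function(seed, n_pigments = 6, ring_radius = 3.4,
                             inter_pigment_spacing = 10,
                             disorder_sigma = 0.02,
                             site_energy_means = 1.9) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (inter_pigment_spacing <= 3) {
    stop("generator_config(): inter-pigment spacing must exceed 3 A (clash)")
  }
  structure(list(seed = as.integer(seed),
                 n_pigments = as.integer(n_pigments),
                 ring_radius = ring_radius,
                 inter_pigment_spacing = inter_pigment_spacing,
                 disorder_sigma = disorder_sigma,
                 site_energy_means = rep_len(site_energy_means, n_pigments)),
            class = "frl_generator_config")
}

random_rotation_matrix <- function() {
  # QR of a Gaussian matrix, sign-fixed, det forced to +1
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Idealized planar chlorin: Mg at origin, four pyrrole nitrogens at
# 2.05 A (NA, NB, NC, ND at 45/135/225/315 degrees, so NB -> ND is an
# in-plane diagonal), sixteen ring carbons C1..C16 on the outer circle.
ideal_chlorin_template <- function(ring_radius = 3.4, mg_n = 2.05) {
  ang_n <- (c(45, 135, 225, 315)) * pi / 180
  nitro <- cbind(mg_n * cos(ang_n), mg_n * sin(ang_n), 0)
  ang_c <- (seq(0, 360, length.out = 17)[-17] + 11.25) * pi / 180
  carb <- cbind(ring_radius * cos(ang_c), ring_radius * sin(ang_c), 0)
  data.frame(
    atom_name = c("MG", "NA", "NB", "NC", "ND", paste0("C", 1:16)),
    element = c("MG", rep("N", 4), rep("C", 16)),
    x = c(0, nitro[, 1], carb[, 1]),
    y = c(0, nitro[, 2], carb[, 2]),
    z = c(0, nitro[, 3], carb[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Generate an idealized pigment cluster and its PDB file
#'
#' Places `n_pigments` idealized planar chlorin rings (Mg, four pyrrole
#' nitrogens at 2.05 A, sixteen ring carbons) along the x axis at the
#' configured centre-to-centre spacing, each with a random (seeded) rigid
#' rotation.  The cluster is written as a PDB file (HETATM records, residue
#' CLA, chain A, residue numbers 1..n) that round-trips through
#' [read_pigments()].
#'
#' @param cfg `frl_generator_config`.
#' @param path Output PDB path; default a tempfile.
#' @return List with `pigments` (list of `frl_pigment`), `pdb_path`, and
#'   `selection_map` ready for [read_pigments()].
#' @export
make_pigment_cluster <- function(cfg, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(cfg, "frl_generator_config"))
  template <- ideal_chlorin_template(cfg$ring_radius)
  pigments <- vector("list", cfg$n_pigments)
  all_atoms <- list()
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_pigments)) {
      R <- random_rotation_matrix()
      xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(R)
      xyz[, 1] <- xyz[, 1] + (i - 1) * cfg$inter_pigment_spacing
      at <- template
      at$x <- round(xyz[, 1], 3)  # PDB coordinate precision
      at$y <- round(xyz[, 2], 3)
      at$z <- round(xyz[, 3], 3)
      pigments[[i]] <- pigment(pigment_id = paste0("pig", i),
                               chem_type = "chl_a", site_label = "other",
                               atoms = at)
      all_atoms[[i]] <- at
    }
  })
  atoms <- do.call(rbind, all_atoms)
  natom <- nrow(template)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("HETATM", nrow(atoms)),
    resno = rep(seq_len(cfg$n_pigments), each = natom),
    resid = rep("CLA", nrow(atoms)),
    chain = rep("A", nrow(atoms)),
    elety = atoms$atom_name
  )
  sel <- lapply(seq_len(cfg$n_pigments), function(i)
    list(chain = "A", resname = "CLA", resno = i))
  names(sel) <- paste0("pig", seq_len(cfg$n_pigments))
  list(pigments = pigments, pdb_path = path, selection_map = sel)
}

#' Construct a VEE set with known tuning components
#'
#' Exact right-inverse of [decompose()]: the returned set decomposes into
#' precisely the given strain, electrostatic, and coupling/polarization
#' components.
#'
#' @param pigment_id Identifier.
#' @param baseline Gas-phase VEE at the gas-phase geometry, eV.
#' @param strain,electrostatic,coupling_polarization Components in eV
#'   (negative = redshifting).
#' @return `frl_vee_set`.
#' @export
make_vee_set <- function(pigment_id, baseline, strain, electrostatic,
                         coupling_polarization) {
  vee_set(pigment_id,
          vee_gas_at_gas_geom = baseline,
          vee_gas_at_protein_geom = baseline + strain,
          vee_protein_monomer = baseline + strain + electrostatic,
          vee_multimer = baseline + strain + electrostatic +
            coupling_polarization)
}

#' Generate a random irreversible chain network
#'
#' Forward rates drawn log-uniformly over the given decade range, state
#' energies strictly decreasing; reproducible by seed.
#'
#' @param n_states Number of states (>= 2).
#' @param rate_log10_range Length-2 vector: log10 of the slowest/fastest
#'   admissible rate in s^-1.
#' @param seed Integer seed.
#' @param e_top Energy of the initial state, eV.
#' @param e_step Energy drop per step, eV.
#' @return `frl_kinetic_network` (irreversible: no back rates).
#' @export
make_network <- function(n_states, rate_log10_range = c(3, 11), seed,
                         e_top = 1.8, e_step = 0.1) {
  stopifnot(n_states >= 2, length(rate_log10_range) == 2)
  rates <- with_seed(seed,
    10^stats::runif(n_states - 1, rate_log10_range[1], rate_log10_range[2]))
  energies <- e_top - e_step * (seq_len(n_states) - 1)
  chain_network(paste0("S", seq_len(n_states) - 1), energies, rates,
                reversible = FALSE)
}
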