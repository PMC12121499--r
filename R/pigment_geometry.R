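# Geometry layer: chlorin pigments extracted from PDB structures, their
# Qy dipole axes, and the inter-pigment distance primitives that the
# coupling estimator consumes.

#' Default residue-name to chlorin-type map
#'
#' Residue codes for chlorophyll d/f vary between depositions, so the map is
#' fully overridable.  Values are the supported chemical types: `chl_a`,
#' `chl_d`, `chl_f`, `pheo_a`.
#'
#' @return Named character vector mapping PDB residue names to chem types.
#' @export
default_residue_map <- function() {
  c(CLA = "chl_a", CHL = "chl_a",
    CL7 = "chl_d", CHD = "chl_d",
    CL8 = "chl_f", CHF = "chl_f",
    PHO = "pheo_a", PHE = "pheo_a")
}

#' Macrocycle heavy-atom names of the chlorin ring
#'
#' All carbons and nitrogens of the conjugated chlorin system in the two
#' common naming dialects: IUPAC macrocycle numbering (C1--C20, N21--N24) and
#' the PDB chlorophyll component dialect (NA--ND, C1A--C4A per ring,
#' methine bridges CHA--CHD).  Phytyl-tail and substituent atoms are excluded
#' so that edge-to-edge distances refer to the conjugated system.  In the PDB
#' component dialect the phytyl carbons reuse the plain `C1..C20` names; when
#' reading such entries, pass a custom set restricted to the ring names.
#'
#' @return Character vector of atom names.
#' @export
macrocycle_atom_names <- function() {
  c(paste0("C", 1:20),
    paste0("N", 21:24), "NA", "NB", "NC", "ND",
    paste0("C", rep(1:4, 4), rep(c("A", "B", "C", "D"), each = 4)),
    paste0("CH", c("A", "B", "C", "D")))
}

pyrrole_nitrogen_names <- function() c("NA", "NB", "NC", "ND", "N21", "N22", "N23", "N24")

#' Construct a pigment object
#'
#' Low-level constructor; most users will obtain pigments from
#' [read_pigments()] or [make_pigment_cluster()].
#'
#' @param pigment_id Character identifier.
#' @param chem_type One of `"chl_a"`, `"chl_d"`, `"chl_f"`, `"pheo_a"`.
#' @param site_label Reaction-center site: one of `"P_D1"`, `"P_D2"`,
#'   `"Chl_D1"`, `"Chl_D2"`, `"Pheo_D1"`, `"Pheo_D2"`, `"other"`.
#' @param atoms data.frame with columns `atom_name`, `element`, `x`, `y`, `z`
#'   (Angstrom, as stored in the file; no re-centering).
#' @param dipole_magnitude Qy transition-dipole magnitude in Debye.  The
#'   default 4.0 D is a typical effective in-protein value for chlorin Qy
#'   transitions and applies to all chem types unless overridden.
#' @param axis_atoms Length-2 character vector naming the nitrogens defining
#'   the Qy axis, from first to second (default NB -> ND; the N21/N23
#'   dialect is accepted automatically if NB/ND are absent).
#' @return An object of class `frl_pigment`.
#' @export
pigment <- function(pigment_id, chem_type, site_label, atoms,
                    dipole_magnitude = 4.0, axis_atoms = c("NB", "ND")) {
  chem_type <- match.arg(chem_type, c("chl_a", "chl_d", "chl_f", "pheo_a"))
  site_label <- match.arg(site_label, c("P_D1", "P_D2", "Chl_D1", "Chl_D2",
                                        "Pheo_D1", "Pheo_D2", "other"))
  stopifnot(is.data.frame(atoms),
            all(c("atom_name", "element", "x", "y", "z") %in% names(atoms)))
  if (!is.finite(dipole_magnitude) || dipole_magnitude <= 0) {
    stop("pigment(): dipole_magnitude must be positive")
  }
  mg <- atoms[toupper(atoms$element) == "MG" | atoms$atom_name == "MG", , drop = FALSE]
  mg_position <- if (nrow(mg) >= 1) as.numeric(mg[1, c("x", "y", "z")]) else NULL
  p <- structure(list(
    pigment_id = pigment_id,
    chem_type = chem_type,
    site_label = site_label,
    atoms = atoms,
    mg_position = mg_position,
    axis_atoms = axis_atoms,
    dipole_magnitude = dipole_magnitude
  ), class = "frl_pigment")
  p$qy_unit_vector <- qy_axis(p)
  p
}

#' @export
print.frl_pigment <- function(x, ...) {
  cat(sprintf("<pigment %s> %s at %s: %d atoms, |mu| = %.2f D, Qy axis (%.3f, %.3f, %.3f)\n",
              x$pigment_id, x$chem_type, x$site_label, nrow(x$atoms),
              x$dipole_magnitude, x$qy_unit_vector[1], x$qy_unit_vector[2],
              x$qy_unit_vector[3]))
  invisible(x)
}

atom_xyz <- function(p, name) {
  i <- which(p$atoms$atom_name == name)
  if (length(i) == 0) return(NULL)
  as.numeric(p$atoms[i[1], c("x", "y", "z")])
}

#' Qy transition-dipole axis of a pigment
#'
#' Unit vector along the NB -> ND nitrogen axis (the conventional Qy
#' polarization direction of chlorins), with deterministic sign from the
#' first axis atom towards the second.  The N21/N23 dialect is used as a
#' fallback when the configured names are absent.
#'
#' @param p `frl_pigment` object (or a list with an `atoms` data.frame).
#' @param axis_atoms Length-2 character vector of nitrogen names; defaults to
#'   the pigment's own configuration.
#' @return Unit 3-vector.
#' @export
qy_axis <- function(p, axis_atoms = NULL) {
  if (is.null(axis_atoms)) {
    axis_atoms <- if (!is.null(p$axis_atoms)) p$axis_atoms else c("NB", "ND")
  }
  a <- atom_xyz(p, axis_atoms[1])
  b <- atom_xyz(p, axis_atoms[2])
  if (is.null(a) || is.null(b)) {
    # dialect fallback
    alt <- c(NB = "N21", ND = "N23", N21 = "NB", N23 = "ND")
    a2 <- atom_xyz(p, alt[axis_atoms[1]])
    b2 <- atom_xyz(p, alt[axis_atoms[2]])
    if (!is.null(a2) && !is.null(b2)) {
      a <- a2; b <- b2
    } else {
      miss <- axis_atoms[c(is.null(a), is.null(b))]
      stop(sprintf("qy_axis(): missing axis atom(s) %s in pigment '%s'",
                   paste(miss, collapse = ", "),
                   if (!is.null(p$pigment_id)) p$pigment_id else "?"))
    }
  }
  v <- b - a
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("qy_axis(): axis atoms coincide (zero-length axis)")
  v / n
}

macrocycle_coords <- function(p, atom_names = macrocycle_atom_names()) {
  keep <- p$atoms$atom_name %in% atom_names &
    toupper(p$atoms$element) %in% c("C", "N")
  m <- p$atoms[keep, c("x", "y", "z"), drop = FALSE]
  as.matrix(m)
}

#' Minimum edge-to-edge distance between two pigment macrocycles
#'
#' Minimum pairwise Euclidean distance between the conjugated-macrocycle
#' heavy atoms (C and N of the chlorin ring) of the two pigments.  This is
#' the "edge-to-edge" inter-pigment distance convention used for the
#' P_D1/P_D2 special pair.
#'
#' @param p1,p2 `frl_pigment` objects.
#' @param atom_names Macrocycle atom-name set; see [macrocycle_atom_names()].
#' @return Distance in Angstrom (symmetric in its arguments).
#' @export
edge_to_edge_distance <- function(p1, p2, atom_names = macrocycle_atom_names()) {
  m1 <- macrocycle_coords(p1, atom_names)
  m2 <- macrocycle_coords(p2, atom_names)
  if (nrow(m1) == 0 || nrow(m2) == 0) {
    stop("edge_to_edge_distance(): empty macrocycle atom set")
  }
  # all-pairs squared distances via the cross-term expansion
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * m1 %*% t(m2)
  sqrt(max(0, min(d2)))
}

pigment_center <- function(p) {
  if (!is.null(p$mg_position)) {
    list(center = p$mg_position, fallback = FALSE)
  } else {
    m <- macrocycle_coords(p)
    if (nrow(m) == 0) m <- as.matrix(p$atoms[, c("x", "y", "z")])
    list(center = colMeans(m), fallback = TRUE)
  }
}

#' Centre-to-centre (Mg--Mg) distance between two pigments
#'
#' Euclidean distance between the Mg centres; pigments without a central Mg
#' (pheophytins) fall back to the macrocycle centroid, and the returned value
#' carries a `centroid_fallback` attribute flagging that per pigment.
#'
#' @param p1,p2 `frl_pigment` objects.
#' @return Distance in Angstrom with attribute `centroid_fallback`
#'   (logical length 2).
#' @export
mg_mg_distance <- function(p1, p2) {
  c1 <- pigment_center(p1)
  c2 <- pigment_center(p2)
  d <- sqrt(sum((c1$center - c2$center)^2))
  attr(d, "centroid_fallback") <- c(c1$fallback, c2$fallback)
  d
}

#' Read reaction-center pigments from a PDB structure
#'
#' Extracts one pigment per selection entry from the HETATM records of a PDB
#' file (read with \pkg{bio3d}), inferring the chemical type from the residue
#' name via a configurable map.
#'
#' @param structure_path Path to a PDB file.
#' @param selection_map Named list; names are site labels (`P_D1`, `Chl_D1`,
#'   ...), each element a list with `chain`, `resname` (alias `resid`) and
#'   `resno`.
#' @param residue_map Named chr vector residue name -> chem type; see
#'   [default_residue_map()].
#' @param axis_atoms Qy axis nitrogen names, default `c("NB","ND")`.
#' @param dipole_magnitude Either a single Debye value applied to every
#'   pigment or a named vector per chem type (e.g. `c(chl_a = 4.0)`).
#' @return List of `frl_pigment` objects, one per selection entry, atoms in
#'   file order.
#' @examples
#' cl <- make_pigment_cluster(generator_config(seed = 7, n_pigments = 2))
#' sel <- list(Chl_D1 = list(chain = "A", resname = "CLA", resno = 1),
#'             P_D1   = list(chain = "A", resname = "CLA", resno = 2))
#' pigs <- read_pigments(cl$pdb_path, sel)
#' @export
read_pigments <- function(structure_path, selection_map,
                          residue_map = default_residue_map(),
                          axis_atoms = c("NB", "ND"),
                          dipole_magnitude = 4.0) {
  if (!file.exists(structure_path)) {
    stop(sprintf("read_pigments(): file not found: %s", structure_path))
  }
  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  at <- pdb$atom
  out <- vector("list", length(selection_map))
  names(out) <- names(selection_map)
  for (lab in names(selection_map)) {
    sel <- selection_map[[lab]]
    resname <- if (!is.null(sel$resname)) sel$resname else sel$resid
    rows <- at$chain == sel$chain & at$resid == resname & at$resno == sel$resno
    rows[is.na(rows)] <- FALSE
    if (!any(rows)) {
      stop(sprintf(paste0("read_pigments(): selection '%s' (chain %s, residue ",
                          "%s %s) matches no residue in %s"),
                   lab, sel$chain, resname, sel$resno, basename(structure_path)))
    }
    sub <- at[rows, , drop = FALSE]
    element <- sub$elesy
    if (is.null(element) || all(is.na(element))) element <- NA_character_
    # infer element from the atom name where the file lacks element columns
    element <- ifelse(is.na(element) | element == "",
                      ifelse(sub$elety == "MG", "MG",
                             substr(gsub("[0-9]", "", sub$elety), 1, 1)),
                      element)
    atoms <- data.frame(atom_name = sub$elety, element = element,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    if (!resname %in% names(residue_map)) {
      stop(sprintf("read_pigments(): residue name '%s' not in residue map", resname))
    }
    ctype <- unname(residue_map[resname])
    nitro <- intersect(atoms$atom_name, pyrrole_nitrogen_names())
    if (length(nitro) < 4) {
      expected <- if (any(grepl("^N2", nitro))) paste0("N", 21:24) else c("NA", "NB", "NC", "ND")
      miss <- setdiff(expected, atoms$atom_name)
      stop(sprintf("read_pigments(): pigment '%s' is missing pyrrole nitrogen(s) %s",
                   lab, paste(miss, collapse = ", ")))
    }
    mu <- if (length(dipole_magnitude) > 1) {
      if (!ctype %in% names(dipole_magnitude)) {
        stop(sprintf("read_pigments(): no dipole magnitude for chem type '%s'", ctype))
      }
      dipole_magnitude[[ctype]]
    } else dipole_magnitude
    site <- if (lab %in% c("P_D1", "P_D2", "Chl_D1", "Chl_D2", "Pheo_D1", "Pheo_D2"))
      lab else "other"
    out[[lab]] <- pigment(pigment_id = lab, chem_type = ctype, site_label = site,
                          atoms = atoms, dipole_magnitude = mu,
                          axis_atoms = axis_atoms)
  }
  out
}
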