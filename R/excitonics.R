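# Site-basis Frenkel exciton model: Hamiltonian construction from site
# energies and couplings (tabulated, or estimated from structure with the
# point-dipole approximation), eigenstates, oscillator strengths,
# localization measures, and site-energy gaps.

#' Point-dipole excitonic coupling between two pigments
#'
#' Standard dipole-dipole interaction between the Qy transition dipoles,
#' evaluated at the pigment centres (Mg, or macrocycle centroid for
#' pheophytins):
#' \deqn{V = 5034.1 \, f \, \kappa \, \mu_1 \mu_2 / R^3}
#' with \eqn{\mu} in Debye, \eqn{R} in Angstrom, the result in cm^-1, and the
#' orientation factor
#' \eqn{\kappa = \hat\mu_1\cdot\hat\mu_2 -
#'      3(\hat\mu_1\cdot\hat R)(\hat\mu_2\cdot\hat R)}.
#' The sign is physical and carried through.  This is a fast geometric
#' estimator; transition-density-based couplings, where available, should be
#' supplied as tabulated data instead.
#'
#' @param p1,p2 `frl_pigment` objects with dipole magnitudes and axes set.
#' @param screening_f Dimensionless dielectric screening factor; the default
#'   0.72 is a standard empirical value for pigment-protein couplings.
#' @return Coupling in cm^-1 (signed).
#' @export
point_dipole_coupling <- function(p1, p2, screening_f = 0.72) {
  r1 <- pigment_center(p1)$center
  r2 <- pigment_center(p2)$center
  rvec <- r2 - r1
  R <- sqrt(sum(rvec^2))
  if (R <= 2) {
    stop(sprintf(paste0("point_dipole_coupling(): centre distance %.2f A <= 2 A; ",
                        "the point-dipole approximation breaks down"), R))
  }
  rhat <- rvec / R
  u1 <- p1$qy_unit_vector
  u2 <- p2$qy_unit_vector
  kappa <- sum(u1 * u2) - 3 * sum(u1 * rhat) * sum(u2 * rhat)
  frl_constants$dipole_coupling_prefactor * screening_f * kappa *
    p1$dipole_magnitude * p2$dipole_magnitude / R^3
}

validate_exciton_system <- function(sys) {
  n <- length(sys$pigments)
  stopifnot(length(sys$site_energies) == n,
            is.matrix(sys$couplings),
            all(dim(sys$couplings) == c(n, n)))
  if (any(sys$site_energies <= 0.5 | sys$site_energies >= 4.0)) {
    stop("exciton system: site energies outside the (0.5, 4.0) eV sanity window")
  }
  if (max(abs(sys$couplings - t(sys$couplings))) > 1e-12) {
    stop("exciton system: coupling matrix not symmetric")
  }
  if (max(abs(diag(sys$couplings))) > 0) {
    stop("exciton system: coupling matrix must have zero diagonal")
  }
  invisible(sys)
}

#' Construct an exciton system
#'
#' @param pigment_ids Character vector of site identifiers.
#' @param site_energies_ev Qy site energies in eV.
#' @param couplings_ev Symmetric coupling matrix in eV, zero diagonal.
#' @param model_label Free-form label (e.g. `"Chl d @ Chl_D1"`).
#' @param pigments Optional list of `frl_pigment` objects (same order) so
#'   that oscillator strengths can be computed.
#' @return Object of class `frl_exciton_system`.
#' @export
exciton_system <- function(pigment_ids, site_energies_ev, couplings_ev,
                           model_label = "", pigments = NULL) {
  dimnames(couplings_ev) <- list(pigment_ids, pigment_ids)
  sys <- structure(list(
    pigments = pigment_ids,
    site_energies = stats::setNames(as.numeric(site_energies_ev), pigment_ids),
    couplings = couplings_ev,
    model_label = model_label,
    pigment_objects = pigments
  ), class = "frl_exciton_system")
  validate_exciton_system(sys)
}

#' @export
print.frl_exciton_system <- function(x, ...) {
  cat(sprintf("<exciton system '%s'> %d sites\n", x$model_label,
              length(x$pigments)))
  cat("  site energies (eV): ",
      paste(sprintf("%s=%.3f", x$pigments, x$site_energies), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

check_unit_column <- function(tab, what, allowed) {
  if (!"unit" %in% names(tab)) {
    stop(sprintf("build_system(): %s table lacks a 'unit' column", what))
  }
  u <- unique(tab$unit)
  bad <- setdiff(u, allowed)
  if (length(bad)) {
    stop(sprintf("build_system(): %s table has unsupported unit(s): %s",
                 what, paste(bad, collapse = ", ")))
  }
  u
}

#' Build an exciton system from tables or from structure
#'
#' Constructs the site-basis Hamiltonian either from a site-energy table plus
#' an explicit coupling table, or from a site-energy table plus pigment
#' geometry (couplings then estimated with [point_dipole_coupling()]).
#'
#' Tables are data frames (see [read_site_energy_table()] /
#' [read_coupling_table()] for the file dialect): site energies with columns
#' `pigment_id, value, unit` (unit `eV`), couplings with columns
#' `pigment_i, pigment_j, value, unit` (unit `cm-1` or `eV`; conversion uses
#' 1 eV = 8065.544 cm^-1).  Couplings listed for both orientations must agree
#' to 1e-6 eV; disagreement is an error, never silently averaged.
#'
#' @param site_energy_table data.frame of site energies.
#' @param coupling_table data.frame of couplings, or `NULL` to estimate from
#'   `pigments`.
#' @param pigments Optional list of `frl_pigment` objects named or ordered as
#'   the site-energy table.
#' @param screening_f Screening factor for the point-dipole estimate.
#' @param model_label Label stored on the system.
#' @return `frl_exciton_system`.
#' @export
build_system <- function(site_energy_table, coupling_table = NULL,
                         pigments = NULL, screening_f = 0.72,
                         model_label = "") {
  stopifnot(is.data.frame(site_energy_table),
            all(c("pigment_id", "value") %in% names(site_energy_table)))
  check_unit_column(site_energy_table, "site-energy", "eV")
  ids <- as.character(site_energy_table$pigment_id)
  if (anyDuplicated(ids)) stop("build_system(): duplicate pigment ids")
  eps <- as.numeric(site_energy_table$value)
  n <- length(ids)
  V <- matrix(0, n, n, dimnames = list(ids, ids))

  if (!is.null(coupling_table)) {
    stopifnot(all(c("pigment_i", "pigment_j", "value") %in% names(coupling_table)))
    check_unit_column(coupling_table, "coupling", c("cm-1", "eV"))
    off <- unique(c(setdiff(coupling_table$pigment_i, ids),
                    setdiff(coupling_table$pigment_j, ids)))
    if (length(off)) {
      stop(sprintf("build_system(): coupling table ids not in site-energy table: %s",
                   paste(off, collapse = ", ")))
    }
    seen <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (r in seq_len(nrow(coupling_table))) {
      i <- as.character(coupling_table$pigment_i[r])
      j <- as.character(coupling_table$pigment_j[r])
      if (i == j) stop("build_system(): coupling table lists a diagonal entry")
      v <- as.numeric(coupling_table$value[r])
      if (coupling_table$unit[r] == "cm-1") v <- cm1_to_ev(v)
      if (!is.na(seen[j, i]) && abs(seen[j, i] - v) > 1e-6) {
        stop(sprintf(paste0("build_system(): asymmetric coupling input for (%s, %s): ",
                            "%.8f vs %.8f eV"), i, j, seen[j, i], v))
      }
      seen[i, j] <- v
      V[i, j] <- v
      V[j, i] <- if (is.na(seen[j, i])) v else seen[j, i]
    }
  } else if (!is.null(pigments)) {
    if (length(pigments) != n) {
      stop("build_system(): pigment list length does not match site-energy table")
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- cm1_to_ev(point_dipole_coupling(pigments[[i]], pigments[[j]],
                                             screening_f = screening_f))
        V[i, j] <- V[j, i] <- v
      }
    }
  }
  exciton_system(ids, eps, V, model_label = model_label, pigments = pigments)
}

#' Diagonalize an exciton system
#'
#' Eigen-decomposition of the site-basis Hamiltonian.  Eigenvalues are
#' returned ascending; each eigenvector's sign is fixed so that its
#' largest-magnitude coefficient is positive (ties broken by lowest site
#' index).  The participation ratio \eqn{1/\sum_i c_{ki}^4} measures
#' delocalization: 1 for a fully localized state, N for a uniform one.
#'
#' @param sys `frl_exciton_system`.
#' @param pigments Optional pigment list (defaults to the system's own); when
#'   available, oscillator strengths are attached.
#' @return Object of class `frl_exciton_states` with fields `energies` (eV,
#'   ascending), `coefficients` (state x site matrix), `participation_ratios`,
#'   and `oscillator_strengths` (NA when no dipoles are known).
#' @export
diagonalize <- function(sys, pigments = NULL) {
  validate_exciton_system(sys)
  H <- sys$couplings
  diag(H) <- sys$site_energies
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  energies <- eig$values[ord]
  # rows = states, columns = sites
  coef <- t(eig$vectors[, ord, drop = FALSE])
  for (k in seq_len(nrow(coef))) {
    if (coef[k, which.max(abs(coef[k, ]))] < 0) coef[k, ] <- -coef[k, ]
  }
  dimnames(coef) <- list(NULL, sys$pigments)
  pr <- 1 / rowSums(coef^4)
  st <- structure(list(
    energies = energies,
    coefficients = coef,
    participation_ratios = pr,
    oscillator_strengths = rep(NA_real_, length(energies)),
    system = sys
  ), class = "frl_exciton_states")
  if (is.null(pigments)) pigments <- sys$pigment_objects
  if (!is.null(pigments)) {
    st$oscillator_strengths <- oscillator_strengths(st, pigments)
  }
  st
}

#' @export
print.frl_exciton_states <- function(x, ...) {
  cat(sprintf("<exciton states> %d states\n", length(x$energies)))
  f <- x$oscillator_strengths
  for (k in seq_along(x$energies)) {
    cat(sprintf("  %d: %.4f eV (%d nm)  PR %.2f  f %s%s\n", k, x$energies[k],
                report_nm(x$energies[k]), x$participation_ratios[k],
                ifelse(is.na(f[k]), "NA", sprintf("%.4f", f[k])),
                ifelse(!is.na(f[k]) && f[k] < 1e-4, " (dark)", "")))
  }
  invisible(x)
}

dipole_matrix <- function(pigments, n) {
  if (is.matrix(pigments)) {
    stopifnot(nrow(pigments) == n, ncol(pigments) == 3)
    return(pigments)
  }
  t(vapply(pigments, function(p) p$dipole_magnitude * p$qy_unit_vector,
           numeric(3)))
}

#' Oscillator strengths of exciton states
#'
#' The exciton transition dipole is the coefficient-weighted sum of the site
#' dipoles, \eqn{\vec\mu_k = \sum_i c_{ki} \mu_i \hat\mu_i}, and
#' \deqn{f_k = 4.702\times 10^{-7} \tilde E_k(\mathrm{cm}^{-1}) |\vec\mu_k|^2 (\mathrm{D}^2).}
#' States with f below 1e-4 are conventionally reported as dark.
#'
#' @param states `frl_exciton_states`.
#' @param pigments List of `frl_pigment` objects (site order), or an
#'   N x 3 matrix of site transition-dipole vectors in Debye.
#' @return Non-negative numeric vector, one value per state.
#' @export
oscillator_strengths <- function(states, pigments) {
  n <- ncol(states$coefficients)
  mu_site <- dipole_matrix(pigments, n)
  mu_exc <- states$coefficients %*% mu_site    # states x 3
  mu2 <- rowSums(mu_exc^2)
  frl_constants$oscillator_prefactor * ev_to_cm1(states$energies) * mu2
}

resolve_site <- function(sys, site) {
  if (site %in% sys$pigments) return(unname(sys$site_energies[site]))
  # the special pair is tabulated as one value assigned to both P_D1 and P_D2
  if (site %in% c("P_D1/P_D2", "P_D2/P_D1") &&
      all(c("P_D1", "P_D2") %in% sys$pigments)) {
    return(unname(mean(sys$site_energies[c("P_D1", "P_D2")])))
  }
  stop(sprintf("site_energy_gap(): unknown site '%s' (sites: %s)", site,
               paste(sys$pigments, collapse = ", ")))
}

#' Signed site-energy gap between two sites
#'
#' Returns \eqn{\epsilon_a - \epsilon_b} in eV.  The alias `"P_D1/P_D2"`
#' resolves to the special-pair site energy (the mean of P_D1 and P_D2; the
#' two are equal in the shipped fixtures, where the tabulated pair value is
#' assigned to both diagonals).
#'
#' @param sys `frl_exciton_system`.
#' @param site_a,site_b Site identifiers.
#' @return Gap in eV (signed).
#' @examples
#' fx <- psii_fixtures()
#' site_energy_gap(fx$systems[["chl_d_at_chl_d1"]], "P_D1/P_D2", "Chl_D1")
#' @export
site_energy_gap <- function(sys, site_a, site_b) {
  resolve_site(sys, site_a) - resolve_site(sys, site_b)
}
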