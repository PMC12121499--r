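# Independent oracles used across the suite: closed forms and brute-force
# evaluations kept deliberately separate from the package implementation.

# Closed-form eigenvalues of a two-site exciton Hamiltonian.
dimer_eigenvalues <- function(e1, e2, v) {
  mean_e <- (e1 + e2) / 2
  split <- sqrt((e1 - e2)^2 / 4 + v^2)
  c(mean_e - split, mean_e + split)
}

# Brute-force minimum distance over all atom pairs of two coordinate sets.
brute_min_distance <- function(m1, m2) {
  best <- Inf
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m2))) {
      best <- min(best, sqrt(sum((m1[i, ] - m2[j, ])^2)))
    }
  }
  best
}

# Minimal pigment with an explicit dipole geometry, for coupling tests.
toy_pigment <- function(id, center, axis, mu = 4.0) {
  axis <- axis / sqrt(sum(axis^2))
  # any vector perpendicular to the axis, for the NA/NC placeholders
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  pos <- rbind(c(0, 0, 0), perp, -axis, -perp, axis) * 2.05
  atoms <- data.frame(
    atom_name = c("MG", "NA", "NB", "NC", "ND"),
    element = c("MG", "N", "N", "N", "N"),
    x = center[1] + pos[, 1],
    y = center[2] + pos[, 2],
    z = center[3] + pos[, 3],
    stringsAsFactors = FALSE
  )
  pigment(id, "chl_a", "other", atoms, dipole_magnitude = mu)
}

# A square planar "macrocycle" of four atoms around a center (z-normal).
square_ring_pigment <- function(id, center, half = 2.0, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dx <- c(half, -half, -half, half)
  dy <- c(half, half, -half, -half)
  atoms <- data.frame(
    atom_name = paste0("C", 1:4),
    element = "C",
    x = center[1] + dx + stats::runif(4, -jitter, jitter),
    y = center[2] + dy + stats::runif(4, -jitter, jitter),
    z = center[3] + stats::runif(4, -jitter, jitter),
    stringsAsFactors = FALSE
  )
  # add the axis nitrogens so the constructor can define a Qy axis
  atoms <- rbind(atoms, data.frame(
    atom_name = c("NA", "NB", "NC", "ND"), element = "N",
    x = center[1] + c(0, -1, 0, 1), y = center[2] + c(1, 0, -1, 0),
    z = center[3], stringsAsFactors = FALSE))
  pigment(id, "chl_a", "other", atoms)
}

kT_298 <- 8.61733e-5 * 298.15
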