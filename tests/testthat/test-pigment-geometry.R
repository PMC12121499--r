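test_that("qy_axis follows the NB->ND nitrogen axis with deterministic sign", {
  mk <- function(nb, nd) {
    atoms <- data.frame(atom_name = c("NA", "NB", "NC", "ND"),
                        element = "N",
                        x = c(0, nb[1], 1, nd[1]),
                        y = c(1, nb[2], -1, nd[2]),
                        z = c(0, nb[3], 0, nd[3]),
                        stringsAsFactors = FALSE)
    pigment("p", "chl_a", "other", atoms)
  }
  expect_equal(mk(c(0, 0, 0), c(2, 0, 0))$qy_unit_vector, c(1, 0, 0))
  expect_equal(mk(c(0, 0, 0), c(1, 1, 0))$qy_unit_vector,
               c(1, 1, 0) / sqrt(2), tolerance = 1e-9)
  expect_error(mk(c(1, 1, 0), c(1, 1, 0)), "zero-length")
})

test_that("qy_axis is translation invariant and rotation equivariant", {
  cl <- make_pigment_cluster(generator_config(seed = 11, n_pigments = 1))
  p <- cl$pigments[[1]]
  shift <- c(5.3, -2.1, 7.7)
  p_shift <- p
  p_shift$atoms[, c("x", "y", "z")] <- sweep(p$atoms[, c("x", "y", "z")], 2,
                                             -shift)
  expect_equal(qy_axis(p_shift), qy_axis(p), tolerance = 1e-9)

  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  p_rot <- p
  p_rot$atoms[, c("x", "y", "z")] <-
    as.matrix(p$atoms[, c("x", "y", "z")]) %*% t(R)
  expect_equal(qy_axis(p_rot), as.numeric(R %*% qy_axis(p)), tolerance = 1e-9)
})

test_that("edge-to-edge distance matches the brute-force minimum over atom pairs", {
  # two single-atom "macrocycles"
  a <- pigment("a", "chl_a", "other",
               data.frame(atom_name = c("C1", "NA", "NB", "NC", "ND"),
                          element = c("C", "N", "N", "N", "N"),
                          x = c(0, 0, -1, 0, 1), y = c(0, 1, 0, -1, 0),
                          z = c(0, 0, 0, 0, 0), stringsAsFactors = FALSE))
  b <- a
  b$atoms$z <- b$atoms$z + 3.5
  expect_equal(edge_to_edge_distance(a, b, atom_names = "C1"), 3.5)

  # jittered square rings offset along z: equals brute force, lands in band
  set.seed(42)
  for (rep in 1:5) {
    p1 <- square_ring_pigment("p1", c(0, 0, 0), jitter = 0.1)
    p2 <- square_ring_pigment("p2", c(0, 0, 3.53), jitter = 0.1)
    d <- edge_to_edge_distance(p1, p2)
    oracle <- brute_min_distance(macrocycle_coords <- as.matrix(
      p1$atoms[p1$atoms$element %in% c("C", "N"), c("x", "y", "z")]),
      as.matrix(p2$atoms[p2$atoms$element %in% c("C", "N"), c("x", "y", "z")]))
    expect_equal(d, oracle, tolerance = 1e-12)
    expect_gte(d, 3.53 - 3 * 0.1)
    expect_lte(d, 3.53 + 3 * 0.1)
    expect_equal(edge_to_edge_distance(p2, p1), d)  # symmetry
  }
})

test_that("mg_mg_distance uses Mg centres with centroid fallback for pheophytins", {
  a <- toy_pigment("a", c(0, 0, 0), c(1, 0, 0))
  b <- toy_pigment("b", c(0, 0, 8.2), c(1, 0, 0))
  expect_equal(as.numeric(mg_mg_distance(a, b)), 8.2)
  expect_equal(attr(mg_mg_distance(a, b), "centroid_fallback"), c(FALSE, FALSE))

  # strip the Mg: centroid fallback, flagged, equals the brute-force centroid
  b_pheo <- b
  b_pheo$atoms <- b_pheo$atoms[b_pheo$atoms$atom_name != "MG", ]
  b_pheo$mg_position <- NULL
  d <- mg_mg_distance(a, b_pheo)
  expect_true(attr(d, "centroid_fallback")[2])
  centroid <- colMeans(b_pheo$atoms[, c("x", "y", "z")])
  expect_equal(as.numeric(d), sqrt(sum((centroid - c(0, 0, 0))^2)),
               tolerance = 1e-12)
})

test_that("edge-to-edge never exceeds the centre distance plus both ring radii", {
  set.seed(7)
  for (rep in 1:10) {
    c1 <- runif(3, -5, 5); c2 <- c1 + c(runif(1, 6, 12), runif(2, -2, 2))
    p1 <- square_ring_pigment("p1", c1, jitter = 0.2)
    p2 <- square_ring_pigment("p2", c2, jitter = 0.2)
    d_edge <- edge_to_edge_distance(p1, p2)
    d_c <- as.numeric(mg_mg_distance(p1, p2))
    rad <- function(p) {
      ctr <- colMeans(p$atoms[, c("x", "y", "z")])
      max(sqrt(rowSums(sweep(as.matrix(p$atoms[, c("x", "y", "z")]), 2, ctr)^2)))
    }
    expect_lte(d_edge, d_c + rad(p1) + rad(p2) + 1e-9)
    expect_gte(d_edge, 0)
  }
})

test_that("read_pigments extracts mapped residues and reports missing ones", {
  cl <- make_pigment_cluster(generator_config(seed = 7, n_pigments = 2,
                                              inter_pigment_spacing = 9))
  pigs <- read_pigments(cl$pdb_path, cl$selection_map)
  expect_length(pigs, 2)
  expect_equal(pigs[[1]]$chem_type, "chl_a")
  expect_equal(nrow(pigs[[1]]$atoms), 21)
  # coordinates round-trip at PDB precision
  for (i in 1:2) {
    expect_equal(as.matrix(pigs[[i]]$atoms[, c("x", "y", "z")]),
                 as.matrix(cl$pigments[[i]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  expect_error(
    read_pigments(cl$pdb_path, list(P_D1 = list(chain = "Z", resname = "CLA",
                                                resno = 1))),
    "P_D1")
})
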