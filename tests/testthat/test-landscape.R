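test_that("backbone RMSD behaves as a pseudo-metric with symmetry credit", {
  a <- closed_gly_ring(8, seed = 1)
  expect_equal(backbone_rmsd(a, a), 0, tolerance = 1e-12)
  ## rigid motion: zero
  R <- cycpep:::rodrigues_matrix(cycpep:::unitv(c(2, -1, 1)), 61)
  b <- a
  for (i in 1:8) for (s in seq_along(cycpep:::.atom_slots)) {
    if (!anyNA(a$coords[i, s, ])) {
      b$coords[i, s, ] <- as.numeric(a$coords[i, s, ] %*% R) + c(-4, 2, 9)
    }
  }
  expect_lt(backbone_rmsd(a, b), 1e-9)
  ## mirror image needs the mirror flag for a chiral structure
  m <- mirror_conformation(a)
  expect_gt(backbone_rmsd(a, m), 0.1)
  expect_lt(backbone_rmsd(a, m, allow_mirror = TRUE), 1e-9)
  ## cyclic relabeling needs the permutation flag
  p <- cyclic_permute(a, 3)
  expect_lt(backbone_rmsd(a, p, allow_cyclic_perm = TRUE), 1e-9)
  ## symmetry and triangle inequality on random triples
  set.seed(12)
  confs <- lapply(1:3, function(s) closed_gly_ring(8, seed = s + 4))
  d12 <- backbone_rmsd(confs[[1]], confs[[2]])
  d21 <- backbone_rmsd(confs[[2]], confs[[1]])
  d13 <- backbone_rmsd(confs[[1]], confs[[3]])
  d23 <- backbone_rmsd(confs[[2]], confs[[3]])
  expect_equal(d12, d21, tolerance = 1e-9)
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("minimisation never increases the energy and keeps the ring shut", {
  ring <- closed_gly_ring(7, seed = 3)
  e0 <- score_conformation(ring)$total
  mm <- minimize_conformation(ring, max_iter = 12)
  expect_lte(mm$energy, e0)
  expect_equal(mm$initial, e0, tolerance = 1e-9)
  gg <- closure_geometry(mm$conformation)
  expect_lt(abs(gg$bondlength - ideal_geometry()$closure$bondlength), 0.1)
  ## re-minimising an already-relaxed structure changes little
  mm2 <- minimize_conformation(mm$conformation, max_iter = 12)
  expect_lte(mm2$energy, mm$energy)
  expect_lte(mm$energy - mm2$energy, 0.5)
  expect_lt(backbone_rmsd(mm$conformation, mm2$conformation), 0.5)
  ## mirrored input minimises to the mirrored output
  mmi <- minimize_conformation(mirror_conformation(ring), max_iter = 12)
  expect_equal(mmi$energy, mm$energy, tolerance = 1e-6)
})

test_that("landscape prediction is seeded and always includes LE_0", {
  ring <- closed_gly_ring(6, seed = 2)
  ls0 <- predict_landscape(ring$seq, ring, n_samples = 0, rng_seed = 1,
                           minimize_iter = 5)
  expect_identical(nrow(ls0$points), 1L)
  expect_true(ls0$points$is_design[1])
  ls1 <- predict_landscape(ring$seq, ring, n_samples = 3, rng_seed = 9,
                           attempts_per_sample = 40, minimize_iter = 5)
  ls2 <- predict_landscape(ring$seq, ring, n_samples = 3, rng_seed = 9,
                           attempts_per_sample = 40, minimize_iter = 5)
  expect_identical(ls1$points, ls2$points)
  expect_true(any(ls1$points$is_design))
  expect_true(all(ls1$points$rmsd >= 0))
})

test_that("leader clustering partitions points with stable labels", {
  ## two artificial basins far beyond the cutoff
  a <- closed_gly_ring(8, seed = 1)
  b <- closed_gly_ring(8, seed = 2)
  stopifnot(backbone_rmsd(a, b) > 1.0)
  jig <- function(conf, eps) {
    out <- conf
    out$coords <- conf$coords + eps
    out
  }
  confs <- list(jig(a, 0), jig(a, 0.01), jig(b, 0), jig(b, 0.01), jig(b, 0.02))
  energies <- c(-5, -4.5, -3, -2.5, -2)
  cl <- energy_based_cluster(confs, n_lowest = NULL, rmsd_cutoff = 1.0,
                             energies = energies)
  expect_identical(nrow(cl), 5L)
  expect_identical(length(unique(cl$cluster)), 2L)
  ## lowest-energy cluster is LE_1, every point assigned exactly once
  expect_identical(cl$cluster[which.min(cl$energy)], "LE_1")
  expect_false(anyNA(cl$cluster))
  ## shuffling the input leaves the labelling invariant
  perm <- c(4, 1, 5, 2, 3)
  cl2 <- energy_based_cluster(confs[perm], n_lowest = NULL, rmsd_cutoff = 1.0,
                              energies = energies[perm])
  expect_identical(sort(table(cl$cluster)), sort(table(cl2$cluster)))
  expect_identical(cl$cluster[order(cl$energy)],
                   cl2$cluster[order(cl2$energy)])
  ## all-identical points collapse to one cluster
  same <- energy_based_cluster(list(a, a, a), n_lowest = NULL,
                               energies = c(1, 2, 3))
  expect_identical(length(unique(same$cluster)), 1L)
})

test_that("isoenergetic state detection honours the 5-unit threshold", {
  mk <- function(E, om) data.frame(id = paste0("s", seq_along(E)), energy = E,
                                   rmsd = 0, cluster = paste0("LE_", seq_along(E)),
                                   center = TRUE, omega_signature = om,
                                   stringsAsFactors = FALSE)
  one <- mk(-10, "tttt")
  expect_identical(nrow(detect_isoenergetic_states(one)), 0L)
  close2 <- mk(c(-10, -7), c("tttt", "ttct"))
  got <- detect_isoenergetic_states(close2)
  expect_identical(nrow(got), 1L)
  expect_equal(got$delta_energy, 3)
  expect_true(got$cis_trans_switch)
  far2 <- mk(c(-10, -2), c("tttt", "tttt"))
  expect_identical(nrow(detect_isoenergetic_states(far2)), 0L)
})

test_that("the funnel summary splits the design basin from alternatives", {
  pts <- data.frame(id = c("LE_0_design", "S1", "S2"),
                    energy = c(-12, -4, -6),
                    rmsd = c(0.2, 3.5, 4.0),
                    omega_signature = "tttttt",
                    is_design = c(TRUE, FALSE, FALSE))
  fs <- funnel_summary(pts)
  expect_equal(fs$delta_e, -6 - (-12))
  expect_identical(fs$lowest$id, "LE_0_design")
})
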