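test_that("total energy is a weighted sum of its terms", {
  conf <- closed_gly_ring(8)
  for (ws in c("standard", "closure_selection", "hbond_upweighted")) {
    eb <- score_conformation(conf, ws)
    w <- weight_set(ws)
    manual <- sum(vapply(names(w), function(t) w[[t]] * eb[[t]], numeric(1)))
    expect_equal(eb$total, manual, tolerance = 1e-12)
  }
  expect_error(weight_set("nonsense"), "unknown")
  expect_error(weight_set(c(fa_rep = -1)), "non-negative")
})

test_that("the closure-selection weight set carries the printed weights", {
  w <- weight_set("closure_selection")
  expect_equal(unname(w[c("fa_rep", "fa_atr", "hbond_sr_bb", "hbond_lr_bb",
                          "rama_prepro", "omega", "p_aa_pp")]),
               c(0.1, 0.2, 2.0, 2.0, 0.45, 0.4, 0.6))
  wu <- weight_set("hbond_upweighted")
  expect_equal(unname(wu["hbond_sr_bb"]), 5.0)
  expect_equal(unname(wu["hbond_lr_bb"]), 5.0)
})

test_that("energies are invariant under mirroring and cyclic permutation", {
  set.seed(17)
  for (n in c(6, 8, 11)) {
    for (rep in 1:3) {
      conf <- random_open_conf(n, seed = n * 10 + rep)
      e0 <- score_conformation(conf)
      em <- score_conformation(mirror_conformation(conf))
      for (t in cycpep:::.energy_terms) {
        expect_lt(abs(e0[[t]] - em[[t]]), 1e-9)
      }
      k <- sample(n - 1, 1)
      ep <- score_conformation(cyclic_permute(conf, k))
      expect_lt(abs(e0$total - ep$total),
                1e-9 * max(1, abs(e0$total)))
    }
  }
})

test_that("the hydrogen-bond form behaves at ideal and weak geometry", {
  e_ideal <- hbond_energy(1.9, 180, 125)
  expect_lte(e_ideal, -0.25)
  expect_gt(e_ideal, -1.05)
  expect_gt(hbond_energy(4.5, 180, 125), -0.25)  # far: not reportable
  ## monotone weakening with distance beyond the optimum
  d <- seq(2.0, 3.5, by = 0.1)
  e <- hbond_energy(d, 180, 125)
  expect_true(all(diff(e) >= 0))
})

test_that("detected hydrogen bonds respect the separation exclusion", {
  for (n in c(6, 8, 10)) {
    ring <- closed_gly_ring(n, seed = 2)
    hb <- detect_backbone_hbonds(ring, energy_cutoff = 0)
    if (nrow(hb)) {
      expect_true(all(cycpep:::cyclic_separation(hb$donor, hb$acceptor, n) >= 3))
    }
  }
})

test_that("hbond terms in the breakdown equal the sum over detected bonds", {
  found <- FALSE
  for (s in 1:6) {
    ring <- closed_gly_ring(8, seed = s)
    hb <- detect_backbone_hbonds(ring)
    eb <- score_conformation(ring)
    expect_equal(eb$hbond_sr_bb + eb$hbond_lr_bb, sum(hb$energy),
                 tolerance = 1e-12)
    expect_identical(count_internal_hbonds(ring), nrow(hb))
    if (nrow(hb) > 0) found <- TRUE
  }
  expect_true(found)
})

test_that("unsatisfied-NH analysis skips proline and N-methyl positions", {
  seq <- macrocycle_sequence(
    c("ALA", "PRO", "LEU", "GLY", "VAL", "PHE"),
    c("L", "D", "L", "achiral", "D", "L"),
    c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  set.seed(9)
  pp <- cycpep:::sample_flat_symm(6)
  conf <- build_from_torsions(seq, cbind(phi = pp[, 1], psi = pp[, 2],
                                         omega = rep(180, 6)))
  unsat <- find_unsatisfied_nh(conf)
  expect_false(1 %in% unsat)  # N-methylated
  expect_false(2 %in% unsat)  # proline
  ## with an impossible cutoff nothing is satisfied except non-donors
  expect_identical(find_unsatisfied_nh(conf, energy_cutoff = -10),
                   c(3L, 4L, 5L, 6L))
})

test_that("a fully donating ring reports an empty unsatisfied set", {
  ## synthetic fixture: every NH is placed in an exact hydrogen bond to the
  ## carbonyl three positions ahead
  ring <- closed_gly_ring(8, seed = 3)
  fake <- ring
  for (i in 1:8) {
    fake <- place_ideal_hbond(fake, i, (i + 2) %% 8 + 1)
  }
  expect_length(find_unsatisfied_nh(fake), 0)
})

test_that("oversaturated acceptors are detected with the per-O maximum of 2", {
  ring <- closed_gly_ring(8, seed = 3)
  ## no hydrogen bonds at an impossible cutoff: trivially a pass
  expect_true(check_oversaturated_acceptors(ring, energy_cutoff = -10)$pass)
  ## two donors on one carbonyl: still a pass (a soft reporting cutoff keeps
  ## the slightly off-axis second and third approaches reportable)
  two <- place_ideal_hbond(ring, 1, 5)
  two <- aim_donor_at(two, 2, 5)
  hb2 <- detect_backbone_hbonds(two, energy_cutoff = -0.01)
  expect_gte(sum(hb2$acceptor == 5), 2)
  expect_true(check_oversaturated_acceptors(two, energy_cutoff = -0.01)$pass)
  ## a third donor oversaturates the acceptor
  three <- aim_donor_at(two, 8, 5)
  res3 <- check_oversaturated_acceptors(three, energy_cutoff = -0.01)
  expect_false(res3$pass)
  expect_true(5 %in% res3$offenders)
})

test_that("distant fragments contribute no nonbonded or hbond energy", {
  ## two residues pulled 50 A apart: all pair terms vanish
  seq <- macrocycle_sequence(rep("ALA", 6), rep("L", 6), strict = FALSE)
  set.seed(1)
  pp <- cycpep:::sample_flat_symm(6)
  conf <- build_from_torsions(seq, cbind(phi = pp[, 1], psi = pp[, 2],
                                         omega = rep(180, 6)))
  far <- conf
  for (a in seq_along(cycpep:::.atom_slots)) {
    if (!anyNA(far$coords[4, a, ])) {
      far$coords[4, a, ] <- far$coords[4, a, ] + c(50, 0, 0)
    }
  }
  eb0 <- score_conformation(conf)
  eb1 <- score_conformation(far)
  ## residue 4 is now beyond every cutoff: its pair terms are absent
  hb <- detect_backbone_hbonds(far)
  expect_false(4 %in% hb$donor)
  expect_false(4 %in% hb$acceptor)
})
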