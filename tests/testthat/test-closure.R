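test_that("closure solutions reproduce the ideal closure-bond geometry", {
  g <- ideal_geometry()$closure
  set.seed(2)
  n <- 8
  seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
  checked <- 0
  for (k in 1:30) {
    pp <- cycpep:::sample_flat_symm(n)
    tor <- cbind(phi = pp[, 1], psi = pp[, 2], omega = rep(180, n))
    sol <- solve_closure(closure_problem(seq, tor, c(2, 5, 7)))
    for (conf in sol$solutions) {
      gg <- closure_geometry(conf)
      expect_lt(abs(gg$bondlength - g$bondlength), 1e-4)
      expect_lt(abs(gg$angle_n - g$angle1), 1e-3)
      expect_lt(abs(gg$angle_c - g$angle2), 1e-3)
      expect_lt(abs(wrap_angle(gg$omega - 180)), 1e-3)
      checked <- checked + 1
    }
    if (checked >= 20) break
  }
  expect_gte(checked, 10)
})

test_that("erase-and-resolve recovers the original pivot torsions", {
  set.seed(31)
  for (n in c(6, 9, 12)) {
    seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
    done <- 0
    tries <- 0
    while (done < 4 && tries < 80) {
      tries <- tries + 1
      pp <- cycpep:::sample_flat_symm(n)
      tor <- cbind(phi = pp[, 1], psi = pp[, 2], omega = rep(180, n))
      pv <- cycpep:::default_pivots(sample.int(n, 1), n)
      sol <- solve_closure(closure_problem(seq, tor, pv),
                           grid_size = 360, thorough = FALSE)
      if (!length(sol$solutions)) next
      ring <- sol$solutions[[1]]
      pv2 <- cycpep:::default_pivots(cycpep:::cyc_next(max(pv), n), n)
      re <- solve_closure(closure_problem(seq, ring$torsions, pv2))
      orig <- as.numeric(t(ring$torsions[pv2, c("phi", "psi")]))
      expect_gt(nrow(re$pivot_torsions), 0)
      best <- min(apply(re$pivot_torsions, 1,
                        function(z) max(cycpep:::ang_dist(z, orig))))
      expect_lt(best, 1e-3)
      done <- done + 1
    }
    expect_gte(done, 2)
  }
})

test_that("an overstretched chain returns the empty solution set", {
  n <- 6
  seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
  tor <- cbind(phi = rep(180, n), psi = rep(180, n), omega = rep(180, n))
  ## adjacent pivots leave a long fully extended wrap segment that cannot
  ## span the remaining virtual-bond triangle
  sol <- solve_closure(closure_problem(seq, tor, c(2, 3, 4)))
  expect_length(sol$solutions, 0)
})

test_that("a mirrored closure problem yields the mirrored solution set", {
  set.seed(5)
  n <- 8
  seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
  found <- FALSE
  for (k in 1:30) {
    pp <- cycpep:::sample_flat_symm(n)
    tor <- cbind(phi = pp[, 1], psi = pp[, 2], omega = rep(180, n))
    sol <- solve_closure(closure_problem(seq, tor, c(2, 5, 7)))
    if (!length(sol$solutions)) next
    msol <- solve_closure(closure_problem(seq, wrap_angle(-tor), c(2, 5, 7)))
    expect_equal(length(msol$solutions), length(sol$solutions))
    ## every solution's mirror appears in the mirrored set, same energy
    for (i in seq_along(sol$solutions)) {
      six <- sol$pivot_torsions[i, ]
      hit <- min(apply(msol$pivot_torsions, 1, function(z) {
        max(cycpep:::ang_dist(z, -six))
      }))
      expect_lt(hit, 1e-6)
      eA <- score_conformation(sol$solutions[[i]], "closure_selection")$total
      eB <- score_conformation(mirror_conformation(sol$solutions[[i]]),
                               "closure_selection")$total
      expect_lt(abs(eA - eB), 1e-9)
    }
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("the backbone sampler is deterministic and honours its filters", {
  n <- 7
  seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
  pol <- backbone_acceptance_policy()
  a <- sample_cyclic_backbones(seq, 120, rng_seed = 3, policy = pol)
  b <- sample_cyclic_backbones(seq, 120, rng_seed = 3, policy = pol)
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))
  expect_gte(length(a), 1)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$torsions, b[[i]]$torsions)
    expect_gte(count_internal_hbonds(a[[i]]),
               min_hbonds_for_length(n, pol$min_hbonds_policy))
    expect_true(loop_bump_check(a[[i]]))
    expect_true(is_closed(a[[i]]))
  }
  ## the mirrored stream with the mirrored sequence gives the exact mirror
  am <- sample_cyclic_backbones(seq, 120, rng_seed = 3, policy = pol,
                                mirror = TRUE)
  expect_equal(length(am), length(a))
  for (i in seq_along(a)) {
    expect_lt(max(abs(wrap_angle(am[[i]]$torsions + a[[i]]$torsions))), 1e-9)
    eA <- score_conformation(a[[i]], "closure_selection")$total
    eB <- score_conformation(am[[i]], "closure_selection")$total
    expect_lt(abs(eA - eB), 1e-9)
  }
})

test_that("hydrogen-bond minimum policies follow the published schedules", {
  expect_identical(vapply(6:12, min_hbonds_for_length, integer(1)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_identical(vapply(6:12, min_hbonds_for_length, integer(1),
                          policy = "fixed2"), rep(2L, 7))
})

test_that("the rama filter mirrors correctly and saturates at +Inf", {
  ring <- closed_gly_ring(8)
  seqL <- macrocycle_sequence(rep("ALA", 8), rep("L", 8), strict = FALSE)
  confL <- cycpep:::thread_sequence(ring, seqL)
  confL$torsions[1, c("phi", "psi")] <- c(-60, -45)
  expect_true(rama_prepro_check(confL, 1, cutoff = 2))
  seqD <- macrocycle_sequence(rep("ALA", 8), rep("D", 8), strict = FALSE)
  confD <- cycpep:::thread_sequence(ring, seqD)
  confD$torsions[1, c("phi", "psi")] <- c(-60, -45)
  expect_false(rama_prepro_check(confD, 1, cutoff = 2))
  expect_true(rama_prepro_check(confD, 1, cutoff = Inf))
})

test_that("the bump check is rigid-motion invariant and detects clashes", {
  ring <- closed_gly_ring(6)
  expect_true(loop_bump_check(ring))
  R <- cycpep:::rodrigues_matrix(c(0, 0, 1), 40)
  moved <- ring
  for (i in 1:6) for (a in seq_along(cycpep:::.atom_slots)) {
    if (!anyNA(ring$coords[i, a, ])) {
      moved$coords[i, a, ] <- as.numeric(ring$coords[i, a, ] %*% R) + 5
    }
  }
  expect_true(loop_bump_check(moved))
  clash <- ring
  clash$coords[4, "O", ] <- clash$coords[1, "N", ] + c(0.5, 0, 0)
  expect_false(loop_bump_check(clash))
})
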