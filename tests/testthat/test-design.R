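test_that("the printed PHE composition penalty evaluates to 0 / 5 / 25", {
  cc <- phe_composition_constraint()
  mk <- function(nphe) {
    aa <- c(rep("PHE", nphe), rep("ALA", 6 - nphe))
    macrocycle_sequence(aa, rep("L", 6), strict = FALSE)
  }
  expect_equal(composition_penalty(mk(2), cc), 0)
  expect_equal(composition_penalty(mk(3), cc), 5)
  expect_equal(composition_penalty(mk(4), cc), 25)
  ## below-range deltas extrapolate as a constant
  expect_equal(composition_penalty(mk(0), cc), 0)
  ## D-PHE counts towards the same constraint
  aa <- c(rep("PHE", 2), "PHE", rep("ALA", 3))
  seqd <- macrocycle_sequence(aa, c("L", "L", "D", "L", "L", "L"),
                              strict = FALSE)
  expect_equal(composition_penalty(seqd, cc), 5)
})

test_that("composition constraints validate their penalty tables", {
  expect_error(composition_constraint("PHE", 2, penalties = c(0, 0)),
               "length")
  expect_error(composition_constraint("PHE", 2,
                                      penalties = c(0, 0, -1, 5, 25)),
               "non-negative")
})

test_that("chirality restricts the per-position design alphabet", {
  ring <- closed_gly_ring(8)
  alpha <- chirality_allowed_alphabet(ring)
  phi <- ring$torsions[, "phi"]
  ab <- design_alphabets()
  for (i in 1:8) {
    expect_setequal(alpha[[i]], if (phi[i] > 0) ab$D else ab$L)
  }
  ## mirroring swaps the alphabets position-wise
  alpha_m <- chirality_allowed_alphabet(mirror_conformation(ring))
  phi_m <- -phi
  for (i in 1:8) {
    expect_setequal(alpha_m[[i]], if (phi_m[i] > 0) ab$D else ab$L)
  }
})

test_that("design respects alphabets, is seeded, and matches brute force", {
  ring <- closed_gly_ring(6)
  pol <- design_policy()
  s1 <- design_sequence(ring, pol, rng_seed = 5, steps = 300)
  s2 <- design_sequence(ring, pol, rng_seed = 5, steps = 300)
  expect_identical(s1$aa, s2$aa)
  alpha <- chirality_allowed_alphabet(ring, pol)
  for (i in 1:6) expect_true(s1$aa[i] %in% alpha[[i]])

  ## exhaustive oracle on a two-letter alphabet: enumerate every assignment
  ## and minimise the public design objective directly
  pol2 <- design_policy(alphabets = list(L = c("ALA", "LEU"),
                                         D = c("ALA", "LEU")))
  alpha2 <- chirality_allowed_alphabet(ring, pol2)
  grid <- expand.grid(alpha2, stringsAsFactors = FALSE)
  energies <- apply(grid, 1, function(aa) {
    design_energy(ring, as.character(aa), "standard")
  })
  best <- min(energies)
  got <- design_sequence(ring, pol2, rng_seed = 2, steps = 400)
  expect_equal(design_energy(ring, got$aa, "standard"), best,
               tolerance = 1e-9)
})

test_that("remedy converts unsatisfied donors to proline or N-methyl", {
  ring <- closed_gly_ring(8, seed = 4)
  seq <- macrocycle_sequence(rep("ALA", 8),
                             ifelse(ring$torsions[, "phi"] > 0, "D", "L"),
                             strict = FALSE)
  conf <- cycpep:::thread_sequence(ring, seq)
  unsat <- find_unsatisfied_nh(conf)
  out <- remedy_unsatisfied(ring, seq)
  for (i in unsat) {
    pb <- proline_bin(ring$torsions[i, "phi"], ring$torsions[i, "psi"])
    if (pb$compatible) {
      expect_identical(out$aa[i], "PRO")
      expect_identical(out$chirality[i], pb$hand)
      expect_false(out$n_methyl[i])
    } else {
      expect_true(out$n_methyl[i])
    }
  }
  ## satisfied positions untouched
  sat <- setdiff(1:8, unsat)
  expect_identical(out$aa[sat], seq$aa[sat])
  expect_identical(out$n_methyl[sat], seq$n_methyl[sat])
  ## an empty unsatisfied set leaves the sequence unchanged
  fake <- conf
  for (i in 1:8) fake <- place_ideal_hbond(fake, i, (i + 2) %% 8 + 1)
  expect_identical(remedy_unsatisfied(fake, fake$seq), fake$seq)
})

test_that("proline-bin membership drives the remedy branch", {
  expect_true(proline_bin(-60, -30)$compatible)   # helical, L hand
  expect_identical(proline_bin(-60, -30)$hand, "L")
  expect_identical(proline_bin(60, 30)$hand, "D")
  expect_true(proline_bin(60, 30)$compatible)
  expect_false(proline_bin(-130, 130)$compatible)  # strand-like
})

test_that("design filters and the protocol contract hold end to end", {
  ring <- closed_gly_ring(7, seed = 2)
  rec <- run_design_protocol(ring, rng_seed = 21, anneal_steps = 400,
                             minimize_iter = 10)
  ## reproducibility
  rec2 <- run_design_protocol(ring, rng_seed = 21, anneal_steps = 400,
                              minimize_iter = 10)
  expect_identical(rec$sequence$aa, rec2$sequence$aa)
  expect_identical(rec$verdicts, rec2$verdicts)
  ## verdicts recompute from the stored conformation alone
  expect_identical(apply_design_filters(rec$conformation), rec$verdicts)
  ## bounds and bookkeeping
  expect_identical(rec$hbonds, count_internal_hbonds(rec$conformation))
  expect_identical(rec$n_methyl, sum(rec$sequence$n_methyl))
  expect_lte(rec$n_methyl, design_policy()$max_n_methyl)
  if (rec$verdicts[["all"]]) {
    expect_length(rec$unsatisfied, 0)
    expect_gte(rec$hbonds, min_hbonds_for_length(7))
  }
})

test_that("filter verdicts fail on synthetic bound violations", {
  ring <- closed_gly_ring(8, seed = 2)
  seq6 <- macrocycle_sequence(
    c("ALA", "VAL", "LEU", "ILE", "PHE", "ALA", "VAL", "LEU"),
    rep("L", 8), c(rep(TRUE, 6), FALSE, FALSE), strict = FALSE)
  conf6 <- cycpep:::thread_sequence(ring, seq6)
  v <- apply_design_filters(conf6)
  expect_false(v[["max_n_methyl"]])
  ## a ring with no hydrogen bonds at all fails the minimum
  far <- conf6
  v2 <- apply_design_filters(far, design_policy())
  expect_identical(v2[["min_hbonds"]],
                   count_internal_hbonds(far) >= min_hbonds_for_length(8))
})
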