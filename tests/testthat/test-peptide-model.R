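test_that("sequence validation enforces the residue vocabulary", {
  expect_error(macrocycle_sequence(rep("ALA", 4)), "length")
  expect_silent(macrocycle_sequence(rep("ALA", 4), strict = FALSE))
  expect_error(macrocycle_sequence(c(rep("ALA", 5), "GLY"),
                                   c(rep("L", 5), "L")), "achiral")
  expect_error(macrocycle_sequence(rep("PRO", 6), n_methyl = TRUE),
               "N-methylated")
  expect_error(macrocycle_sequence(c(rep("ALA", 5), "XYZ")), "unknown")
})

test_that("build/measure is an exact inverse pair", {
  set.seed(7)
  for (n in c(6, 9, 12)) {
    seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
    tor <- cbind(phi = runif(n, -180, 180), psi = runif(n, -180, 180),
                 omega = sample(c(0, 180), n, replace = TRUE))
    conf <- build_from_torsions(seq, tor)
    m <- measure_torsions(conf)
    expect_lt(max(abs(wrap_angle(m - tor))), 1e-6)
  }
})

test_that("trans and cis CA-CA distances match explicit trigonometry", {
  ## independent closed-form construction of the virtual CA-CA distance from
  ## the ideal internal coordinates, using plain rotation matrices
  g <- ideal_geometry()
  place <- function(omega) {
    d2r <- pi / 180
    CA1 <- c(0, 0, 0)
    C <- c(g$b_ca_c, 0, 0)
    thC <- (180 - g$a_ca_c_n) * d2r
    N <- C + g$b_c_n * c(cos(thC), sin(thC), 0)
    ## place CA2 at bond angle a_c_n_ca from the C->N direction, rotated
    ## about the C-N axis by the dihedral omega measured from CA1
    e <- (N - C) / sqrt(sum((N - C)^2))
    ## reference perpendicular in the CA1-C-N plane, pointing back towards CA1
    v <- CA1 - C
    v <- v - e * sum(v * e)
    v <- v / sqrt(sum(v * v))
    w <- c(e[2] * v[3] - e[3] * v[2], e[3] * v[1] - e[1] * v[3],
           e[1] * v[2] - e[2] * v[1])
    thN <- (180 - g$a_c_n_ca) * d2r
    dirCA2 <- cos(thN) * e +
      sin(thN) * (cos(omega * d2r) * v + sin(omega * d2r) * w)
    CA2 <- N + g$b_n_ca * dirCA2
    sqrt(sum((CA2 - CA1)^2))
  }
  d_trans <- place(180)
  d_cis <- place(0)
  expect_equal(d_trans, 3.8, tolerance = 0.01)
  expect_lt(d_cis, d_trans)

  seq <- macrocycle_sequence(rep("GLY", 6), rep("achiral", 6))
  tor <- cbind(phi = rep(-70, 6), psi = rep(60, 6), omega = rep(180, 6))
  conf <- build_from_torsions(seq, tor)
  expect_equal(sqrt(sum((conf$coords[2, "CA", ] - conf$coords[1, "CA", ])^2)),
               d_trans, tolerance = 1e-9)
  tor[1, "omega"] <- 0
  conf_cis <- build_from_torsions(seq, tor)
  expect_equal(sqrt(sum((conf_cis$coords[2, "CA", ] -
                         conf_cis$coords[1, "CA", ])^2)),
               d_cis, tolerance = 1e-9)
})

test_that("measured torsions are rigid-motion invariant and mirror-negated", {
  conf <- random_open_conf(8, seed = 3)
  m0 <- measure_torsions(conf)
  ## rigid rotation + translation
  R <- cycpep:::rodrigues_matrix(c(1, 2, 2) / 3, 77)
  moved <- conf
  for (i in 1:8) for (a in seq_along(cycpep:::.atom_slots)) {
    if (!anyNA(conf$coords[i, a, ])) {
      moved$coords[i, a, ] <- as.numeric(conf$coords[i, a, ] %*% R) + c(3, -1, 2)
    }
  }
  moved$aux <- lapply(conf$aux, function(p) as.numeric(p %*% R) + c(3, -1, 2))
  expect_lt(max(abs(wrap_angle(measure_torsions(moved) - m0))), 1e-9)
  ## mirror: reflect coordinates, recompute -> all torsions negated
  mc <- mirror_conformation(conf)
  expect_lt(max(abs(wrap_angle(measure_torsions(mc) + m0))), 1e-9)
  chiral <- conf$seq$chirality != "achiral"
  expect_identical(mc$seq$chirality[chiral],
                   ifelse(conf$seq$chirality[chiral] == "L", "D", "L"))
  expect_identical(mc$seq$chirality[!chiral], conf$seq$chirality[!chiral])
})

test_that("mirror is an involution and permute composes to identity", {
  conf <- random_open_conf(7, seed = 5)
  mm <- mirror_conformation(mirror_conformation(conf))
  expect_lt(max(abs(mm$coords - conf$coords), na.rm = TRUE), 1e-12)
  expect_identical(mm$seq$chirality, conf$seq$chirality)
  ring <- closed_gly_ring(7)
  p0 <- cyclic_permute(ring, 0)
  expect_identical(p0$coords, ring$coords)
  pk <- cyclic_permute(cyclic_permute(ring, 3), 7 - 3)
  expect_lt(max(abs(pk$coords - ring$coords), na.rm = TRUE), 1e-12)
})

test_that("mirror and permutation commute with building from torsions", {
  ring <- closed_gly_ring(8)
  tor <- ring$torsions
  ## mirrored torsions build the mirror image (after superposition)
  b_mirr <- build_from_torsions(mirror_conformation(ring)$seq,
                                wrap_angle(-tor))
  expect_lt(backbone_rmsd(b_mirr, mirror_conformation(ring)), 1e-6)
  ## permuted torsions build the permuted ring
  k <- 3
  perm <- cyclic_permute(ring, k)
  b_perm <- build_from_torsions(perm$seq, measure_torsions(perm))
  expect_lt(backbone_rmsd(b_perm, perm), 1e-4)
})

test_that("PDB round trip preserves sequence, flags and coordinates", {
  seq <- macrocycle_sequence(
    c("ALA", "PRO", "LEU", "GLY", "VAL", "PHE", "ILE", "ALA"),
    c("L", "D", "L", "achiral", "D", "L", "L", "D"),
    c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  set.seed(4)
  pp <- cycpep:::sample_flat_symm(8)
  conf <- build_from_torsions(seq, cbind(phi = pp[, 1], psi = pp[, 2],
                                         omega = rep(180, 8)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(conf, f)
  back <- read_pdb(f)
  expect_identical(back$seq$aa, seq$aa)
  expect_identical(back$seq$chirality, seq$chirality)
  expect_identical(back$seq$n_methyl, seq$n_methyl)
  expect_lt(max(abs(back$coords - conf$coords), na.rm = TRUE), 6e-4)
  ## D-proline is emitted under its chemical-component name
  txt <- readLines(f)
  expect_true(any(grepl("DPR", txt)))
  ## a residue missing CA is a named parse error
  txt2 <- txt[!(grepl("^ATOM", txt) & grepl(" CA ", txt) & grepl(" 3 ", txt))]
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt2, f2)
  expect_error(read_pdb(f2), "CA at residue 3")
})
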