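## shared test fixtures, generated once per test run

.ring_cache <- new.env(parent = emptyenv())

## a closed polyglycine ring of length n (deterministic per n/seed)
closed_gly_ring <- function(n, seed = 1) {
  key <- paste0("g", n, "s", seed)
  hit <- .ring_cache[[key]]
  if (!is.null(hit)) return(hit)
  seq <- macrocycle_sequence(rep("GLY", n), rep("achiral", n))
  set.seed(seed)
  for (k in 1:400) {
    pp <- cycpep:::sample_flat_symm(n)
    tor <- cbind(phi = pp[, 1], psi = pp[, 2], omega = rep(180, n))
    pv <- cycpep:::default_pivots(sample.int(n, 1), n)
    sol <- solve_closure(closure_problem(seq, tor, pv),
                         grid_size = 360, thorough = FALSE)
    ok <- Filter(loop_bump_check, sol$solutions)
    if (length(ok)) {
      .ring_cache[[key]] <- ok[[1]]
      return(ok[[1]])
    }
  }
  stop("could not build a closed test ring of length ", n)
}

## random open conformation with a mixed sequence
random_open_conf <- function(n, seed = 1) {
  set.seed(seed)
  aas <- c("ALA", "VAL", "LEU", "ILE", "PHE", "PRO", "GLY")
  aa <- sample(aas, n, replace = TRUE)
  chir <- ifelse(aa == "GLY", "achiral",
                 sample(c("L", "D"), n, replace = TRUE))
  nme <- aa != "PRO" & stats::runif(n) < 0.2
  seq <- macrocycle_sequence(aa, chir, nme, strict = FALSE)
  pp <- cycpep:::sample_flat_symm(n)
  build_from_torsions(seq, cbind(phi = pp[, 1], psi = pp[, 2],
                                 omega = rep(180, n)))
}

## place an ideal hydrogen bond from donor residue i to acceptor residue j by
## moving H(i), O(j) and C(j) into an exact N-H...O=C arrangement
place_ideal_hbond <- function(conf, i, j, d_ho = 1.95) {
  N <- conf$coords[i, "N", ]
  O0 <- conf$coords[j, "O", ]
  u <- (O0 - N) / sqrt(sum((O0 - N)^2))
  H <- N + 1.01 * u
  O <- H + d_ho * u
  ## carbonyl carbon at 125 deg from the O->H direction
  p <- c(u[2], -u[1], 0)
  if (sum(p * p) < 1e-8) p <- c(0, u[3], -u[2])
  p <- p / sqrt(sum(p * p))
  ang <- 125 * pi / 180
  C <- O + 1.231 * (cos(ang) * (-u) + sin(ang) * p)
  conf$coords[i, "H", ] <- H
  conf$coords[j, "O", ] <- O
  conf$coords[j, "C", ] <- C
  conf
}


## point an existing donor's H at an (already placed) acceptor carbonyl
aim_donor_at <- function(conf, i, j, d_ho = 1.95) {
  N <- conf$coords[i, "N", ]
  O <- conf$coords[j, "O", ]
  u <- (O - N) / sqrt(sum((O - N)^2))
  conf$coords[i, "H", ] <- O - d_ho * u
  conf
}

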