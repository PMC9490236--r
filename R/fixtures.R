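## Deterministic fixtures ----------------------------------------------------
##
## Closed rings with prescribed secondary-structure character, built by
## fixing most torsions near a motif and solving the closure analytically.
## Used by the test-suite and examples; no external structure files needed.

motif_torsions <- function(length, motif, seq) {
  phi <- numeric(length); psi <- numeric(length)
  if (motif == "all_trans_helix") {
    phi[] <- -63; psi[] <- -43
  } else if (motif %in% c("beta_hairpin_like", "two_state_pair")) {
    half <- floor(length / 2)
    phi[] <- -120; psi[] <- 130
    ## two turn-like positions at the hairpin ends
    phi[c(1, half + 1)] <- -63
    psi[c(1, half + 1)] <- -43
  } else stop("unknown motif: ", motif)
  cbind(phi = phi, psi = psi, omega = rep(180, length))
}

#' Build a deterministic closed fixture ring
#'
#' Perturbs a motif torsion template by small random amounts, solves the
#' closure, and keeps the lowest-energy clash-free solution.  For
#' `two_state_pair`, an N-methylated position is introduced and a second
#' conformation of the same sequence is generated with the omega of that
#' position's bond flipped to cis, giving two closed states of one sequence
#' that differ by a single trans-to-cis peptide-bond flip.
#'
#' @param length ring size in residues (6-12).
#' @param motif `"all_trans_helix"`, `"beta_hairpin_like"` or
#'   `"two_state_pair"`.
#' @param seed integer seed.
#' @param seq optional [macrocycle_sequence()] (default polyglycine, with an
#'   N-methyl-alanine at position 2 for `two_state_pair`).
#' @param max_tries perturbation retries before giving up.
#' @return A `cycpep_conformation`, or a list of two for `two_state_pair`.
#' @export
make_fixture_ring <- function(length, motif = "all_trans_helix", seed = 1,
                              seq = NULL, max_tries = 200) {
  stopifnot(length >= 6, length <= 12)
  set.seed(seed)
  if (is.null(seq)) {
    aa <- rep("GLY", length)
    chir <- rep("achiral", length)
    nme <- rep(FALSE, length)
    if (motif == "two_state_pair") {
      aa[2] <- "ALA"; chir[2] <- "L"; nme[2] <- TRUE
    }
    seq <- macrocycle_sequence(aa, chir, nme)
  }
  base <- motif_torsions(length, motif, seq)
  solve_one <- function(tor) {
    for (try in seq_len(max_tries)) {
      jit <- tor
      jit[, 1:2] <- jit[, 1:2] + stats::runif(2 * length, -25, 25)
      pv <- default_pivots(sample.int(length, 1), length)
      sol <- solve_closure(closure_problem(seq, wrap_angle(jit), pv),
                           grid_size = 360, thorough = FALSE)
      best <- NULL; best_e <- Inf
      for (cf in sol$solutions) {
        if (!loop_bump_check(cf)) next
        e <- score_conformation(cf, "closure_selection")$total
        if (e < best_e) { best <- cf; best_e <- e }
      }
      if (!is.null(best)) return(best)
    }
    stop("fixture closure failed after ", max_tries, " tries")
  }
  first <- solve_one(base)
  if (motif != "two_state_pair") return(first)
  ## second state: flip the peptide bond before the N-methylated position
  ## (omega of bond i-1 -> i, i.e. omega index i-1) to cis
  i <- which(seq$n_methyl)[1]
  tor2 <- first$torsions
  tor2[cyc_prev(i, length), "omega"] <- 0
  second <- solve_one(tor2)
  list(first, second)
}
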