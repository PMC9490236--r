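## Surrogate scoring function ----------------------------------------------
##
## Term names and roles mirror the score terms used for macrocycle design
## (fa_rep / fa_atr / hbond_sr_bb / hbond_lr_bb / rama_prepro / p_aa_pp /
## omega / chainbreak / aa_composition), but the functional forms are a
## self-contained surrogate in arbitrary score units, documented here and in
## the methods vignette.  Side chains beyond CB are collapsed to a single
## CB-centred sphere whose radius reflects residue bulk.

.energy_terms <- c("fa_rep", "fa_atr", "hbond_sr_bb", "hbond_lr_bb",
                   "rama_prepro", "p_aa_pp", "omega", "chainbreak",
                   "aa_composition")

## Lennard-Jones-like parameters
.lj_eps <- 0.2
.lj_cut <- 6.0
.atom_radius <- c(N = 1.55, CA = 1.80, C = 1.80, O = 1.45, CN = 1.80)
.cb_radius <- c(ALA = 1.80, AIB = 1.90, PRO = 1.90, VAL = 2.10,
                ILE = 2.20, LEU = 2.20, PHE = 2.40)

## omega and chainbreak spring constants (per squared degree / Angstrom)
.k_omega <- 0.003
.k_break_len <- 300
.k_break_ang <- 0.02

#' Built-in weight sets
#'
#' `standard` carries beta-style weights for all terms; `closure_selection`
#' is the reduced set used to pick among kinematic-closure solutions
#' (fa_rep 0.1, fa_atr 0.2, hbond_sr_bb 2.0, hbond_lr_bb 2.0,
#' rama_prepro 0.45, omega 0.4, p_aa_pp 0.6); `hbond_upweighted` is
#' `standard` with both backbone hydrogen-bond terms raised to 5.0 (5x),
#' used in the first design round.
#'
#' @param name one of `"standard"`, `"closure_selection"`,
#'   `"hbond_upweighted"`, or a named numeric vector of weights.
#' @return Named numeric vector of non-negative term weights.
#' @export
weight_set <- function(name = "standard") {
  if (is.numeric(name)) {
    w <- name
    stopifnot(!is.null(names(w)), all(names(w) %in% .energy_terms))
    full <- stats::setNames(numeric(length(.energy_terms)), .energy_terms)
    full[names(w)] <- w
    if (any(full < 0)) stop("weights must be non-negative")
    return(full)
  }
  std <- c(fa_rep = 0.55, fa_atr = 1.0, hbond_sr_bb = 1.0, hbond_lr_bb = 1.0,
           rama_prepro = 0.45, p_aa_pp = 0.61, omega = 0.48,
           chainbreak = 1.0, aa_composition = 1.0)
  w <- switch(name,
    standard = std,
    closure_selection = c(fa_rep = 0.1, fa_atr = 0.2, hbond_sr_bb = 2.0,
                          hbond_lr_bb = 2.0, rama_prepro = 0.45,
                          omega = 0.4, p_aa_pp = 0.6, chainbreak = 0,
                          aa_composition = 0),
    hbond_upweighted = {
      s <- std; s["hbond_sr_bb"] <- 5.0; s["hbond_lr_bb"] <- 5.0; s
    },
    stop("unknown weight set: ", name))
  weight_set(w)
}

## Pairwise Lennard-Jones split into repulsive / attractive parts.
## r, sigma vectors; returns list(rep, atr).
lj_split <- function(r, sigma) {
  rep <- numeric(length(r))
  atr <- numeric(length(r))
  inside <- r < sigma
  sr6 <- (sigma / pmax(r, 0.1))^6
  lj <- .lj_eps * (sr6^2 - 2 * sr6)
  rep[inside] <- lj[inside] + .lj_eps
  atr[inside] <- -.lj_eps
  mid <- !inside & r < .lj_cut
  atr[mid] <- lj[mid]
  list(rep = rep, atr = atr)
}

## Hydrogen-bond functional form -------------------------------------------

#' Backbone hydrogen-bond energy from geometry
#'
#' Product of a distance Gaussian centred at the ideal H...O separation and
#' clipped-cosine angular terms for N-H...O linearity (ideal 180 deg) and the
#' H...O=C approach angle (ideal 125 deg), scaled to reach about -1 score
#' units at ideal geometry so the -0.25 reporting cutoff is meaningful.
#'
#' @param d_ho H...O distance (Angstrom).
#' @param ang_nho N-H...O angle (degrees).
#' @param ang_hoc H...O=C angle (degrees).
#' @return Energy in score units (<= 0).
#' @export
hbond_energy <- function(d_ho, ang_nho, ang_hoc) {
  fd <- exp(-(d_ho - 2.0)^2 / (2 * 0.45^2))
  t1 <- pmax(0, cos((180 - ang_nho) * .deg2rad))
  t2 <- pmax(0, cos((ang_hoc - 125) * .deg2rad))
  -1.0 * fd * t1 * t2
}

#' Detect backbone-backbone hydrogen bonds
#'
#' Scans all amide NH donors (residues that are neither proline nor
#' N-methylated) against all carbonyl O acceptors, excluding donor-acceptor
#' pairs within cyclic sequence separation 2, and reports pairs whose
#' geometric energy is at or below `energy_cutoff`.
#'
#' @param conf a `cycpep_conformation` with amide H atoms placed.
#' @param energy_cutoff reporting cutoff in score units.
#' @return Data frame with columns `donor`, `acceptor`, `energy`,
#'   `separation` (cyclic), one row per bond.
#' @export
detect_backbone_hbonds <- function(conf, energy_cutoff = -0.25) {
  hb_eval(score_context(conf$seq), conf$coords, energy_cutoff)
}

#' Count unique internal backbone hydrogen bonds
#'
#' @inheritParams detect_backbone_hbonds
#' @return Integer count (each bond counted once).
#' @export
count_internal_hbonds <- function(conf, energy_cutoff = -0.25) {
  nrow(detect_backbone_hbonds(conf, energy_cutoff))
}

#' Residues with unsatisfied backbone NH donors
#'
#' Returns the indices of residues that carry a backbone amide NH (i.e. are
#' neither proline nor N-methylated) but donate no reported backbone
#' hydrogen bond.
#'
#' @inheritParams detect_backbone_hbonds
#' @return Integer vector of residue indices (possibly empty).
#' @export
find_unsatisfied_nh <- function(conf, energy_cutoff = -0.25) {
  hb <- detect_backbone_hbonds(conf, energy_cutoff)
  donors <- which(has_nh(conf$seq))
  sort(setdiff(donors, unique(hb$donor)))
}

#' Check for oversaturated hydrogen-bond acceptors
#'
#' A carbonyl oxygen can accept at most `per_acceptor_max` hydrogen bonds
#' (default 2, one per sp2 lone pair).  The check fails when more than
#' `max_allowed` acceptors exceed that maximum.
#'
#' @inheritParams detect_backbone_hbonds
#' @param max_allowed number of oversaturated acceptors tolerated.
#' @param per_acceptor_max maximum H-bonds per carbonyl oxygen.
#' @return List with `pass` (logical) and `offenders` (residue indices whose
#'   carbonyl is oversaturated).
#' @export
check_oversaturated_acceptors <- function(conf, max_allowed = 0,
                                          per_acceptor_max = 2,
                                          energy_cutoff = -0.25) {
  hb <- detect_backbone_hbonds(conf, energy_cutoff)
  cnt <- table(hb$acceptor)
  off <- as.integer(names(cnt)[cnt > per_acceptor_max])
  list(pass = length(off) <= max_allowed, offenders = off)
}

## Score ---------------------------------------------------------------------

## Per-sequence scoring context: atom bookkeeping, nonbonded pair lists and
## hydrogen-bond candidate pairs, cached on the sequence signature so that
## repeated scoring (minimisation, annealing) costs only vector arithmetic.
.score_ctx_cache <- new.env(parent = emptyenv())

score_context <- function(seq) {
  key <- paste(seq$aa, seq$chirality, seq$n_methyl, collapse = "|")
  hit <- .score_ctx_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(seq)
  pres <- atom_presence(seq)
  ids <- which(t(pres))
  slot <- rep(seq_along(.atom_slots), n)[ids]
  res <- rep(seq_len(n), each = length(.atom_slots))[ids]
  bs <- bond_separation(seq)
  heavy <- .atom_slots[slot] != "H"
  hres <- res[heavy]; hslot <- slot[heavy]
  rad <- ifelse(.atom_slots[hslot] == "CB", .cb_radius[seq$aa[hres]],
                .atom_radius[.atom_slots[hslot]])
  m <- sum(heavy)
  sep <- bs$sep[heavy, heavy, drop = FALSE]
  pair <- which(upper.tri(sep) & sep >= 4, arr.ind = TRUE)
  sigma <- rad[pair[, 1]] + rad[pair[, 2]]
  ## bump-check pairs: backbone heavy atoms, separation > 2 bonds
  bbmask <- .atom_slots[hslot] %in% c("N", "CA", "C", "O", "CN")
  bsep <- sep[bbmask, bbmask, drop = FALSE]
  bpair <- which(upper.tri(bsep) & bsep > 2, arr.ind = TRUE)
  ## hydrogen-bond candidates
  donors <- which(has_nh(seq))
  hb <- NULL
  for (i in donors) for (j in seq_len(n)) {
    if (cyclic_separation(i, j, n) > 2) hb <- rbind(hb, c(i, j))
  }
  nxt <- cyc_next(seq_len(n), n)
  ctx <- list(n = n, pres = pres,
              hres = hres, hslot = hslot,
              bb_rows = which(bbmask),
              pair = pair, sigma = as.numeric(sigma), bpair = bpair,
              hb = hb,
              hb_sep = if (is.null(hb)) integer() else
                cyclic_separation(hb[, 1], hb[, 2], n),
              prepro = seq$aa[nxt] == "PRO" | seq$n_methyl[nxt],
              aa = seq$aa, chirality = seq$chirality)
  .score_ctx_cache[[key]] <- ctx
  ctx
}

## heavy-atom coordinate matrix in context row order
ctx_heavy_xyz <- function(ctx, co) {
  cbind(co[cbind(ctx$hres, ctx$hslot, 1L)],
        co[cbind(ctx$hres, ctx$hslot, 2L)],
        co[cbind(ctx$hres, ctx$hslot, 3L)])
}

## vectorised angle between point triples (degrees), rows of matrices
rows_angle <- function(P1, P2, P3) {
  u <- P1 - P2
  v <- P3 - P2
  cu <- sqrt(rowSums(u * u))
  cv <- sqrt(rowSums(v * v))
  cosang <- pmax(-1, pmin(1, rowSums(u * v) / (cu * cv)))
  acos(cosang) / .deg2rad
}

## hydrogen bonds over candidate pairs (vectorised); returns data frame
hb_eval <- function(ctx, co, energy_cutoff) {
  if (is.null(ctx$hb)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric(), separation = integer()))
  }
  di <- ctx$hb[, 1]; aj <- ctx$hb[, 2]
  sH <- match("H", .atom_slots); sN <- match("N", .atom_slots)
  sO <- match("O", .atom_slots); sC <- match("C", .atom_slots)
  H <- cbind(co[cbind(di, sH, 1L)], co[cbind(di, sH, 2L)], co[cbind(di, sH, 3L)])
  N <- cbind(co[cbind(di, sN, 1L)], co[cbind(di, sN, 2L)], co[cbind(di, sN, 3L)])
  O <- cbind(co[cbind(aj, sO, 1L)], co[cbind(aj, sO, 2L)], co[cbind(aj, sO, 3L)])
  C <- cbind(co[cbind(aj, sC, 1L)], co[cbind(aj, sC, 2L)], co[cbind(aj, sC, 3L)])
  if (anyNA(H)) {
    bad <- unique(di[is.na(H[, 1])])
    stop("amide H missing for donor residue ", paste(bad, collapse = ", "))
  }
  d <- sqrt(rowSums((H - O)^2))
  near <- which(d <= 3.5)
  if (!length(near)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric(), separation = integer()))
  }
  e <- hbond_energy(d[near],
                    rows_angle(N[near, , drop = FALSE],
                               H[near, , drop = FALSE],
                               O[near, , drop = FALSE]),
                    rows_angle(H[near, , drop = FALSE],
                               O[near, , drop = FALSE],
                               C[near, , drop = FALSE]))
  keep <- e <= energy_cutoff
  data.frame(donor = di[near][keep], acceptor = aj[near][keep],
             energy = e[keep], separation = ctx$hb_sep[near][keep])
}

#' Score a conformation with the surrogate energy function
#'
#' Computes every term of the surrogate score: a Lennard-Jones-like
#' repulsive/attractive split over backbone heavy atoms plus one CB-centred
#' side-chain sphere per residue (pairs within 3 covalent bonds excluded);
#' backbone hydrogen-bond energies split into short-range (cyclic separation
#' <= 4) and long-range parts; surrogate rama_prepro and p_aa_pp torsional
#' terms (D = mirrored L); a harmonic omega penalty to the nearest of 0/180;
#' a chainbreak term summing harmonic deviations of every peptide bond from
#' ideal bond geometry (for chains built from torsions only the closure gap
#' contributes); and the amino-acid composition penalty when constraints are
#' supplied.  Every term is invariant under mirroring and cyclic relabelling.
#'
#' @param conf a `cycpep_conformation`.
#' @param weights a weight-set name or named vector, see [weight_set()].
#' @param constraints optional list of composition constraints, see
#'   [composition_constraint()].
#' @param hbond_cutoff reporting cutoff for hydrogen-bond detection.
#' @return An `energy_breakdown`: named list of term values plus `total`.
#' @export
score_conformation <- function(conf, weights = "standard", constraints = NULL,
                               hbond_cutoff = -0.25) {
  w <- weight_set(weights)
  seq <- conf$seq
  n <- nrow(seq)
  terms <- stats::setNames(numeric(length(.energy_terms)), .energy_terms)
  ctx <- score_context(seq)
  co <- conf$coords

  ## nonbonded LJ over heavy atoms with bond separation >= 4
  xyz <- ctx_heavy_xyz(ctx, co)
  if (nrow(ctx$pair)) {
    dx <- xyz[ctx$pair[, 1], , drop = FALSE] - xyz[ctx$pair[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dx * dx))
    lj <- lj_split(r, ctx$sigma)
    terms["fa_rep"] <- sum(lj$rep)
    terms["fa_atr"] <- sum(lj$atr)
  }

  ## hydrogen bonds
  hb <- hb_eval(ctx, co, hbond_cutoff)
  if (nrow(hb)) {
    sr <- hb$separation <= 4
    terms["hbond_sr_bb"] <- sum(hb$energy[sr])
    terms["hbond_lr_bb"] <- sum(hb$energy[!sr])
  }

  ## torsional terms, measured from the actual cyclic atoms so that every
  ## term is independent of where the formal cut sits
  tor <- measure_torsions(conf, use_aux = FALSE)
  nxt <- cyc_next(seq_len(n), n)
  prepro <- seq$aa[nxt] == "PRO" | seq$n_methyl[nxt]
  terms["rama_prepro"] <- sum(vapply(seq_len(n), function(i) {
    rama_prepro_energy(tor[i, "phi"], tor[i, "psi"], seq$aa[i],
                       seq$chirality[i], prepro[i])
  }, numeric(1)))
  terms["p_aa_pp"] <- sum(vapply(seq_len(n), function(i) {
    p_aa_pp_energy(tor[i, "phi"], tor[i, "psi"], seq$aa[i], seq$chirality[i])
  }, numeric(1)))

  ## omega: harmonic to the nearest of 0 / 180
  dev <- pmin(ang_dist(tor[, "omega"], 180), ang_dist(tor[, "omega"], 0))
  terms["omega"] <- .k_omega * sum(dev^2)

  ## chainbreak: harmonic deviation of every peptide bond from ideal geometry
  terms["chainbreak"] <- chainbreak_energy(conf)

  if (!is.null(constraints)) {
    terms["aa_composition"] <- composition_penalty(seq, constraints)
  }

  total <- sum(w[.energy_terms] * terms)
  structure(c(as.list(terms), list(total = total, weights = w)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (t in .energy_terms) cat(sprintf("  %-14s %10.4f\n", t, x[[t]]))
  cat(sprintf("  %-14s %10.4f\n", "total", x$total))
  invisible(x)
}

## Sum over all n peptide bonds of harmonic deviations from ideal geometry.
## Invariant under cyclic relabelling because every bond is visited.
chainbreak_energy <- function(conf) {
  co <- conf$coords
  n <- dim(co)[1]
  g <- .ideal
  j <- cyc_next(seq_len(n), n)
  sN <- match("N", .atom_slots); sCA <- match("CA", .atom_slots)
  sC <- match("C", .atom_slots)
  Ci <- cbind(co[cbind(1:n, sC, 1L)], co[cbind(1:n, sC, 2L)], co[cbind(1:n, sC, 3L)])
  CAi <- cbind(co[cbind(1:n, sCA, 1L)], co[cbind(1:n, sCA, 2L)], co[cbind(1:n, sCA, 3L)])
  Nj <- cbind(co[cbind(j, sN, 1L)], co[cbind(j, sN, 2L)], co[cbind(j, sN, 3L)])
  CAj <- cbind(co[cbind(j, sCA, 1L)], co[cbind(j, sCA, 2L)], co[cbind(j, sCA, 3L)])
  d <- sqrt(rowSums((Nj - Ci)^2))
  ## cap the distance deviation so open chains get a large, finite penalty
  e <- .k_break_len * sum(pmin((d - g$b_c_n)^2, 100))
  near <- which(d < 3)  # angles only meaningful when the bond roughly forms
  if (length(near)) {
    a1 <- rows_angle(CAi[near, , drop = FALSE], Ci[near, , drop = FALSE],
                     Nj[near, , drop = FALSE])
    a2 <- rows_angle(Ci[near, , drop = FALSE], Nj[near, , drop = FALSE],
                     CAj[near, , drop = FALSE])
    e <- e + .k_break_ang * sum(ang_dist(a1, g$a_ca_c_n)^2 +
                                ang_dist(a2, g$a_c_n_ca)^2)
  }
  e
}

#' Backbone bump check
#'
#' True iff no pair of non-bonded backbone heavy atoms (N, CA, C, O, CN;
#' separated by more than 2 covalent bonds) is closer than `clash_distance`.
#'
#' @param conf a `cycpep_conformation`.
#' @param clash_distance Angstrom; default 2.6.
#' @return Logical.
#' @export
loop_bump_check <- function(conf, clash_distance = 2.6) {
  ctx <- score_context(conf$seq)
  xyz <- ctx_heavy_xyz(ctx, conf$coords)[ctx$bb_rows, , drop = FALSE]
  if (!nrow(ctx$bpair)) return(TRUE)
  dx <- xyz[ctx$bpair[, 1], , drop = FALSE] - xyz[ctx$bpair[, 2], , drop = FALSE]
  all(rowSums(dx * dx) >= clash_distance^2)
}

#' Write energy breakdowns to TSV
#'
#' @param breakdowns a list of `energy_breakdown` objects (or a single one).
#' @param path output file.
#' @param ids optional identifiers, one per breakdown.
#' @return The path, invisibly.
#' @export
write_energy_tsv <- function(breakdowns, path, ids = NULL) {
  if (inherits(breakdowns, "energy_breakdown")) breakdowns <- list(breakdowns)
  if (is.null(ids)) ids <- seq_along(breakdowns)
  rows <- lapply(seq_along(breakdowns), function(k) {
    b <- breakdowns[[k]]
    data.frame(id = ids[k], as.list(unlist(b[.energy_terms])),
               total = b$total)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
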