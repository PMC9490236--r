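## Surrogate torsional potentials ------------------------------------------
##
## rama_prepro is a flat-bottom potential over rectangular favourable
## regions of the Ramachandran map; p_aa_pp is a mild Gaussian-well
## identity preference.  Neither is a molecular-mechanics force field:
## they reproduce the roles of the corresponding score terms (favouring
## canonical backbone regions, mirroring for D-amino acids, distinct
## pre-proline/pre-N-methyl variants) in arbitrary score units.  D tables
## are exact mirrors of L tables; the glycine/AIB tables are symmetrised,
## so every term is exactly invariant under mirroring.

## Flat-bottom region tables: zero pseudo-energy inside the favourable
## boxes (rows: phi_lo, phi_hi, psi_lo, psi_hi, for the L hand), growing
## quadratically with the angular distance outside them
## (.rama_k per squared degree).  The generic boxes are the same regions the
## backbone sampler draws from, so the sampling distribution is exactly the
## flat bottom of the scoring potential.
.rama_boxes <- list(
  generic = rbind(
    alpha = c(-140, -40, -70, 30),
    beta  = c(-180, -50, 100, 180),
    beta_wrap = c(-180, -50, -180, -170)
  ),
  pro = rbind(
    c(-100, -40, -70, 10),
    c(-100, -40, 110, 180)
  ),
  prepro = rbind(                 # residues preceding PRO or an N-methyl
    alpha = c(-140, -40, -30, 30),
    beta  = c(-180, -50, 100, 180),
    beta_wrap = c(-180, -50, -180, -170)
  ),
  pro_prepro = rbind(
    c(-100, -40, -30, 10),
    c(-100, -40, 110, 180)
  )
)
.rama_k <- 0.002

## squared angular distance (wrap-aware) from (phi, psi) to the nearest box
box_dist2 <- function(boxes, phi, psi) {
  if (phi > 180 || phi <= -180) phi <- wrap_angle(phi)
  if (psi > 180 || psi <= -180) psi <- wrap_angle(psi)
  best <- Inf
  for (k in seq_len(nrow(boxes))) {
    lo <- boxes[k, 1]; hi <- boxes[k, 2]
    if (phi >= lo && phi <= hi) dp <- 0 else {
      d1 <- abs(phi - lo); if (d1 > 180) d1 <- 360 - d1
      d2 <- abs(phi - hi); if (d2 > 180) d2 <- 360 - d2
      dp <- if (d1 < d2) d1 else d2
    }
    lo <- boxes[k, 3]; hi <- boxes[k, 4]
    if (psi >= lo && psi <= hi) ds <- 0 else {
      d1 <- abs(psi - lo); if (d1 > 180) d1 <- 360 - d1
      d2 <- abs(psi - hi); if (d2 > 180) d2 <- 360 - d2
      ds <- if (d1 < d2) d1 else d2
    }
    dd <- dp * dp + ds * ds
    if (dd < best) best <- dd
  }
  best
}

rama_flat_energy <- function(boxes, phi, psi) {
  .rama_k * box_dist2(boxes, phi, psi)
}

## residue class for torsional potentials
rama_class <- function(aa, chirality) {
  if (aa %in% .achiral_aa) "sym"
  else if (aa == "PRO") if (chirality == "D") "proD" else "proL"
  else if (chirality == "D") "D" else "L"
}

#' Surrogate Ramachandran pseudo-energy (rama_prepro role)
#'
#' Pseudo-energy of a (phi, psi) pair for a residue class.  D-amino acids use
#' the exact mirror of the L table; glycine and AIB use a symmetrised table.
#' When the following residue (cyclically) is proline or N-methylated, the
#' pre-proline table variant applies.
#'
#' @param phi,psi torsions in degrees.
#' @param aa 3-letter identity.
#' @param chirality `"L"`, `"D"` or `"achiral"`.
#' @param prepro does the residue precede a proline or N-methylated position?
#' @return Pseudo-energy in score units (0 inside the favourable region,
#'   growing quadratically with distance outside it; the mirrored canonical
#'   helical point scores about 20 for an L residue).
#' @export
rama_prepro_energy <- function(phi, psi, aa, chirality, prepro = FALSE) {
  cls <- rama_class(aa, chirality)
  bx <- if (cls %in% c("proL", "proD")) {
    if (prepro) .rama_boxes$pro_prepro else .rama_boxes$pro
  } else if (prepro) .rama_boxes$prepro else .rama_boxes$generic
  switch(cls,
    L = , proL = rama_flat_energy(bx, phi, psi),
    D = , proD = rama_flat_energy(bx, -phi, -psi),
    sym = min(rama_flat_energy(bx, phi, psi),
              rama_flat_energy(bx, -phi, -psi)))
}

#' Ramachandran filter used during kinematic closure
#'
#' True iff the surrogate Ramachandran pseudo-energy of the residue is at or
#' below `cutoff` (the pre-proline variant is applied when the cyclically
#' following residue is proline or N-methylated).
#'
#' @param conf a `cycpep_conformation`.
#' @param residue 1-based residue index.
#' @param cutoff pseudo-energy cutoff (score units).
#' @return Logical.
#' @export
rama_prepro_check <- function(conf, residue, cutoff = 2) {
  n <- nrow(conf$seq)
  tor <- conf$torsions
  i <- residue
  nx <- cyc_next(i, n)
  prepro <- conf$seq$aa[nx] == "PRO" || conf$seq$n_methyl[nx]
  e <- rama_prepro_energy(tor[i, "phi"], tor[i, "psi"], conf$seq$aa[i],
                          conf$seq$chirality[i], prepro)
  e <= cutoff
}

## p_aa_pp surrogate: mild identity-dependent preference for helical vs
## strand regions.  alpha_pref in [0, 1]: 1 = helix-lover, 0 = strand-lover.
.paapp_pref <- c(ALA = 0.7, LEU = 0.6, PHE = 0.5, ILE = 0.3, VAL = 0.3,
                 PRO = 0.5, GLY = 0.5, AIB = 0.8)
.paapp_scale <- 0.4

p_aa_pp_energy <- function(phi, psi, aa, chirality) {
  if (chirality == "D") { phi <- -phi; psi <- -psi }
  fa <- exp(-0.5 * (ang_dist(phi, -63)^2 + ang_dist(psi, -43)^2) / 30^2)
  fb <- exp(-0.5 * (ang_dist(phi, -120)^2 + ang_dist(psi, 130)^2) / 40^2)
  pref <- .paapp_pref[[aa]]
  if (chirality == "achiral") {
    fa2 <- exp(-0.5 * (ang_dist(phi, 63)^2 + ang_dist(psi, 43)^2) / 30^2)
    fb2 <- exp(-0.5 * (ang_dist(phi, 120)^2 + ang_dist(psi, -130)^2) / 40^2)
    fa <- (fa + fa2) / 2
    fb <- (fb + fb2) / 2
  }
  -.paapp_scale * log(pref * fa + (1 - pref) * fb + 0.2)
}

## Flat-bottom mirror-symmetric Ramachandran sampling table -----------------
##
## A uniform distribution over the favourable L-region boxes (the flat
## bottom of the scoring potential above), unioned with their exact D
## mirrors.  Rows: phi_lo, phi_hi, psi_lo, psi_hi.
.flat_symm_regions_L <- .rama_boxes$generic

flat_symm_regions <- function() {
  L <- .flat_symm_regions_L
  D <- L[, c(2, 1, 4, 3)] * -1   # mirror: negate and swap bounds
  colnames(D) <- colnames(L)
  rownames(D) <- paste0(rownames(L), "_D")
  rbind(L, D)
}

## Draw k (phi, psi) pairs uniformly from the flat-bottom symmetric table
## (the same regions that form the zero-energy bottom of the scoring
## potential, so sampling is biased by the scoring potential as intended).
sample_flat_symm <- function(k) {
  reg <- flat_symm_regions()
  area <- (reg[, 2] - reg[, 1]) * (reg[, 4] - reg[, 3])
  ri <- sample.int(nrow(reg), k, replace = TRUE, prob = area / sum(area))
  phi <- stats::runif(k, reg[ri, 1], reg[ri, 2])
  psi <- stats::runif(k, reg[ri, 3], reg[ri, 4])
  cbind(phi = phi, psi = psi)
}

## Proline-compatible torsion bin ------------------------------------------
##
## Rectangular polygons in (phi, psi) within which an L-proline (or, after
## mirroring, a D-proline) backbone is considered compatible.  Configurable;
## the default covers the alpha and polyproline psi branches at phi ~ -65.
.pro_bin_L <- rbind(
  c(-100, -40, -70, 10),
  c(-100, -40, 110, 180)
)

#' Is a (phi, psi) pair proline-compatible?
#'
#' Tests membership of the proline-compatible torsion bin.  Negative-phi
#' points are tested against the L-proline polygon, positive-phi points
#' against its mirror (D-proline).  phi = 0 is treated as negative.
#'
#' @param phi,psi torsions in degrees.
#' @param polygons optional replacement polygon table (rows:
#'   phi_lo, phi_hi, psi_lo, psi_hi, for the L hand).
#' @return List with `compatible` (logical) and `hand` (`"L"` or `"D"`).
#' @export
proline_bin <- function(phi, psi, polygons = NULL) {
  poly <- if (is.null(polygons)) .pro_bin_L else polygons
  hand <- if (phi > 0) "D" else "L"
  if (hand == "D") { phi <- -phi; psi <- -psi }
  inside <- any(phi >= poly[, 1] & phi <= poly[, 2] &
                psi >= poly[, 3] & psi <= poly[, 4])
  list(compatible = inside, hand = hand)
}
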