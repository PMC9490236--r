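## Torsion-bin strings -------------------------------------------------------
##
## Six bins: A (right-handed helical, phi < 0), B (right-handed strand,
## phi < 0), X and Y (their exact mirrors at phi > 0), and O / Z for
## residues followed by a cis peptide bond (phi < 0 -> O, phi > 0 -> Z).
## A macrocycle maps to a cyclic string over {A,B,O,X,Y,Z}; structural
## cluster identity is the lexicographic minimum over all rotations of the
## string and of its mirror image (strings are never reversed: a physical
## mirror does not change chain direction).

#' Torsion-bin boundary definitions
#'
#' @param a_psi_lo,a_psi_hi half-open psi interval `(lo, hi]` defining bin A
#'   within the trans, phi < 0 region (B is its complement there); X/Y are
#'   exact mirrors.
#' @param cis_abs_omega |omega| below which a peptide bond counts as cis.
#' @return A `bin_boundaries` list, including the `mirror_map`.
#' @export
bin_boundaries <- function(a_psi_lo = -80, a_psi_hi = 50,
                           cis_abs_omega = 90) {
  structure(list(a_psi_lo = a_psi_lo, a_psi_hi = a_psi_hi,
                 cis_abs_omega = cis_abs_omega,
                 mirror_map = c(A = "X", B = "Y", O = "Z",
                                X = "A", Y = "B", Z = "O")),
            class = "bin_boundaries")
}

#' Assign the torsion bin of one residue
#'
#' The cis assignment (from the omega of the bond to the next residue)
#' overrides the phi/psi classification: phi < 0 gives O, phi > 0 gives Z.
#' In the trans case, phi < 0 residues are A when psi lies in the A
#' interval, otherwise B; phi > 0 residues mirror that rule (X / Y).
#' phi = 0 is treated as negative.
#'
#' @param phi,psi residue torsions (degrees).
#' @param omega_next omega of the peptide bond to the following residue.
#' @param bounds a [bin_boundaries()].
#' @return Single bin character.
#' @export
assign_bin <- function(phi, psi, omega_next, bounds = bin_boundaries()) {
  stopifnot(is.finite(phi), is.finite(psi), is.finite(omega_next))
  cis <- abs(wrap_angle(omega_next)) < bounds$cis_abs_omega
  neg <- phi <= 0
  if (cis) return(if (neg) "O" else "Z")
  in_a <- function(p) p > bounds$a_psi_lo && p <= bounds$a_psi_hi
  if (neg) {
    if (in_a(psi)) "A" else "B"
  } else {
    if (in_a(-psi)) "X" else "Y"
  }
}

#' Torsion-bin string of a conformation
#'
#' @param conf a `cycpep_conformation`.
#' @param bounds a [bin_boundaries()].
#' @return Character string, one bin letter per residue in cycle order.
#' @export
binstring <- function(conf, bounds = bin_boundaries()) {
  tor <- conf$torsions
  if (is.null(tor)) tor <- measure_torsions(conf)
  paste(vapply(seq_len(nrow(tor)), function(i) {
    assign_bin(tor[i, "phi"], tor[i, "psi"], tor[i, "omega"], bounds)
  }, character(1)), collapse = "")
}

## string helpers
rotate_string <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  k <- ((k %% n) + n) %% n
  paste(ch[((seq_len(n) - 1 + k) %% n) + 1], collapse = "")
}

mirror_string <- function(s, bounds = bin_boundaries()) {
  ch <- strsplit(s, "")[[1]]
  paste(bounds$mirror_map[ch], collapse = "")
}

#' Canonical form of a cyclic bin string
#'
#' The lexicographic minimum (A < B < O < X < Y < Z) over all n rotations of
#' the string and all n rotations of its mirror-mapped image.  Idempotent
#' and invariant under the full rotation/mirror symmetry group.
#'
#' @param s a bin string.
#' @param bounds a [bin_boundaries()] (supplies the mirror map).
#' @return The canonical representative.
#' @export
canonical_form <- function(s, bounds = bin_boundaries()) {
  ch <- strsplit(s, "")[[1]]
  if (!all(ch %in% names(bounds$mirror_map))) {
    stop("bin string may contain only A, B, O, X, Y, Z")
  }
  n <- nchar(s)
  variants <- character(0)
  for (base in c(s, mirror_string(s, bounds))) {
    for (k in 0:(n - 1)) variants <- c(variants, rotate_string(base, k))
  }
  min(variants)
}

#' Group design records by canonical bin string
#'
#' Designs whose bin strings transform into each other under circular
#' permutation or mirror inversion fall into one nondegenerate cluster.
#' Records of different lengths are grouped separately by construction
#' (their strings differ in length).
#'
#' @param records list of `design_record`s or `cycpep_conformation`s.
#' @param bounds a [bin_boundaries()].
#' @return Named list of integer index vectors, keyed by canonical form.
#' @export
cluster_designs_by_binstring <- function(records, bounds = bin_boundaries()) {
  keys <- vapply(records, function(r) {
    conf <- if (inherits(r, "design_record")) r$conformation else r
    canonical_form(binstring(conf, bounds), bounds)
  }, character(1))
  split(seq_along(records), keys)
}
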