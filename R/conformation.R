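## Conformation data model --------------------------------------------------
##
## Coordinates are stored as an n x 7 x 3 array; the 7 atom slots are
## N, CA, C, O, CB, H, CN.  Slots that do not exist for a residue (CB for
## glycine, H for proline/N-methylated residues, CN for everything without an
## N-methyl) hold NA.  Torsions are an n x 3 matrix (phi, psi, omega) in
## degrees, in (-180, 180]; omega(i) is the peptide bond between residues i
## and i+1, cyclically.
##
## Conformations built from torsions additionally carry `aux` anchor atoms:
## the virtual pre-N(1) carbonyl carbon `C0` (which defines phi(1) before the
## ring is closed) and the ideal-geometry images `N_img`/`CA_img` of N(1) and
## CA(1) continued past C(n) (which define psi(n) and omega(n)).  For a closed
## ring these coincide with the real atoms to within the closure residual.

.atom_slots <- c("N", "CA", "C", "O", "CB", "H", "CN")

new_conformation <- function(seq, torsions, coords, aux = NULL) {
  structure(list(seq = seq, torsions = torsions, coords = coords, aux = aux),
            class = "cycpep_conformation")
}

#' @export
print.cycpep_conformation <- function(x, ...) {
  cat("macrocycle conformation: ", sequence_string(x$seq), "\n", sep = "")
  res <- closure_geometry(x)
  cat(sprintf("  closure bond %.4f A (ideal %.6f), gap residual %.2e A\n",
              res$bondlength, .ideal$closure$bondlength,
              abs(res$bondlength - .ideal$closure$bondlength)))
  invisible(x)
}

## which atom slots exist for each residue of a sequence
atom_presence <- function(seq) {
  n <- nrow(seq)
  pres <- matrix(FALSE, n, length(.atom_slots),
                 dimnames = list(NULL, .atom_slots))
  pres[, c("N", "CA", "C", "O")] <- TRUE
  pres[, "CB"] <- seq$aa != "GLY"
  pres[, "H"] <- has_nh(seq)
  pres[, "CN"] <- seq$n_methyl
  pres
}

#' Build a macrocycle conformation from backbone torsions
#'
#' Builds the chain by sequential internal-coordinate placement
#' (natural-extension reference frames) using the ideal geometry table.
#' Dependent atoms (carbonyl O, amide H, N-methyl CN, side-chain CB sphere)
#' are placed from the local peptide-bond frames.  No closure is enforced:
#' the C(n) to N(1) gap may be open; use [solve_closure()] to obtain closed
#' rings.
#'
#' @param seq a [macrocycle_sequence()].
#' @param torsions n x 3 numeric matrix of (phi, psi, omega) in degrees.
#' @return A `cycpep_conformation`.
#' @export
build_from_torsions <- function(seq, torsions) {
  n <- nrow(seq)
  torsions <- as.matrix(torsions)
  if (nrow(torsions) != n || ncol(torsions) != 3) {
    stop("torsion matrix must be ", n, " x 3 (phi, psi, omega)")
  }
  if (!all(is.finite(torsions))) stop("non-finite torsion angles")
  tor <- wrap_angle(torsions)
  dimnames(tor) <- list(NULL, c("phi", "psi", "omega"))
  g <- .ideal

  co <- array(NA_real_, dim = c(n, length(.atom_slots), 3),
              dimnames = list(NULL, .atom_slots, c("x", "y", "z")))
  ## seed frame: N1 at origin, CA1 on +x, virtual C0 in the xy plane
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_n_ca, 0, 0)
  th <- g$a_c_n_ca * .deg2rad
  C0 <- N1 + g$b_c_n * c(cos(th), sin(th), 0)
  co[1, "N", ] <- N1
  co[1, "CA", ] <- CA1
  co[1, "C", ] <- nerf_place(C0, N1, CA1, g$b_ca_c, g$a_n_ca_c, tor[1, "phi"])
  for (i in seq_len(n - 1)) {
    co[i + 1, "N", ] <- nerf_place(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                                   g$b_c_n, g$a_ca_c_n, tor[i, "psi"])
    co[i + 1, "CA", ] <- nerf_place(co[i, "CA", ], co[i, "C", ], co[i + 1, "N", ],
                                    g$b_n_ca, g$a_c_n_ca, tor[i, "omega"])
    co[i + 1, "C", ] <- nerf_place(co[i, "C", ], co[i + 1, "N", ], co[i + 1, "CA", ],
                                   g$b_ca_c, g$a_n_ca_c, tor[i + 1, "phi"])
  }
  ## ideal-geometry images of N(1), CA(1) continued past C(n)
  N_img <- nerf_place(co[n, "N", ], co[n, "CA", ], co[n, "C", ],
                      g$b_c_n, g$a_ca_c_n, tor[n, "psi"])
  CA_img <- nerf_place(co[n, "CA", ], co[n, "C", ], N_img,
                       g$b_n_ca, g$a_c_n_ca, tor[n, "omega"])
  conf <- new_conformation(seq, tor, co,
                           aux = list(C0 = C0, N_img = N_img, CA_img = CA_img))
  place_dependent_atoms(conf)
}

## Place O, H, CN, CB from the backbone frame.  O(i) sits in the peptide
## plane anti to N(i+1) (dihedral psi + 180 about N-CA-C); H/CN sit on the
## amide nitrogen along the in-plane bisector opposite the two N bonds;
## CB is placed by the chirality-signed improper C-N-CA-CB.
place_dependent_atoms <- function(conf) {
  seq <- conf$seq
  n <- nrow(seq)
  g <- .ideal
  co <- conf$coords
  pres <- atom_presence(seq)
  psi <- conf$torsions[, "psi"]
  for (i in seq_len(n)) {
    co[i, "O", ] <- nerf_place(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                               g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    cprev <- if (i > 1) co[i - 1, "C", ] else if (!is.null(conf$aux)) {
      conf$aux$C0
    } else co[n, "C", ]
    u <- unitv(cprev - co[i, "N", ])
    v <- unitv(co[i, "CA", ] - co[i, "N", ])
    hdir <- -unitv(u + v)
    if (pres[i, "H"]) co[i, "H", ] <- co[i, "N", ] + g$b_n_h * hdir
    if (pres[i, "CN"]) co[i, "CN", ] <- co[i, "N", ] + g$b_n_cn * hdir
    if (pres[i, "CB"]) {
      sgn <- if (seq$chirality[i] == "D") 1 else -1
      co[i, "CB", ] <- nerf_place(co[i, "C", ], co[i, "N", ], co[i, "CA", ],
                                  g$b_ca_cb, g$a_n_ca_cb, sgn * g$t_c_n_ca_cb)
    }
  }
  conf$coords <- co
  conf
}

#' Measure backbone torsions from coordinates
#'
#' Standard IUPAC dihedral convention, cyclic: phi(i) uses C(i-1) (C(n) for
#' residue 1), psi(i) uses N(i+1), omega(i) is measured over
#' CA(i)-C(i)-N(i+1)-CA(i+1).  For conformations built from torsions with an
#' open closure gap, the stored ideal-frame anchor atoms are used for the
#' wrap-around dihedrals so that build/measure is an exact inverse pair.
#'
#' @param conf a `cycpep_conformation`.
#' @param use_aux honour the stored ideal-frame anchors of open chains (the
#'   default).  `FALSE` always measures the wrap-around dihedrals from the
#'   actual cyclic atoms, which makes the result independent of where the
#'   formal cut sits (used by the scoring machinery).
#' @return n x 3 matrix of (phi, psi, omega) in degrees.
#' @export
measure_torsions <- function(conf, use_aux = TRUE) {
  co <- conf$coords
  n <- dim(co)[1]
  if (anyNA(co[, c("N", "CA", "C"), ])) {
    bad <- which(apply(is.na(co[, c("N", "CA", "C"), , drop = FALSE]), 1, any))
    stop("missing backbone atoms at residue(s) ", paste(bad, collapse = ", "))
  }
  aux <- if (use_aux) conf$aux else NULL
  Cprev1 <- if (!is.null(aux)) aux$C0 else co[n, "C", ]
  Nnext_n <- if (!is.null(aux)) aux$N_img else co[1, "N", ]
  CAnext_n <- if (!is.null(aux)) aux$CA_img else co[1, "CA", ]
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    cp <- if (i > 1) co[i - 1, "C", ] else Cprev1
    nn <- if (i < n) co[i + 1, "N", ] else Nnext_n
    can <- if (i < n) co[i + 1, "CA", ] else CAnext_n
    out[i, "phi"] <- dihedral(cp, co[i, "N", ], co[i, "CA", ], co[i, "C", ])
    out[i, "psi"] <- dihedral(co[i, "N", ], co[i, "CA", ], co[i, "C", ], nn)
    out[i, "omega"] <- dihedral(co[i, "CA", ], co[i, "C", ], nn, can)
  }
  out
}

#' Geometry of the ring-closure bond
#'
#' Measures the C(n)-N(1) bond length, the flanking bond angles
#' CA(n)-C(n)-N(1) and C(n)-N(1)-CA(1), and the closure omega dihedral
#' CA(n)-C(n)-N(1)-CA(1), from the actual coordinates.
#'
#' @param conf a `cycpep_conformation`.
#' @return List with `bondlength`, `angle_c` (at the carbonyl carbon),
#'   `angle_n` (at the ring nitrogen) and `omega`.
#' @export
closure_geometry <- function(conf) {
  co <- conf$coords
  n <- dim(co)[1]
  Cn <- co[n, "C", ]; CAn <- co[n, "CA", ]
  N1 <- co[1, "N", ]; CA1 <- co[1, "CA", ]
  list(bondlength = vnorm(N1 - Cn),
       angle_c = bond_angle(CAn, Cn, N1),
       angle_n = bond_angle(Cn, N1, CA1),
       omega = dihedral(CAn, Cn, N1, CA1))
}

#' Is the ring closed to within tolerance?
#' @param conf a `cycpep_conformation`.
#' @param tol_bond,tol_angle tolerances in Angstrom / degrees.
#' @return Logical.
#' @export
is_closed <- function(conf, tol_bond = 1e-4, tol_angle = 1e-3) {
  gg <- closure_geometry(conf)
  g0 <- .ideal$closure
  abs(gg$bondlength - g0$bondlength) <= tol_bond &&
    ang_dist(gg$angle_n, g0$angle1) <= tol_angle &&
    ang_dist(gg$angle_c, g0$angle2) <= tol_angle
}

#' Mirror a conformation
#'
#' Reflects the coordinates through the xy plane, swaps L and D chirality
#' flags (achiral residues unchanged) and negates all torsions.
#'
#' @param conf a `cycpep_conformation`.
#' @return The mirrored `cycpep_conformation`.
#' @export
mirror_conformation <- function(conf) {
  co <- conf$coords
  co[, , 3] <- -co[, , 3]
  aux <- conf$aux
  if (!is.null(aux)) aux <- lapply(aux, function(p) p * c(1, 1, -1))
  new_conformation(mirror_sequence(conf$seq), wrap_angle(-conf$torsions), co, aux)
}

#' Cyclically permute the starting residue
#'
#' Residue i becomes residue i - k (mod n); coordinates are unchanged, only
#' the labelling rotates.  The ideal-frame anchor atoms of open chains are
#' dropped (they are tied to the original cut position), so wrap-around
#' torsions of a permuted conformation are measured from the actual atoms.
#'
#' @param conf a `cycpep_conformation`.
#' @param k integer shift (reduced mod n).
#' @return The permuted `cycpep_conformation`.
#' @export
cyclic_permute <- function(conf, k) {
  n <- nrow(conf$seq)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(conf)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  co <- conf$coords[idx, , , drop = FALSE]
  out <- new_conformation(permute_sequence(conf$seq, k),
                          NULL, co, aux = NULL)
  out$torsions <- measure_torsions(out)
  out
}

## Flat atom table used by the scoring machinery: one row per existing atom.
atom_table <- function(conf) {
  pres <- atom_presence(conf$seq)
  n <- nrow(conf$seq)
  rows <- which(t(pres))  # column-major over slots within residue
  slot <- rep(seq_along(.atom_slots), n)[rows]
  res <- rep(seq_len(n), each = length(.atom_slots))[rows]
  xyz <- matrix(NA_real_, length(rows), 3)
  for (j in seq_along(rows)) xyz[j, ] <- conf$coords[res[j], slot[j], ]
  data.frame(res = res, atom = .atom_slots[slot], x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], stringsAsFactors = FALSE)
}

## Bond-separation matrix between all existing atoms of a sequence (number of
## covalent bonds on the shortest path, ring topology included).  Cached per
## atom-presence signature.
.bondsep_cache <- new.env(parent = emptyenv())

bond_separation <- function(seq) {
  pres <- atom_presence(seq)
  key <- paste(c(nrow(seq), as.integer(pres)), collapse = "")
  hit <- .bondsep_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(seq)
  ids <- which(t(pres))
  slot <- .atom_slots[rep(seq_along(.atom_slots), n)[ids]]
  res <- rep(seq_len(n), each = length(.atom_slots))[ids]
  m <- length(ids)
  name <- paste(slot, res)
  index_of <- stats::setNames(seq_len(m), name)
  adj <- vector("list", m)
  add_edge <- function(a, b) {
    ia <- index_of[[a]]; ib <- index_of[[b]]
    if (is.null(ia) || is.null(ib)) return()
    adj[[ia]] <<- c(adj[[ia]], ib)
    adj[[ib]] <<- c(adj[[ib]], ia)
  }
  for (i in seq_len(n)) {
    ip <- cyc_next(i, n)
    add_edge(paste("N", i), paste("CA", i))
    add_edge(paste("CA", i), paste("C", i))
    add_edge(paste("C", i), paste("O", i))
    add_edge(paste("C", i), paste("N", ip))
    if (pres[i, "CB"]) add_edge(paste("CA", i), paste("CB", i))
    if (pres[i, "H"]) add_edge(paste("N", i), paste("H", i))
    if (pres[i, "CN"]) add_edge(paste("N", i), paste("CN", i))
  }
  sep <- matrix(Inf, m, m)
  for (s in seq_len(m)) {
    dist <- rep(Inf, m)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] > d]
      dist[nxt] <- d
      frontier <- nxt
    }
    sep[s, ] <- dist
  }
  out <- list(sep = sep, res = res, slot = slot)
  .bondsep_cache[[key]] <- out
  out
}
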