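## PDB input/output ---------------------------------------------------------
##
## Single-chain macrocycle models.  D-amino acids use their chemical-
## component names (DAL, DPH, DIL, DLE, DPR, DVA); the N-methyl carbon is
## written as atom "CN" on the residue's nitrogen.  bio3d does the actual
## record parsing/formatting.

resname_for <- function(aa, chirality) {
  ifelse(chirality == "D", .d_resname[aa], aa)
}

#' Write a macrocycle conformation to a PDB file
#'
#' @param conf a `cycpep_conformation`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(conf, path) {
  seq <- conf$seq
  n <- nrow(seq)
  at <- atom_table(conf)
  at <- at[stats::complete.cases(at), , drop = FALSE]
  resid <- resname_for(seq$aa[at$res], seq$chirality[at$res])
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = round(xyz, 3),
                   resno = at$res, resid = resid,
                   elety = at$atom, chain = rep("A", nrow(at)),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a macrocycle conformation from a PDB file
#'
#' Accepts ATOM and HETATM records for a single peptide chain.  Residue
#' chirality is inferred from the component name, N-methylation from the
#' presence of a CN atom.  Missing amide H or carbonyl O atoms are
#' reconstructed from ideal geometry; a missing backbone N, CA or C is an
#' error naming the residue.
#'
#' @param path PDB file path.
#' @return A `cycpep_conformation`.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (length(unique(a$chain[!is.na(a$chain)])) > 1) {
    stop("expected a single peptide chain, found: ",
         paste(unique(a$chain), collapse = ", "))
  }
  resnos <- sort(unique(a$resno))
  n <- length(resnos)
  aa <- character(n); chir <- character(n); nme <- logical(n)
  co <- array(NA_real_, dim = c(n, length(.atom_slots), 3),
              dimnames = list(NULL, .atom_slots, c("x", "y", "z")))
  for (i in seq_len(n)) {
    rows <- a[a$resno == resnos[i], , drop = FALSE]
    rn <- toupper(rows$resid[1])
    if (rn %in% .aa_identities) {
      aa[i] <- rn
      chir[i] <- if (rn %in% .achiral_aa) "achiral" else "L"
    } else if (rn %in% names(.d_resname_rev)) {
      aa[i] <- .d_resname_rev[[rn]]
      chir[i] <- "D"
    } else {
      stop("unknown residue name '", rn, "' at residue ", i)
    }
    for (atom in .atom_slots) {
      j <- which(toupper(rows$elety) == atom)
      if (length(j) == 1) {
        co[i, atom, ] <- as.numeric(rows[j, c("x", "y", "z")])
      }
    }
    nme[i] <- !anyNA(co[i, "CN", ])
    for (atom in c("N", "CA", "C")) {
      if (anyNA(co[i, atom, ])) {
        stop("missing backbone atom ", atom, " at residue ", i)
      }
    }
  }
  seq <- macrocycle_sequence(aa, chir, nme, strict = FALSE)
  conf <- new_conformation(seq, NULL, co, aux = NULL)
  conf$torsions <- measure_torsions(conf)
  ## reconstruct any dependent atoms the file did not carry
  pres <- atom_presence(seq)
  rebuilt <- place_dependent_atoms(conf)
  for (atom in c("O", "H", "CN", "CB")) {
    miss <- pres[, atom] & apply(is.na(co[, atom, , drop = FALSE]), 1, any)
    co[miss, atom, ] <- rebuilt$coords[miss, atom, ]
  }
  conf$coords <- co
  conf
}
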