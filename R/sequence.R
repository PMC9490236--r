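## Residue vocabulary -------------------------------------------------------

## Hydrophobic design alphabet plus glycine and AIB.  AIB is supported by the
## data model but excluded from the default design alphabet.
.aa_identities <- c("ALA", "VAL", "LEU", "ILE", "PHE", "PRO", "GLY", "AIB")
.achiral_aa <- c("GLY", "AIB")

## PDB chemical-component names for the D-amino acids in the alphabet.
.d_resname <- c(ALA = "DAL", PHE = "DPH", ILE = "DIL", LEU = "DLE",
                PRO = "DPR", VAL = "DVA")
.d_resname_rev <- stats::setNames(names(.d_resname), .d_resname)

#' Hydrophobic design alphabets
#'
#' The identities allowed during sequence design: L-amino acids at negative-phi
#' positions and D-amino acids at positive-phi positions.  Both lists are
#' hydrophobic-only; glycine and AIB are excluded by default.
#'
#' @return A list with components `L` and `D`, each a character vector of
#'   3-letter identities.
#' @export
design_alphabets <- function() {
  list(L = c("ALA", "VAL", "LEU", "PHE", "ILE", "PRO"),
       D = c("ALA", "PHE", "ILE", "LEU", "PRO", "VAL"))
}

#' Construct a macrocycle sequence
#'
#' A cyclic, ordered list of residue specifications.  Indexing is cyclic (the
#' residue after position n is position 1) but equality is position-wise: no
#' implicit rotation is applied when comparing sequences.
#'
#' @param aa character vector of 3-letter identities (`ALA`, `VAL`, `LEU`,
#'   `ILE`, `PHE`, `PRO`, `GLY`, `AIB`).
#' @param chirality character vector, one of `"L"`, `"D"`, `"achiral"` per
#'   residue.  Glycine and AIB must be achiral.
#' @param n_methyl logical vector of backbone N-methylation flags.  Proline
#'   (either hand) cannot be N-methylated.
#' @param strict enforce the default 6-12 residue length policy.
#' @return An object of class `macrocycle_sequence`: a data frame with columns
#'   `aa`, `chirality`, `n_methyl` and 1-based cyclic position as row order.
#' @export
macrocycle_sequence <- function(aa, chirality = NULL, n_methyl = FALSE,
                                strict = TRUE) {
  aa <- toupper(as.character(aa))
  n <- length(aa)
  if (is.null(chirality)) {
    chirality <- ifelse(aa %in% .achiral_aa, "achiral", "L")
  }
  chirality <- rep_len(as.character(chirality), n)
  n_methyl <- rep_len(as.logical(n_methyl), n)
  if (strict && (n < 6 || n > 12)) {
    stop("macrocycle length must be in [6, 12] (got ", n,
         "); use strict = FALSE to override")
  }
  bad <- !aa %in% .aa_identities
  if (any(bad)) stop("unknown residue identity: ", paste(aa[bad], collapse = ", "))
  if (!all(chirality %in% c("L", "D", "achiral"))) {
    stop("chirality must be 'L', 'D' or 'achiral'")
  }
  ach <- aa %in% .achiral_aa
  if (any(ach & chirality != "achiral")) {
    stop("GLY and AIB are achiral")
  }
  if (any(!ach & chirality == "achiral")) {
    stop("only GLY and AIB may be achiral")
  }
  if (any(aa == "PRO" & n_methyl)) {
    stop("proline (L or D) cannot be N-methylated")
  }
  out <- data.frame(aa = aa, chirality = chirality, n_methyl = n_methyl,
                    stringsAsFactors = FALSE)
  class(out) <- c("macrocycle_sequence", "data.frame")
  out
}

#' @export
print.macrocycle_sequence <- function(x, ...) {
  cat("macrocycle sequence, ", nrow(x), " residues: ",
      sequence_string(x), "\n", sep = "")
  invisible(x)
}

#' One-letter style summary of a macrocycle sequence
#'
#' Lower case marks D-amino acids, `*` marks N-methylation (the convention
#' used when printing designed macrocycles).
#'
#' @param seq a [macrocycle_sequence()].
#' @return A single character string.
#' @export
sequence_string <- function(seq) {
  one <- c(ALA = "A", VAL = "V", LEU = "L", ILE = "I", PHE = "F",
           PRO = "P", GLY = "G", AIB = "B")
  ch <- one[seq$aa]
  ch[seq$chirality == "D"] <- tolower(ch[seq$chirality == "D"])
  ch[seq$n_methyl] <- paste0(ch[seq$n_methyl], "*")
  paste(ch, collapse = "")
}

## cyclic successor / predecessor indices
cyc_next <- function(i, n) i %% n + 1L
cyc_prev <- function(i, n) (i - 2L) %% n + 1L

## cyclic separation between residue indices (0 .. floor(n/2))
cyclic_separation <- function(i, j, n) {
  d <- abs(i - j) %% n
  pmin(d, n - d)
}

## Does this residue have a backbone amide NH donor?
has_nh <- function(seq) {
  !(seq$aa == "PRO" | seq$n_methyl)
}

#' Read / write the macrocycle sequence dialect (JSON)
#'
#' The on-disk dialect is a JSON array of objects with fields `aa`,
#' `chirality` and `n_methyl`.
#'
#' @param path file path.
#' @return `read_sequence_json` returns a [macrocycle_sequence()].
#' @export
read_sequence_json <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  macrocycle_sequence(rec$aa, rec$chirality, rec$n_methyl)
}

#' @rdname read_sequence_json
#' @param seq a [macrocycle_sequence()].
#' @export
write_sequence_json <- function(seq, path) {
  df <- data.frame(aa = seq$aa, chirality = seq$chirality,
                   n_methyl = seq$n_methyl, stringsAsFactors = FALSE)
  jsonlite::write_json(df, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

## Mirror a sequence: swap L <-> D, achiral unchanged.
mirror_sequence <- function(seq) {
  ch <- seq$chirality
  ch[seq$chirality == "L"] <- "D"
  ch[seq$chirality == "D"] <- "L"
  macrocycle_sequence(seq$aa, ch, seq$n_methyl, strict = FALSE)
}

## Rotate a sequence so residue i becomes residue i - k (mod n).
permute_sequence <- function(seq, k) {
  n <- nrow(seq)
  k <- ((k %% n) + n) %% n
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  macrocycle_sequence(seq$aa[idx], seq$chirality[idx], seq$n_methyl[idx],
                      strict = FALSE)
}
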