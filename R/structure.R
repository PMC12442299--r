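# The protein_structure container: a flat atom table plus derived
# per-residue views. All geometry operations in the package consume it.

#' Construct a protein structure object
#'
#' A `protein_structure` is a light container around a flat atom table, in the
#' spirit of a PDB file: one row per atom with residue number, residue name,
#' atom name, element, coordinates and a per-atom confidence value stored in
#' the B-factor column (pLDDT, 0-100, for AlphaFold-style models).
#'
#' @param atoms data.frame with columns `resno` (integer, strictly
#'   non-decreasing), `resid` (3-letter residue code), `elety` (atom name,
#'   e.g. "CA"), `element` (chemical element symbol), `x`, `y`, `z`
#'   (Angstrom), `b` (B-factor / pLDDT) and optionally `o` (occupancy,
#'   default 1).
#' @param id identifier string.
#' @param plddt logical; if `TRUE` the B-factor column is interpreted as
#'   pLDDT and validated to lie in \[0, 100\].
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, id = "structure", plddt = TRUE) {
  req <- c("resno", "resid", "elety", "element", "x", "y", "z", "b")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (is.null(atoms$o)) atoms$o <- 1
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  if (any(diff(atoms$resno) < 0)) stop("residue numbers must be non-decreasing")
  if (plddt && (any(atoms$b < 0) || any(atoms$b > 100))) {
    stop("pLDDT (B-factor) values must lie in [0, 100]")
  }
  atoms$resid <- toupper(as.character(atoms$resid))
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, plddt = plddt),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "<protein_structure> %s: %d residues, %d atoms, mean %s %.1f\n",
    x$id, n_residues(x), nrow(x$atoms),
    if (x$plddt) "pLDDT" else "B-factor", mean_plddt(x)
  ))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `protein_structure`.
#' @return integer count of distinct residues.
#' @export
n_residues <- function(structure) length(unique(structure$atoms$resno))

#' Residue numbers, in chain order
#' @param structure a `protein_structure`.
#' @return integer vector of residue numbers.
#' @export
residue_numbers <- function(structure) unique(structure$atoms$resno)

#' One-letter sequence derived from residue names
#'
#' Every standard 3-letter code maps to its 1-letter code; anything else
#' becomes `"X"`.
#'
#' @param structure a `protein_structure`.
#' @return character scalar, one letter per residue.
#' @export
structure_sequence <- function(structure) {
  at <- structure$atoms
  res3 <- at$resid[!duplicated(at$resno)]
  paste(aa3_to_aa1(res3), collapse = "")
}

#' Extract coordinates of one atom type per residue
#'
#' @param structure a `protein_structure`.
#' @param elety atom name to pick (default "CA"). Residues lacking the atom
#'   yield a row of `NA`.
#' @return numeric matrix, residues x 3, rownames = residue numbers.
#' @export
atom_coords <- function(structure, elety = "CA") {
  at <- structure$atoms
  resnos <- unique(at$resno)
  sel <- at[at$elety == elety, , drop = FALSE]
  sel <- sel[!duplicated(sel$resno), , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(resnos), ncol = 3,
              dimnames = list(resnos, c("x", "y", "z")))
  idx <- match(sel$resno, resnos)
  m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
  m
}

#' Per-residue pLDDT values
#'
#' AlphaFold writes the same pLDDT for every atom of a residue; the CA atom's
#' B-factor is taken as the canonical per-residue value (falling back to the
#' residue's first atom when CA is absent).
#'
#' @param structure a `protein_structure`.
#' @return numeric vector, one value per residue.
#' @export
residue_plddt <- function(structure) {
  at <- structure$atoms
  resnos <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- at$b[!duplicated(at$resno)]
  names(out) <- resnos
  hit <- match(ca$resno, resnos)
  out[hit] <- ca$b
  unname(out)
}

#' Mean per-residue pLDDT of a structure
#' @param structure a `protein_structure`.
#' @return numeric scalar in \[0, 100\].
#' @export
mean_plddt <- function(structure) mean(residue_plddt(structure))

#' Apply a rigid motion to a structure
#'
#' @param structure a `protein_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed `protein_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Draw a uniformly random rotation matrix
#'
#' @param seed optional integer seed for reproducibility.
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  # fix signs so the distribution is Haar and the determinant is +1
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
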