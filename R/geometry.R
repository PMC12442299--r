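# Scalar geometric metrics: radius of gyration and residue contact maps.

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_c|^2 / sum_i m_i )` with `r_c` the
#' mass-weighted centroid; atomic masses come from the element column.
#'
#' @param structure a `protein_structure`.
#' @return radius of gyration in Angstrom (>= 0).
#' @export
radius_of_gyration <- function(structure) {
  at <- structure$atoms
  m <- .ATOM_MASS[toupper(at$element)]
  if (anyNA(m)) {
    stop("unknown element mass for: ",
         paste(unique(at$element[is.na(m)]), collapse = ", "))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ctr <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
}

#' Residue contact map
#'
#' Boolean residue-by-residue matrix: two residues are in contact when
#' their CB atoms (CA for glycine or when CB is absent) lie within the
#' cutoff. Symmetric; the diagonal is excluded.
#'
#' @param structure a `protein_structure`.
#' @param cutoff contact distance in Angstrom (default 8).
#' @return logical matrix, residues x residues.
#' @export
contact_map <- function(structure, cutoff = 8) {
  cb <- atom_coords(structure, "CB")
  ca <- atom_coords(structure, "CA")
  use_ca <- is.na(cb[, 1])
  cb[use_ca, ] <- ca[use_ca, ]
  d <- as.matrix(stats::dist(cb))
  m <- d < cutoff
  diag(m) <- FALSE
  dimnames(m) <- dimnames(d)
  m
}
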