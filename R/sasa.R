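# Shrake-Rupley solvent-accessible surface area, relative accessibility,
# surface residues and formal surface charge.
#
# The quadrature sphere is a Fibonacci point set expressed in a canonical
# frame derived from the structure itself (mass-weighted principal axes with
# a skewness-based sign convention). Because that frame co-rotates with the
# coordinates, SASA values are invariant under rigid motions up to solver
# round-off rather than drifting with the orientation of a fixed global
# point set.

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation-equivariant canonical frame anchored on the first atoms of the
# chain: first axis along atom1 -> atom2, second axis the orthogonalised
# direction to the first non-colinear atom, third by the right-hand rule.
# Because the frame depends only on these leading atoms, appending atoms
# elsewhere leaves every quadrature point fixed (exact monotonicity), and
# rigid motions rotate the frame with the structure (exact invariance).
.canonical_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) return(diag(3))
  a <- xyz[2, ] - xyz[1, ]
  na <- sqrt(sum(a * a))
  if (na < 1e-6) return(diag(3))
  u1 <- a / na
  for (k in 3:n) {
    b <- xyz[k, ] - xyz[1, ]
    b <- b - sum(b * u1) * u1
    nb <- sqrt(sum(b * b))
    if (nb > 1e-6) return(cbind(u1, b / nb, .cross3(u1, b / nb)))
  }
  diag(3)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default 1.4 Angstrom, a water molecule) over the
#' atomic model: each atom's extended sphere (van der Waals radius + probe)
#' is sampled at `n_points` quadrature points, and the fraction not occluded
#' by any neighbouring atom's extended sphere contributes to the atom's
#' exposed area. Per-residue SASA sums the residue's atoms.
#'
#' @param structure a `protein_structure`.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @return object of class `sasa_result`: list with `atom_sasa`,
#'   `residue_sasa` (named by residue number), `residue_rsa` (filled by
#'   [relative_accessibility()]), `probe`, `n_points`.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960) {
  at <- structure$atoms
  elem <- toupper(at$element)
  unknown <- setdiff(unique(elem), names(.VDW_RADII))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  radii <- unname(.VDW_RADII[elem]) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  sphere <- .fibonacci_sphere(n_points) %*% t(.canonical_frame(xyz))
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + radii)^2 & seq_len(n) != i)
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- dj >= radii[j]^2
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    atom_sasa[i] <- frac * 4 * pi * radii[i]^2
  }
  resnos <- unique(at$resno)
  residue_sasa <- vapply(resnos, function(r) sum(atom_sasa[at$resno == r]), numeric(1))
  names(residue_sasa) <- resnos
  structure(
    list(atom_sasa = atom_sasa, residue_sasa = residue_sasa,
         residue_rsa = NULL, probe = probe, n_points = n_points,
         sequence = structure_sequence(structure)),
    class = "sasa_result"
  )
}

#' Relative solvent accessibility
#'
#' RSA = per-residue SASA divided by the residue type's theoretical maximum
#' ASA (Tien et al. values; unknown residue types use the median table
#' value).
#'
#' @param sasa a `sasa_result` from [shrake_rupley_sasa()].
#' @param max_asa named numeric vector of maximum ASA per 1-letter code;
#'   defaults to [max_asa_table()].
#' @return the `sasa_result` with `residue_rsa` filled in.
#' @export
relative_accessibility <- function(sasa, max_asa = max_asa_table()) {
  aa <- strsplit(sasa$sequence, "")[[1]]
  denom <- max_asa[aa]
  denom[is.na(denom)] <- stats::median(max_asa)
  rsa <- unname(sasa$residue_sasa) / unname(denom)
  names(rsa) <- names(sasa$residue_sasa)
  sasa$residue_rsa <- rsa
  sasa
}

#' Surface residues by RSA threshold
#'
#' @param sasa a `sasa_result` with RSA filled (see
#'   [relative_accessibility()]).
#' @param threshold residues with RSA strictly above this are surface
#'   (default 0.25).
#' @return integer vector of surface residue numbers.
#' @export
surface_residues <- function(sasa, threshold = 0.25) {
  if (is.null(sasa$residue_rsa)) stop("RSA not computed; call relative_accessibility() first")
  as.integer(names(sasa$residue_rsa)[sasa$residue_rsa > threshold])
}

#' Formal surface charge of a structure
#'
#' Sums integer formal charges at pH 7 (Asp/Glu -1, Lys/Arg +1, His and all
#' others 0; termini uncharged) over surface residues.
#'
#' @param structure a `protein_structure`.
#' @param sasa optional precomputed `sasa_result` (RSA will be added if
#'   missing); computed from the structure when absent.
#' @param threshold RSA surface threshold (default 0.25).
#' @param charge_table optional named numeric vector of per-residue charges
#'   (1-letter codes) overriding the formal model.
#' @return signed integer-valued charge.
#' @export
surface_charge <- function(structure, sasa = NULL, threshold = 0.25,
                           charge_table = NULL) {
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(structure)
  if (is.null(sasa$residue_rsa)) sasa <- relative_accessibility(sasa)
  surf <- surface_residues(sasa, threshold)
  aa <- strsplit(sasa$sequence, "")[[1]]
  resnos <- as.integer(names(sasa$residue_sasa))
  surf_aa <- aa[match(surf, resnos)]
  if (is.null(charge_table)) {
    sum(residue_formal_charge(surf_aa))
  } else {
    ch <- charge_table[surf_aa]
    ch[is.na(ch)] <- 0
    sum(ch)
  }
}
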