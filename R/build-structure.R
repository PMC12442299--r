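# Ideal-geometry backbone builder for synthetic structures. Chains are
# grown residue by residue from internal coordinates (bond lengths, bond
# angles, phi/psi/omega torsions) with the standard NeRF construction.
# Standard backbone geometry: N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A,
# tau(N-CA-C) ~ 111 deg; sufficient for SASA / secondary structure / Rg
# testing, not for rotamer-level realism.

.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231, CA_CB = 1.521)
.ANGLE <- c(N_CA_C = 111.0, CA_C_N = 116.6, C_N_CA = 121.7,
            CA_C_O = 120.5, N_CA_CB = 110.4)
.DIHEDRAL_BY_SS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -119, psi = 113)
)

.deg <- function(x) x * pi / 180

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v * v))

# Place atom D given positions A, B, C, the C-D bond length, B-C-D angle
# (degrees) and A-B-C-D torsion (degrees).
.nerf <- function(A, B, C, bond, angle, torsion) {
  th <- .deg(angle); ph <- .deg(torsion)
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + cbind(bc, m, n) %*% d2
}

#' Specify a synthetic structure
#'
#' @param segments data.frame (or list coercible to one) with columns
#'   `type` (`"helix"`, `"strand"` or `"coil"`), `length` (residues, >= 1)
#'   and `plddt` (per-residue confidence written into the B-factor column,
#'   0-100).
#' @param sequence optional 1-letter amino-acid string for the whole chain;
#'   when absent a random sequence is drawn at build time.
#' @return object of class `structure_spec`.
#' @export
structure_spec <- function(segments, sequence = NULL) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("type", "length", "plddt") %in% names(segments)))
  if (!all(segments$type %in% c("helix", "strand", "coil"))) {
    stop("segment type must be helix, strand or coil")
  }
  if (any(segments$length < 1)) stop("segment lengths must be >= 1")
  if (any(segments$plddt < 0 | segments$plddt > 100)) stop("plddt must lie in [0, 100]")
  total <- sum(segments$length)
  if (!is.null(sequence) && nchar(sequence) != total) {
    stop("sequence length does not match total segment length")
  }
  structure(list(segments = segments, sequence = sequence), class = "structure_spec")
}

# Expand a structure_spec into a per-residue table (aa, ss, plddt, phi, psi),
# drawing random sequence letters and coil torsions from the supplied seed.
.residue_plan <- function(spec, seed) {
  segs <- spec$segments
  n <- sum(segs$length)
  ss <- rep(segs$type, segs$length)
  plddt <- rep(segs$plddt, segs$length)
  set.seed(seed)
  aa <- if (!is.null(spec$sequence)) strsplit(spec$sequence, "")[[1]] else {
    sample(unname(.AA_3TO1), n, replace = TRUE)
  }
  phi <- psi <- numeric(n)
  for (type in c("helix", "strand")) {
    idx <- ss == type
    phi[idx] <- .DIHEDRAL_BY_SS[[type]]["phi"]
    psi[idx] <- .DIHEDRAL_BY_SS[[type]]["psi"]
  }
  coil <- ss == "coil"
  phi[coil] <- stats::runif(sum(coil), -180, 180)
  psi[coil] <- stats::runif(sum(coil), -180, 180)
  data.frame(aa = aa, ss = ss, plddt = plddt, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# Build a protein_structure (N, CA, C, O backbone + CB except Gly) from a
# per-residue plan.
.build_backbone <- function(plan, id) {
  n <- nrow(plan)
  Npos <- CApos <- Cpos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(.BOND["N_CA"], 0, 0)
  ang <- .deg(.ANGLE["N_CA_C"])
  Cpos[1, ] <- CApos[1, ] + .BOND["CA_C"] * c(-cos(ang), sin(ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      Npos[i, ] <- .nerf(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                         .BOND["C_N"], .ANGLE["CA_C_N"], plan$psi[i - 1])
      CApos[i, ] <- .nerf(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                          .BOND["N_CA"], .ANGLE["C_N_CA"], 180)
      Cpos[i, ] <- .nerf(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                         .BOND["CA_C"], .ANGLE["N_CA_C"], plan$phi[i])
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    Opos <- .nerf(Npos[i, ], CApos[i, ], Cpos[i, ],
                  .BOND["C_O"], .ANGLE["CA_C_O"], plan$psi[i] + 180)
    atoms <- rbind(
      data.frame(elety = "N", element = "N", x = Npos[i, 1], y = Npos[i, 2], z = Npos[i, 3]),
      data.frame(elety = "CA", element = "C", x = CApos[i, 1], y = CApos[i, 2], z = CApos[i, 3]),
      data.frame(elety = "C", element = "C", x = Cpos[i, 1], y = Cpos[i, 2], z = Cpos[i, 3]),
      data.frame(elety = "O", element = "O", x = Opos[1], y = Opos[2], z = Opos[3])
    )
    if (plan$aa[i] != "G") {
      CBpos <- .nerf(Cpos[i, ], Npos[i, ], CApos[i, ],
                     .BOND["CA_CB"], .ANGLE["N_CA_CB"], 122.6)
      atoms <- rbind(atoms, data.frame(elety = "CB", element = "C",
                                       x = CBpos[1], y = CBpos[2], z = CBpos[3]))
    }
    atoms$resno <- i
    atoms$resid <- .AA_1TO3[[plan$aa[i]]] %||% "UNK"
    atoms$b <- plan$plddt[i]
    rows[[i]] <- atoms
  }
  atoms <- do.call(rbind, rows)
  protein_structure(atoms[, c("resno", "resid", "elety", "element", "x", "y", "z", "b")],
                    id = id)
}

#' Build an ideal-geometry synthetic structure
#'
#' Backbone atoms (N, CA, C, O) plus CB (except glycine) are constructed
#' from ideal internal geometry: alpha-helix phi = -57, psi = -47;
#' beta-strand phi = -119, psi = 113; coil segments take seeded random-walk
#' dihedrals. Per-residue pLDDT values come from the segment specification.
#' The same spec and seed always produce identical coordinates.
#'
#' @param spec a [structure_spec()].
#' @param seed integer seed driving the random sequence (when unspecified)
#'   and coil dihedrals.
#' @param id identifier for the structure.
#' @return a `protein_structure`.
#' @export
make_ideal_structure <- function(spec, seed = 1L, id = "synthetic") {
  .build_backbone(.residue_plan(spec, seed), id = id)
}

#' Build a reference/isoform structure pair with known edits
#'
#' The reference is built from `ref_spec`; the isoform is rebuilt from the
#' edited per-residue plan: `delete` removes residue intervals of the
#' reference, `insert` adds fresh segments after given reference positions
#' (position 0 prepends). Because surviving residues keep their reference
#' torsions and sequence letters, an empty edit reproduces the reference
#' exactly, while deletions/insertions change the rebuilt global fold.
#'
#' @param ref_spec a [structure_spec()] for the reference.
#' @param edit list with optional elements `delete` (list of
#'   `c(start, end)` residue intervals, 1-based inclusive) and `insert`
#'   (list of `list(pos = <after this ref position>, segment =
#'   data.frame(type, length, plddt))`).
#' @param seed integer seed.
#' @return list with `ref` and `iso` (`protein_structure`s) and `truth`
#'   (deleted reference positions, inserted isoform positions, and both
#'   sequences).
#' @export
make_structure_pair <- function(ref_spec, edit = list(), seed = 1L) {
  deletions <- edit$delete %||% list()
  insertions <- edit$insert %||% list()
  plan <- .residue_plan(ref_spec, seed)
  n <- nrow(plan)
  deleted <- integer(0)
  for (iv in deletions) {
    if (iv[1] < 1 || iv[2] > n || iv[1] > iv[2]) stop("delete interval outside reference")
    span <- iv[1]:iv[2]
    if (length(intersect(span, deleted))) stop("overlapping delete intervals")
    deleted <- c(deleted, span)
  }
  ins_pos <- vapply(insertions, function(e) as.numeric(e$pos), numeric(1))
  if (anyDuplicated(ins_pos)) stop("overlapping insert positions")
  if (length(ins_pos) && (any(ins_pos < 0) || any(ins_pos > n))) {
    stop("insert position outside reference")
  }
  # assemble the isoform plan: surviving reference residues, with inserted
  # segments (built from derived seeds) placed after their anchor positions
  iso_plan <- plan[0, ]
  origin <- integer(0)
  add_insert <- function(anchor) {
    hit <- which(ins_pos == anchor)
    if (length(hit)) {
      seg <- as.data.frame(insertions[[hit]]$segment)
      sub_seed <- (seed * 131L + anchor * 7L) %% .Machine$integer.max
      ins_plan <- .residue_plan(structure_spec(seg), sub_seed)
      iso_plan <<- rbind(iso_plan, ins_plan)
      origin <<- c(origin, rep(NA_integer_, nrow(ins_plan)))
    }
  }
  add_insert(0)
  for (i in seq_len(n)) {
    if (!(i %in% deleted)) {
      iso_plan <- rbind(iso_plan, plan[i, , drop = FALSE])
      origin <- c(origin, i)
    }
    add_insert(i)
  }
  if (nrow(iso_plan) == 0L) stop("edit removes every residue")
  ref <- .build_backbone(plan, id = "ref")
  iso <- .build_backbone(iso_plan, id = "iso")
  list(
    ref = ref, iso = iso,
    truth = list(
      deleted_ref_positions = sort(deleted),
      inserted_iso_positions = which(is.na(origin)),
      iso_origin = origin,
      ref_sequence = paste(plan$aa, collapse = ""),
      iso_sequence = paste(iso_plan$aa, collapse = "")
    )
  )
}
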