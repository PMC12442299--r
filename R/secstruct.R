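# Simplified Kabsch-Sander secondary-structure assignment. Hydrogen bonds
# are scored with the classic electrostatic model; helices come from
# consecutive 3-/4-/5-turns, sheets from parallel/antiparallel bridge
# patterns, everything else is loop. The eight DSSP states are collapsed to
# three: G/H/I -> H, B/E -> E, else L.

# Kabsch-Sander hydrogen-bond energy matrix: hb[i, j] is TRUE when the CO
# group of residue i accepts a hydrogen bond from the NH group of residue j
# (E < -0.5 kcal/mol). The amide H is placed 1.0 A from N along the
# direction of the preceding residue's C=O bond (C minus O), as in DSSP;
# the first residue has no donor.
.ks_hbonds <- function(N, CA, C, O, energy_cutoff = -0.5) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    v <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + v / sqrt(sum(v * v))
  }
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {        # acceptor CO on residue i
    for (j in seq_len(n)) {      # donor NH on residue j
      if (abs(i - j) < 2 || is.na(H[j, 1])) next
      d_ON <- sqrt(sum((O[i, ] - N[j, ])^2))
      d_CH <- sqrt(sum((C[i, ] - H[j, ])^2))
      d_OH <- sqrt(sum((O[i, ] - H[j, ])^2))
      d_CN <- sqrt(sum((C[i, ] - N[j, ])^2))
      if (d_ON < 0.5 || d_OH < 0.5) next   # clash guard
      e <- q * (1 / d_ON + 1 / d_CH - 1 / d_OH - 1 / d_CN)
      hb[i, j] <- e < energy_cutoff
    }
  }
  hb
}

#' Three-state secondary structure assignment
#'
#' Assigns each residue helix (`H`), sheet (`E`) or loop (`L`) from backbone
#' hydrogen bonding. Residues missing any backbone atom (N, CA, C, O) are
#' assigned `L` with a warning.
#'
#' @param structure a `protein_structure` with backbone atoms.
#' @return character vector of states in \{"H", "E", "L"\}, one per residue.
#' @export
secondary_structure <- function(structure) {
  N <- atom_coords(structure, "N")
  CA <- atom_coords(structure, "CA")
  C <- atom_coords(structure, "C")
  O <- atom_coords(structure, "O")
  n <- nrow(N)
  incomplete <- is.na(N[, 1]) | is.na(CA[, 1]) | is.na(C[, 1]) | is.na(O[, 1])
  if (any(incomplete)) {
    warning(sum(incomplete), " residue(s) missing backbone atoms; assigned L")
  }
  states <- rep("L", n)
  ok <- !incomplete
  if (sum(ok) < 5) return(states)
  # work on the complete-backbone subset, preserving original indexing
  idx <- which(ok)
  hb <- .ks_hbonds(N[idx, , drop = FALSE], CA[idx, , drop = FALSE],
                   C[idx, , drop = FALSE], O[idx, , drop = FALSE])
  m <- length(idx)
  turn <- function(k) {
    t <- rep(FALSE, m)
    ii <- seq_len(m - k)
    t[ii] <- hb[cbind(ii, ii + k)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  sub <- rep("L", m)
  # sheet: parallel / antiparallel bridge patterns (|i - j| > 2)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (abs(i - j) <= 2) next
      par <- (i > 1 && i < m && hb[i - 1, j] && hb[j, i + 1]) ||
             (j > 1 && j < m && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1 && i < m && j > 1 && j < m &&
               hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) sub[c(i, j)] <- "E"
    }
  }
  # helices overwrite: consecutive turns mark the spanned residues
  mark <- function(t, k) {
    for (i in which(t)) {
      if (i > 1 && t[i - 1]) {
        span <- i:min(i + k - 1, m)
        sub[span] <<- "H"
      }
    }
  }
  mark(t3, 3); mark(t5, 5); mark(t4, 4)
  states[idx] <- sub
  states
}

#' Secondary-structure percentages
#'
#' @param states character vector of per-residue states (`H`, `E`, `L`).
#' @return named numeric vector `c(H =, E =, L =)` in percent, summing
#'   to 100.
#' @export
ss_percentages <- function(states) {
  if (length(states) == 0L) stop("empty state vector")
  100 * c(H = mean(states == "H"), E = mean(states == "E"), L = mean(states == "L"))
}
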