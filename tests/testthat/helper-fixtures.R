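# Shared fixtures and independent oracles used across the suite.

# a small mixed-topology structure used by the geometry tests
mixed_structure <- function(seed = 5L) {
  make_ideal_structure(
    structure_spec(data.frame(type = c("helix", "coil", "strand"),
                              length = c(10, 5, 10), plddt = 90)),
    seed = seed
  )
}

# rotation from axis-angle (for deterministic rigid motions)
rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# two ideal strands paired into a parallel beta arrangement (recipe found
# by scanning pairing offsets for maximal backbone hydrogen bonding)
make_sheet_fixture <- function(n = 10) {
  s1 <- make_ideal_structure(
    structure_spec(data.frame(type = "strand", length = n, plddt = 90)), seed = 1)
  ca <- atom_coords(s1, "CA")
  ctr <- colMeans(ca)
  pc <- prcomp(ca)
  u <- pc$rotation[, 1]; v <- pc$rotation[, 3]
  Rm <- 2 * outer(u / sqrt(sum(u^2)), u / sqrt(sum(u^2))) - diag(3)
  s2 <- transform_structure(s1, Rm, as.vector(ctr - Rm %*% ctr) + 4.0 * v - 3.0 * u)
  at2 <- s2$atoms
  at2$resno <- at2$resno + n + 4L
  protein_structure(rbind(s1$atoms, at2), id = "sheet_fixture")
}

# three parallel helices in a triangular bundle; the central helix's core
# residues are buried. Poly-alanine: backbone-plus-CB models under-expose
# bulky residue types, so exposure fixtures use small side chains.
make_bundle_fixture <- function(len = 20) {
  h <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = len, plddt = 90),
                   sequence = strrep("A", len)), seed = 3)
  ca <- atom_coords(h, "CA")
  pc <- prcomp(ca)
  v2 <- pc$rotation[, 2]; v3 <- pc$rotation[, 3]
  at <- h$atoms
  shift <- function(s, d, off) {
    a <- s$atoms
    a[, c("x", "y", "z")] <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, d, "+")
    a$resno <- a$resno + off
    a
  }
  comb <- rbind(at,
                shift(h, 9.5 * v2, len + 5L),
                shift(h, 9.5 * (cos(pi / 3) * v2 + sin(pi / 3) * v3), 2L * (len + 5L)))
  protein_structure(comb, id = "bundle_fixture")
}

# reference = lone exposed helix with a serine site; isoform = the same
# helix plus a second helix packed against the site, burying it. The
# appended residues align as a pure insertion, so reference positions map
# one-to-one.
make_burial_pair <- function() {
  seq30 <- paste(rep("A", 30), collapse = "")
  substr(seq30, 15, 15) <- "S"
  ref <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 30, plddt = 90), sequence = seq30),
    seed = 3, id = "ref")
  ca <- atom_coords(ref, "CA"); cb <- atom_coords(ref, "CB")
  dirv <- cb[15, ] - ca[15, ]; dirv <- dirv / sqrt(sum(dirv^2))
  h2 <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 25, plddt = 90)), seed = 9)
  ca2 <- atom_coords(h2, "CA")
  pc1 <- prcomp(ca); u1 <- pc1$rotation[, 1]
  pc2 <- prcomp(ca2); u2 <- pc2$rotation[, 1]
  vcr <- c(u2[2] * u1[3] - u2[3] * u1[2],
           u2[3] * u1[1] - u2[1] * u1[3],
           u2[1] * u1[2] - u2[2] * u1[1])
  s <- sqrt(sum(vcr^2)); cth <- sum(u2 * u1)
  K <- matrix(c(0, -vcr[3], vcr[2], vcr[3], 0, -vcr[1], -vcr[2], vcr[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + K + K %*% K * ((1 - cth) / max(s^2, 1e-12))
  target <- ca[15, ] + 7 * dirv
  h2t <- transform_structure(h2, Rm, as.vector(target - Rm %*% colMeans(ca2)))
  at2 <- h2t$atoms; at2$resno <- at2$resno + 30L
  iso <- protein_structure(rbind(ref$atoms, at2), id = "iso")
  list(ref = ref, iso = iso, site_pos = 15L,
       aln = global_align(structure_sequence(ref), structure_sequence(iso)))
}

# Build a pair_alignment directly from two gapped aligned strings
align_from_strings <- function(ref_row, iso_row) {
  rc <- strsplit(ref_row, "")[[1]]
  ic <- strsplit(iso_row, "")[[1]]
  stopifnot(length(rc) == length(ic))
  structure(
    list(
      columns = data.frame(
        ref_pos = as.integer(ifelse(rc == "-", NA, cumsum(rc != "-"))),
        iso_pos = as.integer(ifelse(ic == "-", NA, cumsum(ic != "-"))),
        ref_aa = rc, iso_aa = ic, stringsAsFactors = FALSE
      ),
      score = NA_real_, ref_id = "ref", iso_id = "iso"
    ),
    class = "pair_alignment"
  )
}

# Independent TM-score oracle: direct numerical maximisation of the
# TM objective over rigid motions (many restarts: coarse Euler-angle grid
# plus random starts, each refined by Nelder-Mead and BFGS). Independent of
# the fragment-seeded Kabsch path used by the implementation.
tm_oracle <- function(ref, iso, aln, n_random = 40, seed = 99) {
  cols <- aln$columns
  pairs <- cols[!is.na(cols$ref_pos) & !is.na(cols$iso_pos), , drop = FALSE]
  rx <- atom_coords(ref, "CA")[pairs$ref_pos, , drop = FALSE]
  ix <- atom_coords(iso, "CA")[pairs$iso_pos, , drop = FALSE]
  d0 <- function(L) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8)
  euler <- function(th) {
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, 3)
    Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, 3)
    Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(par, L) {
    moved <- sweep(rx %*% t(euler(par[1:3])), 2, par[4:6], "+")
    d <- sqrt(rowSums((moved - ix)^2))
    -sum(1 / (1 + (d / d0(L))^2)) / L
  }
  one_norm <- function(L) {
    set.seed(seed)
    t_guess <- colMeans(ix) - colMeans(rx)
    starts <- list()
    for (a in seq(0, 1.5 * pi, by = pi / 2)) for (b in seq(0, 1.5 * pi, by = pi / 2)) {
      starts[[length(starts) + 1L]] <- c(a, b, 0, t_guess)
    }
    for (k in seq_len(n_random)) {
      starts[[length(starts) + 1L]] <- c(stats::runif(3, -pi, pi),
                                         t_guess + stats::rnorm(3, 0, 5))
    }
    best <- -Inf
    for (p0 in starts) {
      o <- stats::optim(p0, obj, L = L, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      o <- stats::optim(o$par, obj, L = L, method = "BFGS",
                        control = list(maxit = 500))
      best <- max(best, -o$value)
    }
    best
  }
  (one_norm(n_residues(ref)) + one_norm(n_residues(iso))) / 2
}

# Exhaustive global-alignment oracle for tiny sequences: enumerates every
# monotone alignment path with affine run-scored gaps under BLOSUM62 and
# returns the optimum score (end gaps penalized).
enumerate_alignment_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: (i, j, last_op) with ops M/I/D; gap opening charged on run start
  rec <- function(i, j, last, score) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, "M", score + B[av[i], bv[j]])
    }
    if (i <= length(av)) {
      pen <- gap_ext + if (last != "D") gap_open else 0
      rec(i + 1, j, "D", score - pen)
    }
    if (j <= length(bv)) {
      pen <- gap_ext + if (last != "I") gap_open else 0
      rec(i, j + 1, "I", score - pen)
    }
  }
  rec(1, 1, "start", 0)
  best
}

# Brute-force hypergeometric enrichment by enumeration of all draws
enumerate_hypergeometric <- function(k, M, n, N) {
  draws <- utils::combn(M, N)
  hits <- colSums(draws <= n)   # items 1..n carry the property
  c(pmf = mean(hits == k), tail = mean(hits >= k))
}
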