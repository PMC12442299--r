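# Synthetic generators for every non-structure input class: transcript
# pairs exhibiting each splicing type, MSAs with controlled identity,
# expression matrices with planted isoform switches, regression datasets,
# and homology hit tables. All generators are deterministic given a seed
# and return machine-readable ground truth.

#' Generate a reference/isoform transcript pair with a planted event
#'
#' Constructs exon chains whose classification under
#' [compare_exon_chains()] is exactly the requested event type, on either
#' strand ('-'-strand pairs are the mirror image of the '+' construction,
#' so the planted type is strand-invariant). Default geometry uses 99-nt
#' exons and 99-nt introns, so every default length change is a multiple
#' of 3.
#'
#' @param event_type one of `"ES"`, `"ADS"`, `"AAS"`, `"MXE"`, `"IR"`,
#'   `"AFE"`, `"ALE"`, `"MXE-AFE"`, `"MXE-ALE"`.
#' @param strand `"+"` or `"-"`.
#' @param exon_len exon length in nt (default 99).
#' @param shift boundary-shift size for ADS/AAS/AFE/ALE (default 51).
#' @param alt_len alternative-exon length for MXE variants (default 45).
#' @param gene_id,ref_id,iso_id identifiers.
#' @return list with `ref`, `iso` ([transcript_model()]s) and `truth`
#'   (`type`, `delta_nt`).
#' @export
make_transcript_pair <- function(event_type, strand = "+", exon_len = 99,
                                 shift = 51, alt_len = 45,
                                 gene_id = "gene1", ref_id = "ref_tx", iso_id = "iso_tx") {
  if (!event_type %in% .EVENT_TYPES) {
    stop("event_type must be one of: ", paste(.EVENT_TYPES, collapse = ", "))
  }
  l <- exon_len; g <- 99L  # intron length
  e1 <- c(1L, l)
  e2 <- c(l + g + 1L, 2L * l + g)
  e3 <- c(2L * (l + g) + 1L, 3L * l + 2L * g)
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  built <- switch(event_type,
    "ES" = list(ref = iv(e1, e2, e3), iso = iv(e1, e3), delta = -l),
    "ADS" = list(ref = iv(e1, e2), iso = iv(c(1L, l + shift), e2), delta = shift),
    "AAS" = list(ref = iv(e1, e2), iso = iv(e1, c(e2[1] - shift, e2[2])), delta = shift),
    "MXE" = {
      alt <- c(e2[2] + 11L, e2[2] + 10L + alt_len)
      if (alt[2] >= e3[1]) stop("alt_len too large for the intron")
      list(ref = iv(e1, e2, e3), iso = iv(e1, alt, e3), delta = alt_len - l)
    },
    "IR" = list(ref = iv(e1, e2), iso = iv(c(1L, e2[2])), delta = g),
    "AFE" = list(ref = iv(e1, e2), iso = iv(c(1L + shift, l), e2), delta = -shift),
    "ALE" = list(ref = iv(e1, e2), iso = iv(e1, c(e2[1], e2[2] - shift)), delta = -shift),
    "MXE-AFE" = {
      alt <- c(l + 11L, l + 10L + alt_len)
      if (alt[2] >= e2[1]) stop("alt_len too large for the intron")
      list(ref = iv(e1, e2), iso = iv(alt, e2), delta = alt_len - l)
    },
    "MXE-ALE" = {
      alt <- c(e2[2] + 11L, e2[2] + 10L + alt_len)
      list(ref = iv(e1, e2), iso = iv(e1, alt), delta = alt_len - l)
    }
  )
  ref_iv <- built$ref; iso_iv <- built$iso
  if (strand == "-") {
    # mirror the construction so transcription order is preserved
    M <- 1000L
    mirror <- function(d) data.frame(start = M - d$end, end = M - d$start)
    ref_iv <- mirror(ref_iv); iso_iv <- mirror(iso_iv)
  }
  list(
    ref = transcript_model(ref_id, gene_id, ref_iv, strand = strand, is_reference = TRUE),
    iso = transcript_model(iso_id, gene_id, iso_iv, strand = strand),
    truth = list(type = event_type, delta_nt = as.integer(built$delta))
  )
}

#' Generate an MSA with controlled identity to the query
#'
#' The query is a random sequence; each additional row mutates query
#' positions independently at rate `1 - identity_to_query` (substitutions
#' drawn from the 19 other residues).
#'
#' @param n_rows total rows including the query.
#' @param identity_to_query expected per-row identity fraction in \[0, 1\].
#' @param length query length (default 120).
#' @param seed integer seed.
#' @return an [msa()] object.
#' @export
make_msa <- function(n_rows, identity_to_query, length = 120, seed = 1L) {
  stopifnot(n_rows >= 1, identity_to_query >= 0, identity_to_query <= 1)
  set.seed(seed)
  alphabet <- unname(.AA_3TO1)
  query <- sample(alphabet, length, replace = TRUE)
  rows <- character(n_rows)
  rows[1] <- paste(query, collapse = "")
  if (n_rows > 1) {
    for (r in 2:n_rows) {
      mut <- stats::runif(length) > identity_to_query
      row <- query
      if (any(mut)) {
        row[mut] <- vapply(query[mut], function(a) sample(setdiff(alphabet, a), 1), "")
      }
      rows[r] <- paste(row, collapse = "")
    }
  }
  msa(rows, ids = c("query", if (n_rows > 1) paste0("hit", seq_len(n_rows - 1))))
}

#' Specify a planted isoform switch for expression simulation
#'
#' @param gene_id gene identifier.
#' @param isoform_ids character vector of isoform (transcript) identifiers.
#' @param cell_types character vector of cell type labels.
#' @param preferred_map named character vector mapping isoform id to its
#'   preferred cell type (distinct types per switching isoform); isoforms
#'   absent from the map have no planted preference.
#' @param effect mean log2-expression gap between preferred and other cell
#'   types (default 5).
#' @param noise_sd per-cell log2 noise standard deviation (default 0.5).
#' @param n_cells cells per cell type (scalar or per-type vector,
#'   default 100).
#' @param base_log2 baseline log2 mean count (default 5).
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param tissues optional character vector assigning one tissue per cell
#'   type (for the cross-tissue variant); defaults to a single tissue.
#' @return object of class `switch_spec`.
#' @export
switch_spec <- function(gene_id, isoform_ids, cell_types, preferred_map,
                        effect = 5, noise_sd = 0.5, n_cells = 100,
                        base_log2 = 5, dispersion = 0.1, tissues = NULL) {
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  pref_types <- unname(preferred_map)
  if (anyDuplicated(pref_types)) stop("preferred cell types must be distinct per isoform")
  if (!all(pref_types %in% cell_types)) stop("preferred_map types must be in cell_types")
  if (!all(names(preferred_map) %in% isoform_ids)) stop("preferred_map isoforms unknown")
  structure(
    list(gene_id = gene_id, isoform_ids = isoform_ids, cell_types = cell_types,
         preferred_map = preferred_map, effect = effect, noise_sd = noise_sd,
         n_cells = rep_len(n_cells, length(cell_types)), base_log2 = base_log2,
         dispersion = dispersion, tissues = tissues),
    class = "switch_spec"
  )
}

#' Simulate a cell-by-transcript count matrix with a planted switch
#'
#' Counts are drawn from a negative binomial whose per-cell mean is
#' `2^(base_log2 + effect * preferred + N(0, noise_sd))`: each isoform's
#' expression is elevated by `effect` (log2 units) in its preferred cell
#' type. Smart-seq2-style overdispersion is controlled by `dispersion`
#' (NB size = 1/dispersion).
#'
#' @param spec a [switch_spec()].
#' @param seed integer seed.
#' @return list with `counts` (cells x transcripts), `metadata`
#'   (data.frame: `cell`, `cell_type`, `tissue`), `lengths` (named nt
#'   lengths), `tx2gene` (named gene map), and `truth` (the spec).
#' @export
make_expression <- function(spec, seed = 1L) {
  set.seed(seed)
  n_types <- length(spec$cell_types)
  cell_type <- rep(spec$cell_types, spec$n_cells)
  n_cell <- length(cell_type)
  tissues <- spec$tissues %||% rep("tissue1", n_types)
  tissue <- rep(tissues, spec$n_cells)
  n_iso <- length(spec$isoform_ids)
  counts <- matrix(0, n_cell, n_iso,
                   dimnames = list(paste0("cell", seq_len(n_cell)), spec$isoform_ids))
  for (k in seq_len(n_iso)) {
    iso <- spec$isoform_ids[k]
    pref <- spec$preferred_map[iso]
    bump <- if (!is.na(pref)) spec$effect * (cell_type == pref) else 0
    log2mu <- spec$base_log2 + bump + stats::rnorm(n_cell, 0, spec$noise_sd)
    counts[, k] <- stats::rnbinom(n_cell, mu = 2^log2mu, size = 1 / spec$dispersion)
  }
  lengths <- stats::setNames(
    sample(seq(900, 3000, by = 300), n_iso, replace = TRUE), spec$isoform_ids)
  list(
    counts = counts,
    metadata = data.frame(cell = rownames(counts), cell_type = cell_type,
                          tissue = tissue, stringsAsFactors = FALSE),
    lengths = lengths,
    tx2gene = stats::setNames(rep(spec$gene_id, n_iso), spec$isoform_ids),
    truth = spec
  )
}

#' Simulate a linear regression dataset with known effects
#'
#' @param beta named numeric vector of true per-feature effects.
#' @param n number of rows (must exceed the feature count).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `design` (n x p matrix), `outcome` (numeric), and
#'   `truth` (beta).
#' @export
make_regression_dataset <- function(beta, n, noise_sd = 1, seed = 1L) {
  p <- length(beta)
  if (n <= p) stop("n must exceed the number of features")
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, names(beta) %||% paste0("x", seq_len(p))))
  y <- as.vector(X %*% beta + stats::rnorm(n, 0, noise_sd))
  list(design = X, outcome = y, truth = beta)
}

#' Simulate a homology hit table for GO scoring
#'
#' @param n_hits number of hits.
#' @param fraction_with_term fraction of hits annotated with the focal term
#'   `"GO:QUERY"`.
#' @param bitscore_range,identity_range,tm_range,string_range score ranges
#'   sampled uniformly.
#' @param seed integer seed.
#' @return data.frame with `hit_id`, `bitscore`, `identity`, `tm`,
#'   `string_score`, `has_term`, and a `go_terms` list column.
#' @export
make_hit_table <- function(n_hits, fraction_with_term,
                           bitscore_range = c(50, 500), identity_range = c(0.2, 1),
                           tm_range = c(0.3, 1), string_range = c(150, 999),
                           seed = 1L) {
  stopifnot(fraction_with_term >= 0, fraction_with_term <= 1)
  set.seed(seed)
  has_term <- stats::runif(n_hits) < fraction_with_term
  other_terms <- paste0("GO:", sprintf("%07d", sample(1e6, n_hits)))
  df <- data.frame(
    hit_id = paste0("hit", seq_len(n_hits)),
    bitscore = stats::runif(n_hits, bitscore_range[1], bitscore_range[2]),
    identity = stats::runif(n_hits, identity_range[1], identity_range[2]),
    tm = stats::runif(n_hits, tm_range[1], tm_range[2]),
    string_score = stats::runif(n_hits, string_range[1], string_range[2]),
    has_term = has_term,
    stringsAsFactors = FALSE
  )
  df$go_terms <- lapply(seq_len(n_hits), function(i) {
    c(if (has_term[i]) "GO:QUERY", other_terms[i])
  })
  df
}
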