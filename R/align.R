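# Sequence comparison between reference and isoform: Needleman-Wunsch
# global alignment (BLOSUM62, affine gaps), percent identity, splicing
# region labels, and effective MSA depth.

.AA_ALPHABET <- c(unname(.AA_3TO1), "X")

#' Globally align a reference and an isoform sequence
#'
#' Optimal Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (end gaps penalized). The dynamic program is delegated to
#' `Biostrings::pairwiseAlignment`, whose traceback is deterministic.
#'
#' @param ref_seq,iso_seq amino-acid strings (1-letter codes, `X` allowed).
#' @param gap_opening,gap_extension affine gap penalties (positive costs);
#'   defaults 10 and 0.5, the conventional values for this setup.
#' @param ref_id,iso_id identifiers carried into the result.
#' @return object of class `pair_alignment`: a list with `columns`
#'   (data.frame of `ref_pos`, `iso_pos` — `NA` for a gap — and the aligned
#'   characters), `score`, `ref_id`, `iso_id`.
#' @export
global_align <- function(ref_seq, iso_seq, gap_opening = 10, gap_extension = 0.5,
                         ref_id = "ref", iso_id = "iso") {
  for (s in c(ref_seq, iso_seq)) {
    if (nchar(s) == 0L) stop("empty sequence")
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(chars), .AA_ALPHABET)
    if (length(bad)) stop("illegal sequence character(s): ", paste(bad, collapse = ", "))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref_seq),
    subject = Biostrings::AAString(iso_seq),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global"
  )
  ref_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  iso_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- ifelse(ref_chars == "-", NA_integer_, cumsum(ref_chars != "-"))
  iso_pos <- ifelse(iso_chars == "-", NA_integer_, cumsum(iso_chars != "-"))
  columns <- data.frame(
    ref_pos = as.integer(ref_pos), iso_pos = as.integer(iso_pos),
    ref_aa = ref_chars, iso_aa = iso_chars, stringsAsFactors = FALSE
  )
  structure(
    list(columns = columns, score = Biostrings::score(aln),
         ref_id = ref_id, iso_id = iso_id),
    class = "pair_alignment"
  )
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %s vs %s: %d columns, score %.1f, identity %.3f\n",
              x$ref_id, x$iso_id, nrow(x$columns), x$score, sequence_identity(x)))
  invisible(x)
}

#' Swap the two sides of a pair alignment
#' @param aln a `pair_alignment`.
#' @return a `pair_alignment` with reference and isoform roles exchanged.
#' @export
swap_alignment <- function(aln) {
  cols <- aln$columns
  aln$columns <- data.frame(
    ref_pos = cols$iso_pos, iso_pos = cols$ref_pos,
    ref_aa = cols$iso_aa, iso_aa = cols$ref_aa, stringsAsFactors = FALSE
  )
  tmp <- aln$ref_id; aln$ref_id <- aln$iso_id; aln$iso_id <- tmp
  aln
}

#' Percent sequence identity of a pair alignment
#'
#' Identical-residue columns divided by the total alignment length; gap
#' columns count in the denominator.
#'
#' @param aln a `pair_alignment`.
#' @return fraction in \[0, 1\].
#' @export
sequence_identity <- function(aln) {
  cols <- aln$columns
  mean(!is.na(cols$ref_pos) & !is.na(cols$iso_pos) & cols$ref_aa == cols$iso_aa)
}

#' Label alternative-splicing regions from a pair alignment
#'
#' Each alignment column receives one of four column-level states:
#' * `missing` — reference residues absent from the isoform (gap on the
#'   isoform side) whose run is not adjacent to an isoform-only run;
#' * `reference_replaced` / `isoform_replaced` — adjacent paired indel runs,
#'   i.e. reference sequence substituted by new isoform sequence; a lone
#'   isoform-only run is also `isoform_replaced` (sequence unique to the
#'   isoform);
#' * `shared` — columns aligned in both sequences (matched or mismatched).
#'
#' Per-protein projections use the five-label vocabulary: on the reference
#' side `shared` becomes `reference_other`, on the isoform side
#' `isoform_other`.
#'
#' @param aln a `pair_alignment`.
#' @return data.frame of the alignment columns with an added `label` column.
#' @export
label_regions <- function(aln) {
  cols <- aln$columns
  n <- nrow(cols)
  state <- ifelse(!is.na(cols$ref_pos) & !is.na(cols$iso_pos), "shared",
                  ifelse(is.na(cols$iso_pos), "ref_only", "iso_only"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  label <- character(n)
  for (k in seq_along(runs$values)) {
    idx <- starts[k]:ends[k]
    label[idx] <- switch(runs$values[k],
      shared = "shared",
      iso_only = "isoform_replaced",
      ref_only = {
        prev_iso <- k > 1L && runs$values[k - 1L] == "iso_only"
        next_iso <- k < length(runs$values) && runs$values[k + 1L] == "iso_only"
        if (prev_iso || next_iso) "reference_replaced" else "missing"
      }
    )
  }
  out <- cols
  out$label <- label
  out
}

#' Per-residue region labels on one side of the pair
#'
#' @param labels output of [label_regions()].
#' @param side `"reference"` or `"isoform"`.
#' @return character vector, one label per residue of the chosen sequence,
#'   from \{missing, reference_replaced, reference_other\} (reference side)
#'   or \{isoform_replaced, isoform_other\} (isoform side).
#' @export
residue_region_labels <- function(labels, side = c("reference", "isoform")) {
  side <- match.arg(side)
  if (side == "reference") {
    keep <- labels[!is.na(labels$ref_pos), , drop = FALSE]
    keep <- keep[order(keep$ref_pos), , drop = FALSE]
    ifelse(keep$label == "shared", "reference_other", keep$label)
  } else {
    keep <- labels[!is.na(labels$iso_pos), , drop = FALSE]
    keep <- keep[order(keep$iso_pos), , drop = FALSE]
    ifelse(keep$label == "shared", "isoform_other", keep$label)
  }
}

.msa_char_matrix <- function(x) {
  do.call(rbind, strsplit(x$rows, ""))
}

#' Effective depth of a multiple sequence alignment
#'
#' Down-weights redundant rows: `Neff = sum_i 1 / (1 + n_i)` where `n_i`
#' counts the other rows whose pairwise identity with row `i` is at least
#' 0.8. Pairwise identity is computed over mutually non-gap columns and
#' normalised by the shorter ungapped length.
#'
#' @param x an [msa()] object.
#' @param identity_cutoff redundancy threshold (default 0.8).
#' @return numeric scalar in \[1, N\].
#' @export
effective_msa_depth <- function(x, identity_cutoff = 0.8) {
  if (!inherits(x, "msa")) stop("expected an msa object")
  m <- .msa_char_matrix(x)
  n <- nrow(m)
  if (n == 1L) return(1)
  nongap <- m != "-"
  len <- rowSums(nongap)
  similar <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- nongap[i, ] & nongap[j, ]
      matches <- sum(both & m[i, ] == m[j, ])
      id <- matches / min(len[i], len[j])
      similar[i, j] <- similar[j, i] <- id >= identity_cutoff
    }
  }
  sum(1 / (1 + rowSums(similar)))
}

#' Per-residue MSA coverage counts
#'
#' For every query column, the number of rows (query included) carrying a
#' non-gap character.
#'
#' @param x an [msa()] object.
#' @return integer vector of counts, one per query residue.
#' @export
per_residue_msa_count <- function(x) {
  if (!inherits(x, "msa")) stop("expected an msa object")
  m <- .msa_char_matrix(x)
  query_cols <- m[1, ] != "-"
  colSums(m[, query_cols, drop = FALSE] != "-")
}
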