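# PTM site mapping between isoform pairs and exposure-fate classification:
# unchanged, spliced out, spliced in, buried to exposed, exposed to buried.

#' Map a residue position across a pair alignment
#'
#' @param position 1-based residue index on the source sequence.
#' @param aln a `pair_alignment`.
#' @param direction `"ref_to_iso"` or `"iso_to_ref"`.
#' @return the partner position, or `NA` when the site falls in a gap
#'   column (unmapped).
#' @export
map_site <- function(position, aln, direction = c("ref_to_iso", "iso_to_ref")) {
  direction <- match.arg(direction)
  cols <- aln$columns
  if (direction == "ref_to_iso") {
    hit <- which(cols$ref_pos == position)
    if (length(hit) == 0L) stop("position ", position, " outside the reference sequence")
    cols$iso_pos[hit]
  } else {
    hit <- which(cols$iso_pos == position)
    if (length(hit) == 0L) stop("position ", position, " outside the isoform sequence")
    cols$ref_pos[hit]
  }
}

.exposure <- function(rsa, threshold) if (rsa > threshold) "exposed" else "buried"

#' Classify the splicing/exposure fate of a PTM site
#'
#' Reference-side sites whose alignment column is a gap on the isoform are
#' `spliced_out`; isoform-only sites that cannot be mapped back are
#' `spliced_in`. Mapped sites compare solvent exposure (RSA above the
#' threshold = exposed) between the two structures: `unchanged`,
#' `buried_to_exposed` or `exposed_to_buried`. Sites whose stated residue
#' letter disagrees with the sequence are flagged and excluded from
#' summaries; sites mapped onto a substituted residue are classified
#' normally but flagged `residue_changed`.
#'
#' @param site list or one-row data.frame with `protein_id`, `position`,
#'   `residue`, `ptm_type`.
#' @param ref_struct,iso_struct `protein_structure`s of the pair.
#' @param aln `pair_alignment` between their sequences.
#' @param ref_sasa,iso_sasa optional precomputed `sasa_result`s with RSA.
#' @param rsa_threshold exposure threshold (default 0.25).
#' @param side which protein the site is recorded on (`"reference"` or
#'   `"isoform"`).
#' @return one-row data.frame: `position`, `ptm_type`, `category`,
#'   `ref_pos`, `iso_pos`, `ref_sasa`, `iso_sasa`, `ref_rsa`, `iso_rsa`,
#'   `flagged`, `residue_changed`.
#' @export
classify_ptm <- function(site, ref_struct, iso_struct, aln,
                         ref_sasa = NULL, iso_sasa = NULL,
                         rsa_threshold = 0.25, side = c("reference", "isoform")) {
  side <- match.arg(side)
  site <- as.list(site)
  if (is.null(ref_sasa)) ref_sasa <- relative_accessibility(shrake_rupley_sasa(ref_struct))
  if (is.null(iso_sasa)) iso_sasa <- relative_accessibility(shrake_rupley_sasa(iso_struct))
  ref_seq <- strsplit(ref_sasa$sequence, "")[[1]]
  iso_seq <- strsplit(iso_sasa$sequence, "")[[1]]
  pos <- site$position
  row <- data.frame(
    position = pos, ptm_type = site$ptm_type, category = NA_character_,
    ref_pos = NA_integer_, iso_pos = NA_integer_,
    ref_sasa = NA_real_, iso_sasa = NA_real_,
    ref_rsa = NA_real_, iso_rsa = NA_real_,
    flagged = FALSE, residue_changed = FALSE, stringsAsFactors = FALSE
  )
  src_seq <- if (side == "reference") ref_seq else iso_seq
  if (pos < 1 || pos > length(src_seq)) {
    row$flagged <- TRUE
    warning("PTM position ", pos, " outside the ", side, " sequence; flagged")
    return(row)
  }
  if (!is.null(site$residue) && !is.na(site$residue) && src_seq[pos] != site$residue) {
    row$flagged <- TRUE
    warning("PTM residue mismatch at ", side, " position ", pos,
            " (table ", site$residue, ", sequence ", src_seq[pos], "); flagged")
    return(row)
  }
  if (side == "reference") {
    row$ref_pos <- pos
    partner <- map_site(pos, aln, "ref_to_iso")
    if (is.na(partner)) {
      row$category <- "spliced_out"
      row$ref_sasa <- unname(ref_sasa$residue_sasa[pos])
      row$ref_rsa <- unname(ref_sasa$residue_rsa[pos])
      return(row)
    }
    row$iso_pos <- partner
  } else {
    row$iso_pos <- pos
    partner <- map_site(pos, aln, "iso_to_ref")
    if (is.na(partner)) {
      row$category <- "spliced_in"
      row$iso_sasa <- unname(iso_sasa$residue_sasa[pos])
      row$iso_rsa <- unname(iso_sasa$residue_rsa[pos])
      return(row)
    }
    row$ref_pos <- partner
  }
  row$residue_changed <- ref_seq[row$ref_pos] != iso_seq[row$iso_pos]
  row$ref_sasa <- unname(ref_sasa$residue_sasa[row$ref_pos])
  row$iso_sasa <- unname(iso_sasa$residue_sasa[row$iso_pos])
  row$ref_rsa <- unname(ref_sasa$residue_rsa[row$ref_pos])
  row$iso_rsa <- unname(iso_sasa$residue_rsa[row$iso_pos])
  ref_state <- .exposure(row$ref_rsa, rsa_threshold)
  iso_state <- .exposure(row$iso_rsa, rsa_threshold)
  row$category <- if (ref_state == iso_state) "unchanged"
    else if (ref_state == "buried") "buried_to_exposed"
    else "exposed_to_buried"
  row
}

.PTM_CATEGORIES <- c("unchanged", "spliced_out", "spliced_in",
                     "buried_to_exposed", "exposed_to_buried")

#' Tabulate PTM classifications by category and modification type
#'
#' @param classifications data.frame of rows from [classify_ptm()].
#' @return contingency table (category x ptm_type) over unflagged records.
#' @export
ptm_summary <- function(classifications) {
  keep <- classifications[!classifications$flagged, , drop = FALSE]
  table(
    category = factor(keep$category, levels = .PTM_CATEGORIES),
    ptm_type = factor(keep$ptm_type, levels = .PTM_TYPES)
  )
}
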