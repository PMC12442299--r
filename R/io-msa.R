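# Multiple sequence alignments, consumed as aligned FASTA or A3M.

#' Construct an MSA object
#'
#' Rows are aligned sequences over the query coordinate system: every row has
#' the same length as the first row, the query (which carries no applied
#' insertions).
#'
#' @param rows character vector of aligned rows (gaps `-`); first row is the
#'   query.
#' @param ids optional row identifiers.
#' @return object of class `msa`.
#' @export
msa <- function(rows, ids = NULL) {
  if (length(rows) == 0L) stop("empty MSA")
  if (length(unique(nchar(rows))) != 1L) {
    stop("MSA rows have unequal mapped lengths")
  }
  structure(
    list(rows = toupper(rows), ids = ids %||% paste0("seq", seq_along(rows))),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Read an aligned FASTA or A3M file into an MSA
#'
#' The first record is the query. A3M lowercase letters denote insertions
#' relative to the query and are removed, so every row maps onto the query
#' coordinate system.
#'
#' @param path path to aligned FASTA / A3M.
#' @return an [msa()] object.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  if (length(seqs) == 0L) stop("empty MSA file: ", path)
  rows <- as.character(seqs)
  # strip A3M insertion columns (lowercase) relative to the query
  rows <- gsub("[a-z.]", "", rows)
  msa(rows, ids = names(seqs))
}

#' Write an MSA as aligned FASTA
#' @param x an [msa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  writeLines(as.vector(rbind(paste0(">", x$ids), x$rows)), path)
  invisible(path)
}
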