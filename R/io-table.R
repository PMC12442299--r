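# Typed TSV readers for the tabular inputs: PTM sites, homology hits,
# PPI partners, count matrices and cell metadata.

#' Read a typed TSV table
#'
#' Reads a tab-separated file with a header and validates it against a
#' declared schema. Required columns are coerced to their declared types;
#' unknown extra columns are preserved as-is.
#'
#' @param path path to a TSV file with a header row.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"numeric"`, `"logical"`).
#' @return data.frame of typed records (0 rows for a header-only file).
#' @export
read_table_schema <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in names(schema)) {
    target <- schema[[col]]
    val <- df[[col]]
    coerced <- suppressWarnings(switch(target,
      character = as.character(val),
      integer = as.integer(val),
      numeric = as.numeric(val),
      logical = as.logical(val),
      stop("unknown schema type: ", target)
    ))
    if (nrow(df) > 0 && anyNA(coerced) && !anyNA(val)) {
      stop("column '", col, "' cannot be coerced to ", target)
    }
    df[[col]] <- coerced
  }
  df
}

.PTM_TYPES <- c("phosphorylation", "ubiquitination", "acetylation",
                "methylation", "O-GalNAc", "O-GlcNAc", "sumoylation")

#' Read a PTM site table
#'
#' Expects columns `protein_id`, `position` (1-based residue index),
#' `residue` (1-letter code) and `ptm_type` (one of the seven supported
#' modification types: phosphorylation, ubiquitination, acetylation,
#' methylation, O-GalNAc, O-GlcNAc, sumoylation).
#'
#' @param path path to a TSV file.
#' @return data.frame of PTM records.
#' @export
read_ptm_table <- function(path) {
  df <- read_table_schema(path, c(
    protein_id = "character", position = "integer",
    residue = "character", ptm_type = "character"
  ))
  if (nrow(df)) {
    if (any(df$position < 1L)) stop("PTM positions must be >= 1")
    bad <- setdiff(unique(df$ptm_type), .PTM_TYPES)
    if (length(bad)) {
      stop("unknown ptm_type value(s): ", paste(bad, collapse = ", "))
    }
  }
  df
}

#' Read a homology hit table
#'
#' Expects columns `hit_id`, `bitscore`, `identity` and `go_terms`
#' (comma-separated GO identifiers; empty for none). An optional `tm` column
#' carries TM-scores for structure-channel hits.
#'
#' @param path path to a TSV file.
#' @return data.frame with `go_terms` parsed into a list column.
#' @export
read_hit_table <- function(path) {
  df <- read_table_schema(path, c(
    hit_id = "character", bitscore = "numeric", identity = "numeric",
    go_terms = "character"
  ))
  df$go_terms <- strsplit(df$go_terms, ",", fixed = TRUE)
  df$go_terms <- lapply(df$go_terms, function(x) x[nzchar(x)])
  df
}
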