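# PDB input/output. Parsing and fixed-column formatting are delegated to
# bio3d; this layer validates the model and converts to protein_structure.

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records from a PDB file into a [protein_structure()]. Only
#' single-chain models are supported: when several chains are present the
#' first chain is kept with a warning. Alternate locations beyond the first
#' are dropped. The B-factor column is preserved per atom (it carries pLDDT
#' for AlphaFold-style models).
#'
#' @param path path to a PDB file containing ATOM records.
#' @param id identifier for the structure; defaults to the file name.
#' @param plddt logical; validate B-factors as pLDDT in \[0, 100\].
#' @return a `protein_structure`.
#' @export
read_pdb <- function(path, id = NULL, plddt = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("malformed PDB file '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM records in ", path)
  chains <- unique(at$chain)
  if (length(chains) > 1L) {
    warning("multi-chain model in ", path, ": keeping first chain '", chains[1], "'")
    at <- at[at$chain == chains[1], , drop = FALSE]
  }
  # keep the first alternate location only
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    first_alt <- unique(alt[alt != ""])[1]
    at <- at[alt == "" | alt == first_alt, , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1, 1)
  atoms <- data.frame(
    resno = at$resno,
    resid = at$resid,
    elety = at$elety,
    element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    b = at$b,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  protein_structure(atoms, id = id %||% basename(path), plddt = plddt)
}

#' Write a protein structure to a PDB file
#'
#' Emits fixed-column ATOM records (coordinates at 3 decimals, B-factor at
#' 2 decimals) via bio3d's writer.
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (any(nchar(at$resid) != 3L)) {
    stop("residue names must be 3 characters to write PDB: ",
         paste(unique(at$resid[nchar(at$resid) != 3L]), collapse = ", "))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(abs(xyz) > 9999.999)) {
    stop("coordinate overflow: |coordinate| > 9999.999 cannot be written in PDB fixed columns")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", nrow(at)),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$elety,
    chain = rep("A", nrow(at)),
    o = at$o,
    b = at$b,
    elesy = at$element
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
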