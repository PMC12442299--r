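# Transcript models and GTF input. GTF parsing is delegated to rtracklayer.

#' Construct a transcript model
#'
#' An ordered chain of exon intervals on a genome, 5' to 3' in transcript
#' orientation (descending genomic start on the '-' strand). Coordinates are
#' 1-based inclusive.
#'
#' @param transcript_id,gene_id identifiers.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive nt).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param is_reference logical flag marking the gene's reference transcript.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, exons, chrom = "chr1",
                             strand = "+", is_reference = FALSE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$start > exons$end)) stop("exon start > end")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, exons = exons,
         chrom = chrom, strand = strand, is_reference = is_reference),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s: %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), sum(x$exons$end - x$exons$start + 1L)))
  invisible(x)
}

#' Total exonic length of a transcript (nt)
#' @param tx a `transcript_model`.
#' @return integer.
#' @export
transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

#' Read transcript models from a GTF file
#'
#' Imports `exon` features and assembles one [transcript_model()] per
#' `transcript_id`, with exons ordered 5' to 3' in transcript orientation.
#' Non-exon features (gene, CDS, ...) are ignored.
#'
#' @param path path to a GTF file.
#' @return named list of `transcript_model` objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  is_exon <- !is.na(meta$type) & as.character(meta$type) == "exon"
  gr <- gr[is_exon]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("no exon features in ", path)
  if (is.null(meta$transcript_id) || anyNA(meta$transcript_id)) {
    stop("exon feature(s) missing transcript_id attribute in ", path)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(meta$transcript_id),
    gene_id = if (!is.null(meta$gene_id)) as.character(meta$gene_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$strand)) != 1L) {
      stop("mixed strands within transcript ", d$transcript_id[1])
    }
    if (length(unique(d$chrom)) != 1L) {
      stop("mixed chromosomes within transcript ", d$transcript_id[1])
    }
    transcript_model(
      transcript_id = d$transcript_id[1],
      gene_id = d$gene_id[1],
      exons = d[, c("start", "end")],
      chrom = d$chrom[1],
      strand = d$strand[1]
    )
  })
  out
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes; the companion reader [read_gtf()] round-trips the exon sets.
#'
#' @param transcripts list of `transcript_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    sprintf(
      "%s\tisoformetrics\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      tx$chrom, ex$start, ex$end, tx$strand, tx$gene_id, tx$transcript_id
    )
  }))
  writeLines(lines, path)
  invisible(path)
}
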