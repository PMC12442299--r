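# Isoform-switch detection from cell-by-transcript expression: TPM
# normalisation, gene aggregation, per-isoform tests across cell types with
# Bonferroni correction, switch filtering, and the cross-tissue variant.

#' Construct an expression matrix container
#'
#' @param counts non-negative cells x transcripts matrix (rownames = cells,
#'   colnames = transcript ids).
#' @param lengths named transcript lengths (nt, > 0).
#' @param tx2gene named character vector mapping transcript id to gene id.
#' @param metadata data.frame with columns `cell`, `cell_type` and
#'   optionally `tissue`, one row per cell.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, lengths, tx2gene, metadata) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  txs <- colnames(counts)
  if (is.null(txs)) stop("counts must have transcript column names")
  if (!all(txs %in% names(lengths))) stop("lengths missing for some transcripts")
  if (any(lengths[txs] <= 0)) stop("transcript lengths must be > 0")
  if (!all(txs %in% names(tx2gene))) stop("tx2gene missing for some transcripts")
  if (nrow(metadata) != nrow(counts)) stop("metadata rows must match cells")
  if (is.null(metadata$tissue)) metadata$tissue <- "tissue1"
  structure(
    list(counts = counts, lengths = lengths[txs], tx2gene = tx2gene[txs],
         metadata = metadata),
    class = "expression_matrix"
  )
}

#' Transcripts-per-million normalisation
#'
#' Per cell: each transcript's count is divided by its length, and the
#' resulting rates are rescaled to sum to one million. Cells with zero
#' total count yield an all-zero row.
#'
#' @param x an `expression_matrix` (or a counts matrix plus `lengths`).
#' @param lengths transcript lengths when `x` is a bare matrix.
#' @return TPM matrix of the same shape.
#' @export
tpm_normalize <- function(x, lengths = NULL) {
  if (inherits(x, "expression_matrix")) {
    counts <- x$counts; lengths <- x$lengths
  } else {
    counts <- as.matrix(x)
    if (is.null(lengths)) stop("lengths required for a bare counts matrix")
  }
  rate <- sweep(counts, 2, lengths[colnames(counts)], "/")
  tot <- rowSums(rate)
  tpm <- rate / ifelse(tot == 0, 1, tot) * 1e6
  tpm
}

#' Log-transform an expression matrix
#' @param tpm numeric matrix (TPM scale).
#' @return `log2(tpm + 1)`.
#' @export
log_transform <- function(tpm) log2(tpm + 1)

#' Aggregate transcript expression to gene level
#'
#' @param x an `expression_matrix`.
#' @param values optional matrix (e.g. TPM) to aggregate instead of counts.
#' @return cells x genes matrix of column sums by gene.
#' @export
aggregate_gene <- function(x, values = NULL) {
  m <- values %||% x$counts
  genes <- x$tx2gene[colnames(m)]
  out <- sapply(unique(genes), function(g) {
    rowSums(m[, genes == g, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(unique(genes)),
                                       dimnames = list(rownames(m), unique(genes)))
  out
}

# per-isoform test of log-expression across groups: Welch t for 2 groups,
# one-way ANOVA otherwise
.group_test <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) return(NA_real_)
  if (stats::sd(values) == 0) return(1)
  if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    tryCatch(stats::t.test(sp[[1]], sp[[2]])$p.value, error = function(e) 1)
  } else {
    stats::anova(stats::lm(values ~ groups))[["Pr(>F)"]][1]
  }
}

#' Test one gene for an isoform switch across cell types
#'
#' For each isoform of the gene, tests whether its log expression differs
#' across eligible cell types (Welch t-test for two groups, one-way ANOVA
#' otherwise). Raw p-values are Bonferroni-corrected with the supplied
#' family size (all isoform tests in the run). An isoform's preferred cell
#' type is the one with the highest mean log expression; its fold change is
#' the preferred-type mean over the other-types mean on the TPM scale. The
#' gene is flagged as switching when at least two isoforms are significant
#' with distinct preferred cell types (isoforms upregulated in the same
#' cell type do not count twice).
#'
#' @param gene gene id.
#' @param x an `expression_matrix`.
#' @param log_tpm precomputed `log_transform(tpm_normalize(x))` (computed
#'   when absent).
#' @param group_by metadata column used as the grouping factor (default
#'   `"cell_type"`; set `"tissue"` for the cross-tissue variant).
#' @param cells optional logical/index vector restricting the cells used.
#' @param min_cells groups with fewer cells than this are excluded before
#'   testing (default 30).
#' @param bonferroni_n family size for the correction (default: number of
#'   isoform tests in this gene).
#' @param alpha significance threshold on corrected p-values (default
#'   0.05).
#' @return object of class `switch_result`: list with `gene_id`,
#'   `isoforms` (data.frame: `isoform`, `p_raw`, `p_corrected`,
#'   `preferred`, `fold_change`, `significant`), and `switch` flag;
#'   `NULL` when fewer than two eligible groups or isoforms exist.
#' @export
switch_test <- function(gene, x, log_tpm = NULL, group_by = "cell_type",
                        cells = NULL, min_cells = 30, bonferroni_n = NULL,
                        alpha = 0.05) {
  isoforms <- names(x$tx2gene)[x$tx2gene == gene]
  if (length(isoforms) < 2) return(NULL)
  if (is.null(log_tpm)) log_tpm <- log_transform(tpm_normalize(x))
  keep <- rep(TRUE, nrow(log_tpm))
  if (!is.null(cells)) {
    keep <- rep(FALSE, nrow(log_tpm))
    keep[cells] <- TRUE
  }
  groups <- x$metadata[[group_by]][keep]
  tab <- table(groups)
  eligible <- names(tab)[tab >= min_cells]
  if (length(eligible) < 2) return(NULL)
  sel <- keep
  sel[keep] <- groups %in% eligible
  groups <- x$metadata[[group_by]][sel]
  m <- log_tpm[sel, isoforms, drop = FALSE]
  tpm_m <- (2^m) - 1
  res <- lapply(isoforms, function(iso) {
    v <- m[, iso]
    p <- .group_test(v, groups)
    means <- tapply(v, groups, mean)
    pref <- names(means)[which.max(means)]
    in_pref <- groups == pref
    fc <- mean(tpm_m[in_pref, iso]) / max(mean(tpm_m[!in_pref, iso]), .Machine$double.eps)
    data.frame(isoform = iso, p_raw = p, preferred = pref, fold_change = fc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  n_tests <- bonferroni_n %||% nrow(res)
  res$p_corrected <- pmin(1, res$p_raw * n_tests)
  res$significant <- !is.na(res$p_corrected) & res$p_corrected < alpha
  sig <- res[res$significant, , drop = FALSE]
  # isoforms preferring the same cell type are excluded from the switch call
  distinct_pref <- unique(sig$preferred)
  switch_flag <- length(distinct_pref) >= 2
  structure(
    list(gene_id = gene, isoforms = res, switch = switch_flag,
         group_by = group_by),
    class = "switch_result"
  )
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("<switch_result> %s: switch = %s\n", x$gene_id, x$switch))
  print(x$isoforms, row.names = FALSE)
  invisible(x)
}

#' Run the switch test over all genes and filter/rank results
#'
#' Groups below `min_cells` cells are excluded before testing; the
#' Bonferroni family is the total number of isoform tests across genes.
#' Results are returned sorted by the gene's maximum isoform fold change,
#' descending.
#'
#' @param x an `expression_matrix`.
#' @param group_by grouping metadata column (default `"cell_type"`).
#' @param cells optional cell subset.
#' @param min_cells minimum group size (default 30).
#' @param alpha corrected-p threshold (default 0.05).
#' @return list with `results` (named list of `switch_result`s) and
#'   `summary` (data.frame ranked by fold change with the switch flags).
#' @export
filter_switches <- function(x, group_by = "cell_type", cells = NULL,
                            min_cells = 30, alpha = 0.05) {
  genes <- unique(x$tx2gene)
  log_tpm <- log_transform(tpm_normalize(x))
  # first pass uncorrected to count the test family
  prelim <- lapply(genes, function(g) {
    switch_test(g, x, log_tpm = log_tpm, group_by = group_by, cells = cells,
                min_cells = min_cells, bonferroni_n = 1, alpha = alpha)
  })
  names(prelim) <- genes
  n_tests <- sum(vapply(prelim, function(r) if (is.null(r)) 0L else nrow(r$isoforms), integer(1)))
  results <- lapply(genes, function(g) {
    switch_test(g, x, log_tpm = log_tpm, group_by = group_by, cells = cells,
                min_cells = min_cells, bonferroni_n = max(1L, n_tests), alpha = alpha)
  })
  names(results) <- genes
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) {
    return(list(results = results,
                summary = data.frame(gene_id = character(0), switch = logical(0),
                                     max_fold_change = numeric(0))))
  }
  summary <- data.frame(
    gene_id = vapply(results, `[[`, "", "gene_id"),
    switch = vapply(results, `[[`, TRUE, "switch"),
    max_fold_change = vapply(results, function(r) max(r$isoforms$fold_change), numeric(1)),
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-summary$max_fold_change), , drop = FALSE]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Cross-tissue isoform switch within one cell type
#'
#' Identical machinery to [switch_test()] with tissue as the grouping
#' factor, restricted to cells of one cell type.
#'
#' @param gene gene id.
#' @param x an `expression_matrix` whose metadata has a `tissue` column.
#' @param cell_type the cell type to restrict to.
#' @param ... further arguments passed to [switch_test()].
#' @return a `switch_result`, or `NULL` when fewer than two eligible
#'   tissues remain.
#' @export
cross_tissue_switch <- function(gene, x, cell_type, ...) {
  cells <- which(x$metadata$cell_type == cell_type)
  if (length(cells) == 0L) return(NULL)
  switch_test(gene, x, group_by = "tissue", cells = cells, ...)
}
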