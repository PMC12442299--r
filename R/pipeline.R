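# End-to-end orchestration over a manifest of reference/isoform pairs:
# quality filtering, per-pair alignment + events + metrics + PTM fates,
# cohort-level outlier tables and per-residue-effect regressions, with a
# machine-readable run log.

#' Assemble a run configuration
#'
#' Central container for every tunable threshold, with the package
#' defaults.
#'
#' @param rsa_threshold RSA surface/exposure threshold (default 0.25).
#' @param max_length pairs with either sequence at or above this length
#'   are dropped (default 600 residues).
#' @param min_mean_plddt structures at or below this mean pLDDT are
#'   dropped (default 70; strict inequality, so exactly 70 is dropped).
#' @param idr_window,idr_cutoff,idr_min_len disorder detection parameters.
#' @param helix_min_run isolated-helix minimum run (default 21 residues).
#' @param confidence_threshold GO consensus confidence cutoff (default
#'   0.6).
#' @param min_cells switch-test minimum group size (default 30).
#' @param strict drop pairs containing IDRs or isolated helices (default
#'   FALSE).
#' @param gap_opening,gap_extension alignment gap penalties.
#' @param seed integer seed recorded in the run log.
#' @return object of class `run_config`.
#' @export
run_config <- function(rsa_threshold = 0.25, max_length = 600,
                       min_mean_plddt = 70, idr_window = 25, idr_cutoff = 70,
                       idr_min_len = 20, helix_min_run = 21,
                       confidence_threshold = 0.6, min_cells = 30,
                       strict = FALSE, gap_opening = 10, gap_extension = 0.5,
                       seed = 1L) {
  stopifnot(rsa_threshold >= 0, rsa_threshold <= 1, max_length > 0,
            min_mean_plddt >= 0, min_mean_plddt <= 100,
            idr_window >= 1, idr_cutoff >= 0, idr_cutoff <= 100,
            idr_min_len >= 1, helix_min_run >= 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            min_cells >= 1)
  structure(as.list(environment()), class = "run_config")
}

.load_structure <- function(s) {
  if (inherits(s, "protein_structure")) s else read_pdb(s)
}

#' Filter a pair manifest by length and prediction quality
#'
#' Drops pairs in which either sequence has `max_length` or more residues,
#' or either structure's mean pLDDT is at or below `min_mean_plddt`
#' (pairwise gating: both members must pass). With `config$strict`, pairs
#' containing an IDR or an isolated helix in either structure are also
#' dropped.
#'
#' @param pairs list of pair entries; each a list with `gene_id`,
#'   `ref_id`, `iso_id`, `ref`, `iso` (`protein_structure`s or PDB paths)
#'   and optionally `ref_tx`, `iso_tx` (`transcript_model`s) and
#'   `ptm_sites`.
#' @param config a [run_config()].
#' @return the filtered list, with a `filter_log` attribute naming dropped
#'   pairs and reasons.
#' @export
apply_filters <- function(pairs, config = run_config()) {
  keep <- logical(length(pairs))
  log <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    ref <- .load_structure(p$ref); iso <- .load_structure(p$iso)
    reason <- NULL
    if (n_residues(ref) >= config$max_length || n_residues(iso) >= config$max_length) {
      reason <- "length"
    } else if (mean_plddt(ref) <= config$min_mean_plddt ||
               mean_plddt(iso) <= config$min_mean_plddt) {
      reason <- "low_plddt"
    } else if (isTRUE(config$strict)) {
      has_idr <- idr_fraction(ref, config$idr_window, config$idr_cutoff, config$idr_min_len) > 0 ||
        idr_fraction(iso, config$idr_window, config$idr_cutoff, config$idr_min_len) > 0
      has_helix <- nrow(isolated_helices(ref, min_run = config$helix_min_run,
                                         rsa_threshold = config$rsa_threshold)) > 0 ||
        nrow(isolated_helices(iso, min_run = config$helix_min_run,
                              rsa_threshold = config$rsa_threshold)) > 0
      if (has_idr) reason <- "idr" else if (has_helix) reason <- "isolated_helix"
    }
    keep[i] <- is.null(reason)
    if (!is.null(reason)) log[[length(log) + 1L]] <- list(iso_id = p$iso_id, reason = reason)
  }
  out <- pairs[keep]
  attr(out, "filter_log") <- log
  out
}

#' Run the full pairwise analysis pipeline
#'
#' For each manifest pair: global alignment and region labels, splicing
#' events (when transcripts are supplied), per-structure metric reports,
#' TM-score and pairwise differences, and PTM fate classification (when
#' sites are supplied). Cohort level: outlier tables for surface charge
#' and radius-of-gyration differences, the most frequent event types among
#' outliers, and per-residue-effect regressions for each outcome with
#' enough data. A failing pair is isolated, logged, and the run continues.
#'
#' @param pairs list of pair entries (see [apply_filters()]).
#' @param config a [run_config()].
#' @param filter apply [apply_filters()] first (default TRUE).
#' @param outcomes regression outcomes to fit (default
#'   `c("tm", "charge", "rg")`).
#' @return object of class `pipeline_result`: list with `pair_table`
#'   (data.frame of per-pair metrics), `pair_details`, `outliers`,
#'   `top_events`, `effects`, `errors`, and `log` (config hash, seed,
#'   counts).
#' @export
run_pipeline <- function(pairs, config = run_config(), filter = TRUE,
                         outcomes = c("tm", "charge", "rg")) {
  set.seed(config$seed)
  if (filter) pairs <- apply_filters(pairs, config)
  details <- list()
  errors <- list()
  for (p in pairs) {
    res <- tryCatch({
      ref <- .load_structure(p$ref); iso <- .load_structure(p$iso)
      aln <- global_align(structure_sequence(ref), structure_sequence(iso),
                          gap_opening = config$gap_opening,
                          gap_extension = config$gap_extension,
                          ref_id = p$ref_id, iso_id = p$iso_id)
      events <- if (!is.null(p$ref_tx) && !is.null(p$iso_tx)) {
        compare_exon_chains(p$ref_tx, p$iso_tx)
      }
      ref_m <- structure_metrics(ref, rsa_threshold = config$rsa_threshold,
                                 idr_window = config$idr_window,
                                 idr_cutoff = config$idr_cutoff,
                                 idr_min_len = config$idr_min_len)
      iso_m <- structure_metrics(iso, rsa_threshold = config$rsa_threshold,
                                 idr_window = config$idr_window,
                                 idr_cutoff = config$idr_cutoff,
                                 idr_min_len = config$idr_min_len)
      tm <- tm_score(ref, iso, aln)
      pr <- pair_report(ref_m, iso_m, tm)
      ptm <- NULL
      if (!is.null(p$ptm_sites) && nrow(p$ptm_sites) > 0) {
        rows <- lapply(seq_len(nrow(p$ptm_sites)), function(j) {
          s <- p$ptm_sites[j, , drop = FALSE]
          classify_ptm(s, ref, iso, aln,
                       ref_sasa = ref_m$sasa, iso_sasa = iso_m$sasa,
                       rsa_threshold = config$rsa_threshold,
                       side = s$side %||% "reference")
        })
        ptm <- do.call(rbind, rows)
      }
      list(gene_id = p$gene_id, ref_id = p$ref_id, iso_id = p$iso_id,
           alignment = aln, labels = label_regions(aln), events = events,
           ref_metrics = ref_m, iso_metrics = iso_m, report = pr, ptm = ptm,
           identity = sequence_identity(aln))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(iso_id = p$iso_id,
                                            message = conditionMessage(res))
    } else {
      details[[res$iso_id]] <- res
    }
  }
  pair_table <- do.call(rbind, lapply(details, function(d) {
    data.frame(
      gene_id = d$gene_id, ref_id = d$ref_id, iso_id = d$iso_id,
      identity = d$identity, tm_score = d$report$tm_score,
      d_helix = unname(d$report$d_ss_percent["H"]),
      d_sheet = unname(d$report$d_ss_percent["E"]),
      d_loop = unname(d$report$d_ss_percent["L"]),
      d_charge = d$report$d_surface_charge,
      d_rg = d$report$d_rg, d_idr = d$report$d_idr_fraction,
      d_plddt = d$report$d_plddt,
      n_events = if (is.null(d$events)) NA_integer_ else length(d$events$events),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pair_table) <- NULL
  outliers <- list(); top_events <- list(); effects <- NULL
  if (!is.null(pair_table) && nrow(pair_table) >= 4) {
    event_sets <- lapply(details, `[[`, "events")
    for (metric in c("d_charge", "d_rg")) {
      v <- pair_table[[metric]]
      if (stats::sd(v) > 0) {
        cls <- stats::setNames(classify_outliers(v), pair_table$iso_id)
        outliers[[metric]] <- data.frame(iso_id = pair_table$iso_id, value = v,
                                         class = unname(cls), stringsAsFactors = FALSE)
        if (!all(vapply(event_sets, is.null, logical(1)))) {
          top_events[[metric]] <- top_event_types(cls, event_sets)
        }
      }
    }
    has_events <- !vapply(event_sets, is.null, logical(1))
    if (sum(has_events) > 12) {
      reports <- lapply(details[has_events], `[[`, "report")
      esets <- event_sets[has_events]
      tables <- list()
      for (oc in outcomes) {
        tab <- tryCatch({
          design <- build_design(reports, esets, outcome = oc)
          fit_ols(design)
        }, error = function(e) NULL)
        if (!is.null(tab)) tables[[oc]] <- tab
      }
      if (length(tables)) effects <- effect_summary(tables)
    }
  }
  cfg_json <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  structure(
    list(pair_table = pair_table, pair_details = details, outliers = outliers,
         top_events = top_events, effects = effects, errors = errors,
         log = list(config_hash = cfg_hash, seed = config$seed,
                    n_pairs_in = length(pairs), n_pairs_done = length(details),
                    n_errors = length(errors))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d/%d pair(s) analysed, %d error(s)\n",
              x$log$n_pairs_done, x$log$n_pairs_in, x$log$n_errors))
  invisible(x)
}
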