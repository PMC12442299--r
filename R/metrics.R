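# Per-structure metric reports, pair reports, pLDDT quality classes,
# disorder detection from window-averaged pLDDT, isolated-helix detection,
# and the quartile outlier rule.

#' pLDDT quality class of a structure
#'
#' Bands follow the usual AlphaFold convention with strict upper
#' inequalities: mean pLDDT > 90 is `high`, (70, 90\] `confident`,
#' (50, 70\] `low`, <= 50 `very_low` (boundary values fall in the lower
#' class).
#'
#' @param mean_plddt numeric mean pLDDT in \[0, 100\].
#' @return character scalar.
#' @export
quality_class <- function(mean_plddt) {
  stopifnot(is.finite(mean_plddt))
  if (mean_plddt > 90) "high"
  else if (mean_plddt > 70) "confident"
  else if (mean_plddt > 50) "low"
  else "very_low"
}

#' Intrinsically disordered regions from window-averaged pLDDT
#'
#' A residue is disordered when the mean pLDDT over a centered window falls
#' below the cutoff (the window is truncated at the chain ends); maximal
#' disordered runs of at least `min_len` residues are reported as IDRs.
#'
#' @param structure a `protein_structure` with pLDDT in the B-factor column.
#' @param window window width in residues (default 25).
#' @param cutoff pLDDT cutoff (default 70).
#' @param min_len minimum run length reported (default 20).
#' @return data.frame with columns `start`, `end` (residue indices).
#' @export
idr_regions <- function(structure, window = 25, cutoff = 70, min_len = 20) {
  p <- residue_plddt(structure)
  n <- length(p)
  half <- window %/% 2
  wmean <- vapply(seq_len(n), function(i) {
    mean(p[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  dis <- wmean < cutoff
  r <- rle(dis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Fraction of the chain inside IDRs
#'
#' @inheritParams idr_regions
#' @return fraction in \[0, 1\]: disordered residues (in reported runs)
#'   over chain length.
#' @export
idr_fraction <- function(structure, window = 25, cutoff = 70, min_len = 20) {
  regs <- idr_regions(structure, window, cutoff, min_len)
  if (nrow(regs) == 0L) return(0)
  sum(regs$end - regs$start + 1L) / n_residues(structure)
}

#' Isolated helices: long exposed helical runs
#'
#' Maximal runs of residues that are simultaneously helical and surface
#' (RSA above the exposure threshold), longer than 20 residues. Such runs
#' are a known artifact of predicted structures and are used as a filtering
#' criterion.
#'
#' @param structure a `protein_structure`.
#' @param sasa optional precomputed `sasa_result` (RSA added if missing).
#' @param states optional precomputed secondary-structure states.
#' @param min_run minimum reported run length (default 21, i.e. more than
#'   20 residues).
#' @param rsa_threshold surface threshold on RSA (default 0.25).
#' @return data.frame with columns `start`, `end` (residue indices).
#' @export
isolated_helices <- function(structure, sasa = NULL, states = NULL,
                             min_run = 21, rsa_threshold = 0.25) {
  if (is.null(states)) states <- secondary_structure(structure)
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(structure)
  if (is.null(sasa$residue_rsa)) sasa <- relative_accessibility(sasa)
  exposed <- sasa$residue_rsa > rsa_threshold
  flag <- states == "H" & exposed
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

#' Compute the per-structure metric report
#'
#' Bundles every per-structure metric used by the pairwise comparison:
#' mean pLDDT and quality class, three-state secondary-structure
#' percentages, formal surface charge, radius of gyration, IDR fraction,
#' isolated-helix intervals and chain length.
#'
#' @param structure a `protein_structure`.
#' @param rsa_threshold RSA surface threshold (default 0.25).
#' @param idr_window,idr_cutoff,idr_min_len IDR detection parameters.
#' @return object of class `metric_report` (a list).
#' @export
structure_metrics <- function(structure, rsa_threshold = 0.25,
                              idr_window = 25, idr_cutoff = 70, idr_min_len = 20) {
  sasa <- relative_accessibility(shrake_rupley_sasa(structure))
  states <- secondary_structure(structure)
  ssp <- ss_percentages(states)
  mp <- mean_plddt(structure)
  helices <- isolated_helices(structure, sasa = sasa, states = states,
                              rsa_threshold = rsa_threshold)
  structure(
    list(
      id = structure$id,
      length = n_residues(structure),
      mean_plddt = mp,
      quality_class = quality_class(mp),
      ss_percent = ssp,
      surface_charge = surface_charge(structure, sasa = sasa, threshold = rsa_threshold),
      rg = radius_of_gyration(structure),
      idr_fraction = idr_fraction(structure, idr_window, idr_cutoff, idr_min_len),
      isolated_helix_intervals = helices,
      sasa = sasa,
      ss_states = states
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %s: %d aa, pLDDT %.1f (%s), H/E/L %.0f/%.0f/%.0f%%, charge %+d, Rg %.1f A, IDR %.2f\n",
    x$id, x$length, x$mean_plddt, x$quality_class,
    x$ss_percent["H"], x$ss_percent["E"], x$ss_percent["L"],
    x$surface_charge, x$rg, x$idr_fraction
  ))
  invisible(x)
}

#' Pairwise metric differences (isoform minus reference)
#'
#' @param ref_metrics,iso_metrics `metric_report`s for the two structures.
#' @param tm TM-score of the pair.
#' @return object of class `pair_report`: differences are isoform minus
#'   reference for secondary-structure percentages, surface charge, radius
#'   of gyration, IDR fraction and mean pLDDT.
#' @export
pair_report <- function(ref_metrics, iso_metrics, tm) {
  structure(
    list(
      ref_id = ref_metrics$id, iso_id = iso_metrics$id,
      tm_score = tm,
      d_ss_percent = iso_metrics$ss_percent - ref_metrics$ss_percent,
      d_surface_charge = iso_metrics$surface_charge - ref_metrics$surface_charge,
      d_rg = iso_metrics$rg - ref_metrics$rg,
      d_idr_fraction = iso_metrics$idr_fraction - ref_metrics$idr_fraction,
      d_plddt = iso_metrics$mean_plddt - ref_metrics$mean_plddt
    ),
    class = "pair_report"
  )
}

#' Quartile outlier bounds
#'
#' `low = Q1 - 1.5 IQR`, `high = Q3 + 1.5 IQR`, with quartiles computed by
#' linear interpolation (the default quantile definition).
#'
#' @param values numeric vector.
#' @return named numeric vector `c(low =, high =)`.
#' @export
outlier_bounds <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(low = q[1] - 1.5 * iqr, high = q[2] + 1.5 * iqr)
}

#' Classify values against the quartile outlier rule
#'
#' @param values numeric vector.
#' @return character vector in \{"negative", "inlier", "positive"\}:
#'   strictly below the low bound, within bounds, strictly above the high
#'   bound.
#' @export
classify_outliers <- function(values) {
  b <- outlier_bounds(values)
  out <- rep("inlier", length(values))
  out[values < b["low"]] <- "negative"
  out[values > b["high"]] <- "positive"
  out
}

#' Most frequent splicing event types among outlier isoforms
#'
#' @param outlier_classes character vector from [classify_outliers()],
#'   named by isoform id.
#' @param event_sets named list of `splice_event_set`s keyed by isoform id.
#' @param k number of top types per sign (default 5).
#' @return data.frame with columns `sign`, `type`, `count`, ranked within
#'   each sign.
#' @export
top_event_types <- function(outlier_classes, event_sets, k = 5) {
  out <- list()
  for (sgn in c("positive", "negative")) {
    ids <- names(outlier_classes)[outlier_classes == sgn]
    types <- unlist(lapply(ids, function(id) {
      es <- event_sets[[id]]
      if (is.null(es)) character(0) else vapply(es$events, `[[`, "", "type")
    }))
    if (length(types)) {
      tab <- sort(table(types), decreasing = TRUE)
      tab <- utils::head(tab, k)
      out[[sgn]] <- data.frame(sign = sgn, type = names(tab),
                               count = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sign = character(0), type = character(0), count = integer(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
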