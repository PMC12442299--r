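# Per-residue-effect regression: metric differences (or TM-score) modelled
# as a linear function of per-type splicing event lengths in residues,
# with the outcome standardized. Fitting uses ordinary least squares via
# stats::lm, with classical coefficient t-tests.

#' Standardize values to z-scores
#'
#' @param values numeric vector with non-zero variance.
#' @return vector with sample mean 0 and sample standard deviation 1.
#' @export
standardize <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant (zero-variance) vector")
  (values - mean(values)) / s
}

#' Assemble the regression design from pair reports and event sets
#'
#' Builds one row per isoform pair: splicing-length features in residues
#' (nucleotides / 3; pairs with any event length not divisible by 3 are
#' excluded with a warning) plus the pLDDT difference, and the chosen
#' outcome metric standardized to mean 0, sd 1. A TM-score outcome forces
#' absolute mode (unsigned features, ES/IR unsplit), matching its
#' non-directional nature; other outcomes default to signed mode.
#'
#' @param pair_reports list of `pair_report`s.
#' @param event_sets list of `splice_event_set`s, parallel to
#'   `pair_reports`.
#' @param outcome one of `"tm"`, `"helix"`, `"sheet"`, `"loop"`,
#'   `"charge"`, `"rg"`, `"idr"`.
#' @param mode `"signed"` or `"absolute"`; ignored (absolute) for `"tm"`.
#' @return object of class `regression_design`: list with `features`
#'   (matrix), `outcome` (standardized), `mode`, `outcome_name`.
#' @export
build_design <- function(pair_reports, event_sets,
                         outcome = c("tm", "helix", "sheet", "loop", "charge", "rg", "idr"),
                         mode = NULL) {
  outcome <- match.arg(outcome)
  if (length(pair_reports) != length(event_sets)) {
    stop("pair_reports and event_sets must be parallel lists")
  }
  mode <- if (outcome == "tm") "absolute" else (mode %||% "signed")
  rows <- lapply(seq_along(pair_reports), function(i) {
    f <- event_length_features(event_sets[[i]], mode = mode, units = "residue")
    dp <- pair_reports[[i]]$d_plddt
    if (mode == "absolute") dp <- abs(dp)
    c(f, dpLDDT = dp)
  })
  frame_ok <- vapply(seq_along(event_sets), function(i) {
    isTRUE(attr(event_length_features(event_sets[[i]], mode = mode, units = "residue"), "frame_ok"))
  }, logical(1))
  if (any(!frame_ok)) {
    warning(sum(!frame_ok), " pair(s) with frame-ambiguous event lengths excluded")
  }
  X <- do.call(rbind, rows[frame_ok])
  y_raw <- vapply(pair_reports[frame_ok], function(p) {
    switch(outcome,
      tm = p$tm_score,
      helix = unname(p$d_ss_percent["H"]),
      sheet = unname(p$d_ss_percent["E"]),
      loop = unname(p$d_ss_percent["L"]),
      charge = p$d_surface_charge,
      rg = p$d_rg,
      idr = p$d_idr_fraction
    )
  }, numeric(1))
  structure(
    list(features = X, outcome = standardize(y_raw), outcome_raw = y_raw,
         mode = mode, outcome_name = outcome),
    class = "regression_design"
  )
}

#' Fit ordinary least squares with coefficient t-tests
#'
#' Fits `outcome ~ features` with an intercept via `stats::lm` and reports
#' per-feature effects, standard errors and two-sided t-test p-values.
#' Collinear designs are rejected with the offending columns named.
#'
#' @param design a `regression_design`, or a list with `features` (matrix)
#'   and `outcome` (numeric).
#' @return data.frame (`effect_table`): `feature`, `effect`, `se`,
#'   `p_value`.
#' @export
fit_ols <- function(design) {
  X <- design$features
  y <- design$outcome
  if (nrow(X) <= ncol(X)) stop("need more rows than features")
  # drop all-zero columns (event types absent from the cohort) before the
  # rank check; they carry no information
  nonzero <- colSums(X != 0) > 0
  Xa <- X[, nonzero, drop = FALSE]
  qx <- qr(cbind(1, Xa))
  if (qx$rank < ncol(Xa) + 1L) {
    piv <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(ncol(Xa) + 1L), piv) - 1L
    dropped <- dropped[dropped >= 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(Xa)[dropped], collapse = ", "))
  }
  df <- as.data.frame(Xa)
  names(df) <- make.names(colnames(Xa))
  df$.outcome <- y
  fit <- stats::lm(.outcome ~ ., data = df)
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  out <- data.frame(
    feature = colnames(Xa),
    effect = unname(sm[keep, "Estimate"]),
    se = unname(sm[keep, "Std. Error"]),
    p_value = unname(sm[keep, "Pr(>|t|)"]),
    stringsAsFactors = FALSE
  )
  # absent features are reported with zero effect and p = NA
  if (any(!nonzero)) {
    out <- rbind(out, data.frame(feature = colnames(X)[!nonzero],
                                 effect = 0, se = NA_real_, p_value = NA_real_))
  }
  out[match(colnames(X), out$feature), , drop = FALSE]
}

#' Combine effect tables across outcomes into one long table
#'
#' @param tables named list of effect tables from [fit_ols()], keyed by
#'   outcome name.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: `outcome`, `feature`, `effect`, `se`, `p_value`,
#'   `significant`.
#' @export
effect_summary <- function(tables, alpha = 0.05) {
  out <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    t$outcome <- nm
    t
  }))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out[, c("outcome", "feature", "effect", "se", "p_value", "significant")]
}
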