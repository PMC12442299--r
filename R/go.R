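# Template-based GO term scoring: per-channel confidence scores from
# sequence homology, structure homology, PPI partners and domain matches;
# a pluggable consensus combiner; gain/loss comparison between isoforms;
# and hypergeometric enrichment of gain/loss by splicing type.

.score_terms <- function(weights, term_sets, term = NULL) {
  denom <- sum(weights)
  if (denom <= 0) stop("non-positive score denominator")
  all_terms <- unique(unlist(term_sets))
  score_one <- function(q) {
    has <- vapply(term_sets, function(s) q %in% s, logical(1))
    sum(weights[has]) / denom
  }
  if (!is.null(term)) return(score_one(term))
  stats::setNames(vapply(all_terms, score_one, numeric(1)), all_terms)
}

#' Sequence-channel GO confidence score
#'
#' For each GO term q, the identity- and bitscore-weighted fraction of
#' homology hits annotated with q:
#' `sum over hits with q of ID * bitscore / sum over all hits of
#' ID * bitscore`.
#'
#' @param hits data.frame with columns `identity`, `bitscore` and a
#'   `go_terms` list column.
#' @param term optional single GO id; when given, returns that term's
#'   score only.
#' @return named numeric vector of per-term scores in \[0, 1\] (or a
#'   scalar).
#' @export
cscore_sequence <- function(hits, term = NULL) {
  if (nrow(hits) == 0L) stop("no hits")
  .score_terms(hits$identity * hits$bitscore, hits$go_terms, term)
}

#' Structure-channel GO confidence score
#'
#' As [cscore_sequence()] with each hit additionally weighted by its
#' TM-score: `sum_q ID * TM * bitscore / sum ID * TM * bitscore`.
#'
#' @param hits data.frame with columns `identity`, `tm`, `bitscore`,
#'   `go_terms`.
#' @inheritParams cscore_sequence
#' @return named numeric vector (or scalar) in \[0, 1\].
#' @export
cscore_structure <- function(hits, term = NULL) {
  if (nrow(hits) == 0L) stop("no hits")
  .score_terms(hits$identity * hits$tm * hits$bitscore, hits$go_terms, term)
}

#' PPI-channel GO confidence score
#'
#' STRING-score-weighted fraction of interaction partners annotated with
#' the term: `sum_q string / sum string`.
#'
#' @param partners data.frame with columns `string_score`, `go_terms`.
#' @inheritParams cscore_sequence
#' @return named numeric vector (or scalar) in \[0, 1\].
#' @export
cscore_ppi <- function(partners, term = NULL) {
  if (nrow(partners) == 0L) stop("no PPI partners")
  .score_terms(partners$string_score, partners$go_terms, term)
}

#' Domain-channel GO confidence score
#'
#' Logistic regression over domain-family match indicators:
#' `1 / (1 + exp(-(w0 + sum_m w_m x_m)))`. The weights are supplied as a
#' table (training them is outside the package's scope).
#'
#' @param match_vector numeric/logical vector of family match indicators.
#' @param weights numeric vector of per-family weights, parallel to
#'   `match_vector`.
#' @param w0 intercept.
#' @return probability in (0, 1).
#' @export
cscore_pfam <- function(match_vector, weights, w0 = 0) {
  if (length(match_vector) != length(weights)) {
    stop("match_vector and weights must have the same length")
  }
  1 / (1 + exp(-(w0 + sum(weights * as.numeric(match_vector)))))
}

#' Combine channel scores into a consensus probability
#'
#' Default combiner: weighted mean over the available (non-`NA`) channels,
#' uniform weights. A custom combiner function (e.g. an externally trained
#' model) may be plugged in; it receives the named score vector and must
#' return a probability.
#'
#' @param channel_scores named numeric vector of per-channel scores in
#'   \[0, 1\] (`NA` = channel unavailable).
#' @param weights optional named weights parallel to `channel_scores`.
#' @param combiner optional function overriding the weighted mean.
#' @return consensus probability in \[0, 1\].
#' @export
combine_scores <- function(channel_scores, weights = NULL, combiner = NULL) {
  if (!is.null(combiner)) return(combiner(channel_scores))
  ok <- !is.na(channel_scores)
  if (!any(ok)) stop("no available channel scores")
  w <- weights %||% rep(1, length(channel_scores))
  w <- w[ok] / sum(w[ok])
  sum(w * channel_scores[ok])
}

#' Confidently predicted GO terms
#'
#' @param scores named numeric vector of per-term consensus probabilities.
#' @param threshold terms with probability strictly above this are
#'   confident (default 0.6).
#' @return character vector of term ids.
#' @export
confident_terms <- function(scores, threshold = 0.6) {
  names(scores)[scores > threshold]
}

#' GO term gain and loss between reference and isoform
#'
#' @param ref_terms,iso_terms character vectors of confident term ids.
#' @return list with `gained` (isoform minus reference) and `lost`
#'   (reference minus isoform).
#' @export
gain_loss <- function(ref_terms, iso_terms) {
  list(gained = setdiff(iso_terms, ref_terms),
       lost = setdiff(ref_terms, iso_terms))
}

#' Hypergeometric enrichment of a GO term within a splicing type
#'
#' Upper-tail hypergeometric test: from `M` isoforms of which `n`
#' gain/lose the term and `N` carry the splicing type, the probability of
#' observing `k` or more isoforms with both. The point probability mass
#' is also returned.
#'
#' @param k isoforms with the term change and the splicing type.
#' @param M total isoforms.
#' @param n isoforms with the term change.
#' @param N isoforms with the splicing type.
#' @return list with `p_value` (upper tail, `P(X >= k)`) and `pmf`
#'   (`P(X = k)`).
#' @export
enrichment_test <- function(k, M, n, N) {
  if (any(c(k, M, n, N) < 0) || n > M || N > M || k > min(n, N)) {
    stop("infeasible hypergeometric counts")
  }
  pmf <- stats::dhyper(k, m = n, n = M - n, k = N)
  p <- stats::phyper(k - 1, m = n, n = M - n, k = N, lower.tail = FALSE)
  list(p_value = p, pmf = pmf)
}

#' Filter term statistics for gain/loss heatmaps
#'
#' Keeps terms with at least `min_gained` gains (gain panel) or at least
#' `min_lost` losses (loss panel), and drops over-general terms predicted
#' for more than `max_predictions` proteins.
#'
#' @param term_stats data.frame with columns `term`, `n_gained`, `n_lost`,
#'   `n_predictions`.
#' @param min_gained,min_lost,max_predictions filter thresholds (defaults
#'   5, 15, 5000).
#' @return list with `gain` and `loss` data.frames of retained terms.
#' @export
heatmap_filter <- function(term_stats, min_gained = 5, min_lost = 15,
                           max_predictions = 5000) {
  general <- term_stats$n_predictions > max_predictions
  list(
    gain = term_stats[!general & term_stats$n_gained >= min_gained, , drop = FALSE],
    loss = term_stats[!general & term_stats$n_lost >= min_lost, , drop = FALSE]
  )
}
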