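# Classification of the nine alternative-splicing event types from a pair
# of exon chains, and the per-type length features feeding the regression.
#
# Strategy: normalise both transcripts to transcription orientation, anchor
# on exactly-shared exons (longest common subsequence of identical
# intervals), then classify each unanchored gap 5'->3'. Every exon boundary
# difference is assigned to exactly one event.

.EVENT_TYPES <- c("ES", "ADS", "AAS", "MXE", "IR", "AFE", "ALE", "MXE-AFE", "MXE-ALE")

# orient exons into transcription coordinates: ascending intervals whose
# "end" is the 3' (donor-side) boundary
.orient <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") {
    data.frame(start = -ex$end, end = -ex$start)
  } else {
    data.frame(start = ex$start, end = ex$end)
  }
}

.deorient <- function(iv, strand) {
  if (nrow(iv) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  if (strand == "-") data.frame(start = -iv$end, end = -iv$start)
  else iv[, c("start", "end")]
}

.exlen <- function(iv) if (nrow(iv) == 0L) 0L else sum(iv$end - iv$start + 1L)

# longest common subsequence of exactly identical exons; returns index pairs
.lcs_exons <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  L <- matrix(0L, n + 1, m + 1)
  eq <- function(i, j) A$start[i] == B$start[j] && A$end[i] == B$end[j]
  for (i in seq_len(n)) for (j in seq_len(m)) {
    L[i + 1, j + 1] <- if (eq(i, j)) L[i, j] + 1L else max(L[i, j + 1], L[i + 1, j])
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (eq(i, j) && L[i + 1, j + 1] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (L[i, j + 1] >= L[i + 1, j]) i <- i - 1 else j <- j - 1
  }
  pairs
}

.new_event <- function(type, ref_iv, iso_iv, host = "both") {
  list(type = type, ref_intervals = ref_iv, iso_intervals = iso_iv,
       delta_nt = .exlen(iso_iv) - .exlen(ref_iv), host = host)
}

.overlaps <- function(a, b) a["start"] <= b["end"] && b["start"] <= a["end"]

# classify one unanchored gap between (or outside) anchors
.classify_gap <- function(Rg, Ig, position) {
  ev <- list()
  nr <- nrow(Rg); ni <- nrow(Ig)
  if (nr == 0L && ni == 0L) return(ev)
  # intron retention: one exon exactly spanning >= 2 exons on the other side
  if (ni == 1L && nr >= 2L &&
      Ig$start[1] == Rg$start[1] && Ig$end[1] == Rg$end[nr]) {
    return(list(.new_event("IR", Rg, Ig, host = "isoform")))
  }
  if (nr == 1L && ni >= 2L &&
      Rg$start[1] == Ig$start[1] && Rg$end[1] == Ig$end[ni]) {
    return(list(.new_event("IR", Rg, Ig, host = "reference")))
  }
  if (position %in% c("leading", "trailing", "whole")) {
    term_type <- if (position == "trailing") "ALE" else "AFE"
    mxe_type <- paste0("MXE-", term_type)
    overlaps_any <- function(x, df) {
      nrow(df) > 0L && any(x$start <= df$end & df$start <= x$end)
    }
    # the gap contains the transcript's outermost exon(s); inner gap exons
    # that overlap nothing on the other side are plain skipping events
    outer_r <- rep(FALSE, nr); outer_i <- rep(FALSE, ni)
    if (position != "trailing") {
      if (nr) outer_r[1] <- TRUE
      if (ni) outer_i[1] <- TRUE
    }
    if (position != "leading") {
      if (nr) outer_r[nr] <- TRUE
      if (ni) outer_i[ni] <- TRUE
    }
    keep_r <- rep(TRUE, nr); keep_i <- rep(TRUE, ni)
    for (i in seq_len(nr)) {
      if (!outer_r[i] && !overlaps_any(Rg[i, , drop = FALSE], Ig)) {
        ev[[length(ev) + 1L]] <- .new_event("ES", Rg[i, , drop = FALSE],
                                            Rg[0, , drop = FALSE], host = "isoform")
        keep_r[i] <- FALSE
      }
    }
    for (j in seq_len(ni)) {
      if (!outer_i[j] && !overlaps_any(Ig[j, , drop = FALSE], Rg)) {
        ev[[length(ev) + 1L]] <- .new_event("ES", Ig[0, , drop = FALSE],
                                            Ig[j, , drop = FALSE], host = "reference")
        keep_i[j] <- FALSE
      }
    }
    R2 <- Rg[keep_r, , drop = FALSE]; I2 <- Ig[keep_i, , drop = FALSE]
    nr2 <- nrow(R2); ni2 <- nrow(I2)
    if (nr2 == 0L && ni2 == 0L) return(ev)
    if (nr2 == 0L || ni2 == 0L) {
      ev[[length(ev) + 1L]] <- .new_event(term_type, R2, I2,
        host = if (nr2 == 0L) "reference" else "isoform")
      return(ev)
    }
    any_overlap <- any(vapply(seq_len(nr2), function(i) {
      overlaps_any(R2[i, , drop = FALSE], I2)
    }, logical(1)))
    if (!any_overlap) {
      ev[[length(ev) + 1L]] <- .new_event(mxe_type, R2, I2)
      return(ev)
    }
    if (nr2 == 1L && ni2 == 1L) {
      if (position != "trailing" && R2$start[1] == I2$start[1] && R2$end[1] != I2$end[1]) {
        # shared 5' boundary, shifted donor on a first exon
        ev[[length(ev) + 1L]] <- .new_event("ADS", R2, I2)
        return(ev)
      }
      if (position != "leading" && R2$end[1] == I2$end[1] && R2$start[1] != I2$start[1]) {
        # shared 3' boundary, shifted acceptor on a last exon
        ev[[length(ev) + 1L]] <- .new_event("AAS", R2, I2)
        return(ev)
      }
    }
    ev[[length(ev) + 1L]] <- .new_event(term_type, R2, I2)
    return(ev)
  }
  # internal gap
  if (ni == 0L) {
    return(lapply(seq_len(nr), function(i) {
      .new_event("ES", Rg[i, , drop = FALSE], Ig[0, , drop = FALSE], host = "isoform")
    }))
  }
  if (nr == 0L) {
    return(lapply(seq_len(ni), function(j) {
      .new_event("ES", Rg[0, , drop = FALSE], Ig[j, , drop = FALSE], host = "reference")
    }))
  }
  # pair exons greedily by overlap, in order
  i <- 1L; j <- 1L
  while (i <= nr || j <= ni) {
    if (i > nr) {
      ev[[length(ev) + 1L]] <- .new_event("ES", Rg[0, ], Ig[j, , drop = FALSE], host = "reference")
      j <- j + 1L
    } else if (j > ni) {
      ev[[length(ev) + 1L]] <- .new_event("ES", Rg[i, , drop = FALSE], Ig[0, ], host = "isoform")
      i <- i + 1L
    } else if (Rg$start[i] <= Ig$end[j] && Ig$start[j] <= Rg$end[i]) {
      r <- Rg[i, , drop = FALSE]; s <- Ig[j, , drop = FALSE]
      if (r$start == s$start && r$end != s$end) {
        ev[[length(ev) + 1L]] <- .new_event("ADS", r, s)
      } else if (r$end == s$end && r$start != s$start) {
        ev[[length(ev) + 1L]] <- .new_event("AAS", r, s)
      } else if (r$start != s$start && r$end != s$end) {
        # both boundaries shifted: one acceptor and one donor event
        ev[[length(ev) + 1L]] <- .new_event("AAS",
          data.frame(start = r$start, end = r$start), data.frame(start = s$start, end = s$start))
        ev[[length(ev)]]$delta_nt <- r$start - s$start
        ev[[length(ev) + 1L]] <- .new_event("ADS",
          data.frame(start = r$end, end = r$end), data.frame(start = s$end, end = s$end))
        ev[[length(ev)]]$delta_nt <- s$end - r$end
      }
      i <- i + 1L; j <- j + 1L
    } else if (Rg$end[i] < Ig$start[j]) {
      # mutually exclusive internal pair when counts allow, else skipping
      if (nr == ni) {
        ev[[length(ev) + 1L]] <- .new_event("MXE", Rg[i, , drop = FALSE], Ig[j, , drop = FALSE])
        i <- i + 1L; j <- j + 1L
      } else {
        ev[[length(ev) + 1L]] <- .new_event("ES", Rg[i, , drop = FALSE], Ig[0, ], host = "isoform")
        i <- i + 1L
      }
    } else {
      if (nr == ni) {
        ev[[length(ev) + 1L]] <- .new_event("MXE", Rg[i, , drop = FALSE], Ig[j, , drop = FALSE])
        i <- i + 1L; j <- j + 1L
      } else {
        ev[[length(ev) + 1L]] <- .new_event("ES", Rg[0, ], Ig[j, , drop = FALSE], host = "reference")
        j <- j + 1L
      }
    }
  }
  ev
}

#' Classify splicing events between a reference and an isoform transcript
#'
#' Compares the two exon chains (same chromosome and strand required) and
#' returns the set of alternative-splicing events distinguishing them, each
#' typed as one of ES, ADS, AAS, MXE, IR, AFE, ALE, MXE-AFE or MXE-ALE,
#' with its signed nucleotide length change `delta_nt` (isoform minus
#' reference). Multiple events may co-occur in one pair; comparing a
#' transcript with itself yields an empty set.
#'
#' @param ref,iso `transcript_model`s on the same chromosome and strand.
#' @return object of class `splice_event_set`: list with `ref_id`,
#'   `iso_id`, and `events` (list of events with `type`, `ref_intervals`,
#'   `iso_intervals` in genomic coordinates, `delta_nt`, `host`).
#' @export
compare_exon_chains <- function(ref, iso) {
  if (ref$chrom != iso$chrom) stop("transcripts on different chromosomes")
  if (ref$strand != iso$strand) stop("transcripts on different strands")
  A <- .orient(ref); B <- .orient(iso)
  A <- A[order(A$start), , drop = FALSE]
  B <- B[order(B$start), , drop = FALSE]
  anchors <- .lcs_exons(A, B)
  events <- list()
  n_anchor <- nrow(anchors)
  bounds_r <- c(0L, anchors[, 1], nrow(A) + 1L)
  bounds_i <- c(0L, anchors[, 2], nrow(B) + 1L)
  for (g in seq_len(n_anchor + 1L)) {
    ridx <- seq_len(nrow(A))[seq_len(nrow(A)) > bounds_r[g] & seq_len(nrow(A)) < bounds_r[g + 1L]]
    iidx <- seq_len(nrow(B))[seq_len(nrow(B)) > bounds_i[g] & seq_len(nrow(B)) < bounds_i[g + 1L]]
    position <- if (n_anchor == 0L) "whole"
      else if (g == 1L) "leading"
      else if (g == n_anchor + 1L) "trailing"
      else "internal"
    events <- c(events, .classify_gap(A[ridx, , drop = FALSE], B[iidx, , drop = FALSE], position))
  }
  # de-orient event intervals back to genomic coordinates
  events <- lapply(events, function(e) {
    e$ref_intervals <- .deorient(e$ref_intervals, ref$strand)
    e$iso_intervals <- .deorient(e$iso_intervals, ref$strand)
    e
  })
  structure(
    list(ref_id = ref$transcript_id, iso_id = iso$transcript_id, events = events),
    class = "splice_event_set"
  )
}

#' @export
print.splice_event_set <- function(x, ...) {
  cat(sprintf("<splice_event_set> %s vs %s: %d event(s)\n",
              x$ref_id, x$iso_id, length(x$events)))
  for (e in x$events) {
    cat(sprintf("  %s (host %s): delta %+d nt\n", e$type, e$host, e$delta_nt))
  }
  invisible(x)
}

.SIGNED_FEATURES <- c("ADS", "AAS", "MXE", "AFE", "ALE", "MXE-AFE", "MXE-ALE",
                      "ES(R)", "ES(I)", "IR(R)", "IR(I)")
.ABS_FEATURES <- c("ADS", "AAS", "MXE", "AFE", "ALE", "MXE-AFE", "MXE-ALE",
                   "ES", "IR")

#' Per-type splicing length features
#'
#' Aggregates event lengths into the regression feature vector. In signed
#' mode, ES and IR are split by host (reference vs isoform) and features
#' carry the signed length change (isoform minus reference); in absolute
#' mode ES and IR are unsplit and features carry summed absolute length
#' changes.
#'
#' @param events a `splice_event_set`.
#' @param mode `"signed"` or `"absolute"`.
#' @param units `"nt"` (default) or `"residue"` (nucleotides divided by 3;
#'   the result carries attribute `frame_ok = FALSE` when any event length
#'   is not a multiple of 3 — reading frame and UTRs are not modelled).
#' @return named numeric feature vector; zero vector for an empty set.
#' @export
event_length_features <- function(events, mode = c("signed", "absolute"),
                                  units = c("nt", "residue")) {
  mode <- match.arg(mode)
  units <- match.arg(units)
  feats <- if (mode == "signed") .SIGNED_FEATURES else .ABS_FEATURES
  out <- stats::setNames(numeric(length(feats)), feats)
  frame_ok <- TRUE
  for (e in events$events) {
    key <- e$type
    val <- e$delta_nt
    if (mode == "signed" && key %in% c("ES", "IR")) {
      key <- paste0(key, if (e$host == "reference") "(R)" else "(I)")
    }
    if (mode == "absolute") val <- abs(val)
    out[key] <- out[key] + val
    if (e$delta_nt %% 3 != 0) frame_ok <- FALSE
  }
  if (units == "residue") out <- out / 3
  attr(out, "frame_ok") <- frame_ok
  out
}
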