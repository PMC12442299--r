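# Splicing-event classification and the per-type length features.

test_that("all nine planted event types classify exactly on both strands", {
  types <- c("ES", "ADS", "AAS", "MXE", "IR", "AFE", "ALE", "MXE-AFE", "MXE-ALE")
  for (tp in types) {
    for (st in c("+", "-")) {
      p <- make_transcript_pair(tp, strand = st)
      es <- compare_exon_chains(p$ref, p$iso)
      got <- vapply(es$events, `[[`, "", "type")
      expect_identical(got, tp, label = paste(tp, st))
      expect_equal(es$events[[1]]$delta_nt, p$truth$delta_nt,
                   label = paste(tp, st, "delta"))
    }
  }
})

test_that("classifier reproduces the canonical single-event configurations", {
  tm <- function(id, ex, st = "+") {
    transcript_model(id, "g", data.frame(start = vapply(ex, `[`, 0, 1),
                                         end = vapply(ex, `[`, 0, 2)), strand = st)
  }
  check <- function(ref_ex, iso_ex, type, delta, host = NULL) {
    es <- compare_exon_chains(tm("r", ref_ex), tm("i", iso_ex))
    expect_length(es$events, 1)
    e <- es$events[[1]]
    expect_identical(e$type, type)
    expect_equal(e$delta_nt, delta)
    if (!is.null(host)) expect_identical(e$host, host)
  }
  check(list(c(1, 100), c(201, 300), c(401, 500)), list(c(1, 100), c(401, 500)),
        "ES", -100, "isoform")
  check(list(c(1, 100), c(201, 300)), list(c(1, 150), c(201, 300)), "ADS", +50)
  check(list(c(1, 100), c(201, 300)), list(c(1, 100), c(151, 300)), "AAS", +50)
  check(list(c(1, 100), c(201, 300), c(401, 500)),
        list(c(1, 100), c(321, 380), c(401, 500)), "MXE", -40)
  check(list(c(1, 100), c(201, 300)), list(c(1, 300)), "IR", +100, "isoform")
  check(list(c(1, 100), c(201, 300)), list(c(121, 160), c(201, 300)), "MXE-AFE", -60)
  check(list(c(1, 100), c(201, 300)), list(c(31, 100), c(201, 300)), "AFE", -30)
})

test_that("self-comparison is empty; swapping flips signs and ES/IR hosts", {
  p <- make_transcript_pair("ES")
  expect_length(compare_exon_chains(p$ref, p$ref)$events, 0)
  for (tp in c("ES", "IR", "ADS", "MXE-ALE")) {
    p <- make_transcript_pair(tp)
    fwd <- compare_exon_chains(p$ref, p$iso)$events[[1]]
    rev <- compare_exon_chains(p$iso, p$ref)$events[[1]]
    expect_identical(rev$type, fwd$type)
    expect_equal(rev$delta_nt, -fwd$delta_nt)
    if (tp %in% c("ES", "IR")) {
      expect_identical(sort(c(fwd$host, rev$host)), c("isoform", "reference"))
    }
  }
  p1 <- make_transcript_pair("ES")
  p2 <- make_transcript_pair("ES", strand = "-")
  expect_error(compare_exon_chains(p1$ref, p2$iso), "strand")
})

test_that("multiple events in one pair are each assigned once", {
  # exon skipped AND last-exon boundary shifted
  ref <- transcript_model("r", "g",
    data.frame(start = c(1, 201, 401, 601), end = c(100, 300, 500, 700)))
  iso <- transcript_model("i", "g",
    data.frame(start = c(1, 401, 601), end = c(100, 500, 670)))
  es <- compare_exon_chains(ref, iso)
  types <- sort(vapply(es$events, `[[`, "", "type"))
  expect_identical(types, c("ALE", "ES"))
  deltas <- vapply(es$events, function(e) e$delta_nt, numeric(1))
  expect_equal(sum(deltas), transcript_length(iso) - transcript_length(ref))
})

test_that("length features aggregate by type, host and mode", {
  tmx <- function(id, ex, st = "+") {
    transcript_model(id, "g", data.frame(start = vapply(ex, `[`, 0, 1),
                                         end = vapply(ex, `[`, 0, 2)), strand = st)
  }
  es <- compare_exon_chains(
    tmx("r", list(c(1, 100), c(201, 300), c(401, 500))),
    tmx("i", list(c(1, 100), c(401, 500))))
  f <- event_length_features(es, mode = "signed")
  expect_equal(unname(f["ES(I)"]), -100)
  expect_equal(sum(f != 0), 1)

  # ADS +50 and ES -100 in one set
  ref <- tmx("r", list(c(1, 100), c(201, 300), c(401, 500)))
  iso <- tmx("i", list(c(1, 150), c(401, 500)))
  es2 <- compare_exon_chains(ref, iso)
  f2 <- event_length_features(es2, mode = "signed")
  expect_equal(unname(f2["ADS"]), 50)
  expect_equal(unname(f2["ES(I)"]), -100)
  fa <- event_length_features(es2, mode = "absolute")
  expect_equal(unname(fa["ADS"]), 50)
  expect_equal(unname(fa["ES"]), 100)

  empty <- compare_exon_chains(ref, ref)
  expect_true(all(event_length_features(empty) == 0))

  # residue units flag frame-ambiguous lengths
  fr <- event_length_features(es2, mode = "signed", units = "residue")
  expect_false(attr(fr, "frame_ok"))
  p <- make_transcript_pair("ES")  # default geometry is frame-clean
  fr2 <- event_length_features(compare_exon_chains(p$ref, p$iso), units = "residue")
  expect_true(attr(fr2, "frame_ok"))
  expect_equal(unname(fr2["ES(I)"]), -33)
})
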