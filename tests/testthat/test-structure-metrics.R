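# SASA, RSA, surface charge, radius of gyration, secondary structure,
# disorder, isolated helices, contact maps and the outlier rule.

single_atom <- function(elem = "C", x = 0, y = 0, z = 0, resid = "ALA",
                        resno = 1, elety = "CA", b = 50) {
  data.frame(resno = resno, resid = resid, elety = elety, element = elem,
             x = x, y = y, z = z, b = b)
}

test_that("SASA matches analytic sphere areas", {
  s <- protein_structure(single_atom())
  sa <- shrake_rupley_sasa(s)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(sa$atom_sasa - analytic) / analytic, 0.01)

  # two coincident atoms expose exactly one atom's surface in total? no:
  # each point of either sphere lies on the other's surface boundary; the
  # stable analytic case is full overlap with a smaller atom inside
  s2 <- protein_structure(rbind(single_atom(),
                                single_atom(elem = "O", elety = "O", x = 0.05)))
  sa2 <- shrake_rupley_sasa(s2)
  # the larger carbon sphere swallows the oxygen sphere: total ~ one C atom
  expect_lt(abs(sum(sa2$atom_sasa) - analytic) / analytic, 0.01)

  # partial two-sphere overlap against the analytic spherical-cap formula
  d <- 2.0
  r1 <- 1.7 + 1.4; r2 <- 1.52 + 1.4
  s3 <- protein_structure(rbind(single_atom(),
                                single_atom(elem = "O", elety = "O", x = d)))
  sa3 <- shrake_rupley_sasa(s3)
  cap1 <- 2 * pi * r1 * (r1 - (d^2 + r1^2 - r2^2) / (2 * d))
  cap2 <- 2 * pi * r2 * (r2 - (d^2 + r2^2 - r1^2) / (2 * d))
  exact <- c(4 * pi * r1^2 - cap1, 4 * pi * r2^2 - cap2)
  expect_lt(max(abs(sa3$atom_sasa - exact) / exact), 0.01)

  expect_error(shrake_rupley_sasa(
    protein_structure(single_atom(elem = "ZZ"))), "unknown element")
})

test_that("adding atoms never increases another atom's exposed area", {
  s <- mixed_structure()
  base <- shrake_rupley_sasa(s)$atom_sasa
  extra <- single_atom(x = mean(s$atoms$x), y = mean(s$atoms$y),
                       z = mean(s$atoms$z), resno = max(s$atoms$resno) + 1)
  s2 <- protein_structure(rbind(s$atoms[, names(extra)], extra))
  grown <- shrake_rupley_sasa(s2)$atom_sasa
  expect_true(all(grown[seq_along(base)] <= base + 1e-9))
})

test_that("core residues of a helix bundle are buried relative to a lone helix", {
  bundle <- make_bundle_fixture()
  lone <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 20, plddt = 90),
                   sequence = strrep("A", 20)), seed = 3)
  sb <- relative_accessibility(shrake_rupley_sasa(bundle))
  sl <- relative_accessibility(shrake_rupley_sasa(lone))
  # same sequence (same seed): compare residue-by-residue for the first helix
  interior <- 5:16
  expect_lt(mean(sb$residue_rsa[interior]), mean(sl$residue_rsa[interior]))
  # a packed helix is not "isolated" while the lone exposed one is
  expect_equal(nrow(isolated_helices(lone, min_run = 15)), 1)
})

test_that("RSA normalises by residue-type maximum ASA", {
  # extended Ala tripeptide: central residue nearly fully exposed
  tri <- make_ideal_structure(
    structure_spec(data.frame(type = "strand", length = 3, plddt = 90),
                   sequence = "AAA"), seed = 1)
  rsa <- relative_accessibility(shrake_rupley_sasa(tri))
  expect_gt(rsa$residue_rsa[2], 0.7)
  # the denominator is the alanine table value
  expect_equal(rsa$residue_rsa[2],
               rsa$residue_sasa[2] / max_asa_table()["A"],
               ignore_attr = TRUE)
  # zero SASA gives zero RSA; thresholding behaves
  fake <- structure(list(residue_sasa = c(`1` = 0, `2` = 50),
                         sequence = "AA", residue_rsa = NULL),
                    class = "sasa_result")
  fake <- relative_accessibility(fake)
  expect_equal(unname(fake$residue_rsa[1]), 0)
  expect_identical(surface_residues(fake, threshold = 0.25), 2L)
  expect_length(surface_residues(relative_accessibility(
    structure(list(residue_sasa = c(`1` = 0), sequence = "A", residue_rsa = NULL),
              class = "sasa_result"))), 0)
})

test_that("surface charge sums formal charges over exposed residues", {
  kgd <- make_ideal_structure(
    structure_spec(data.frame(type = "strand", length = 3, plddt = 90),
                   sequence = "KGD"), seed = 1)
  expect_equal(surface_charge(kgd), 0)
  polyk <- make_ideal_structure(
    structure_spec(data.frame(type = "strand", length = 10, plddt = 90),
                   sequence = strrep("K", 10)), seed = 1)
  expect_equal(surface_charge(polyk), 10)
  rot <- transform_structure(polyk, rotation_about(c(1, 2, 3), 73), c(4, -6, 1))
  expect_equal(surface_charge(rot), surface_charge(polyk))
})

test_that("radius of gyration has its closed-form values and rigid invariance", {
  expect_equal(radius_of_gyration(protein_structure(single_atom())), 0)
  two <- protein_structure(rbind(single_atom(), single_atom(x = 2, resno = 2)))
  expect_equal(radius_of_gyration(two), 1.0)
  s <- mixed_structure()
  r0 <- radius_of_gyration(s)
  s2 <- transform_structure(s, rotation_about(c(0, 1, 1), 211), c(-8, 3, 12))
  expect_lt(abs(radius_of_gyration(s2) - r0), 1e-9)
})

test_that("secondary structure separates helix, sheet and coil fixtures", {
  helix <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 30, plddt = 90)), seed = 1)
  ss_h <- secondary_structure(helix)
  expect_gte(mean(ss_h == "H"), 0.8)

  sheet <- make_sheet_fixture()
  ss_e <- secondary_structure(sheet)
  # interior residues of both strands assign sheet
  expect_gte(mean(ss_e[c(3:8, 13:18)] == "E"), 0.8)

  he_frac <- vapply(1:10, function(sd) {
    s <- make_ideal_structure(
      structure_spec(data.frame(type = "coil", length = 50, plddt = 60)), seed = sd)
    mean(secondary_structure(s) %in% c("H", "E"))
  }, numeric(1))
  expect_lte(mean(he_frac), 0.20)

  p <- ss_percentages(ss_h)
  expect_equal(sum(p), 100)
  expect_error(ss_percentages(character(0)), "empty")
  expect_equal(ss_percentages(rep("H", 5)), c(H = 100, E = 0, L = 0))
})

test_that("contact maps are symmetric CB-distance maps without the diagonal", {
  s <- mixed_structure()
  cm <- contact_map(s)
  expect_true(isSymmetric(cm))
  expect_true(all(!diag(cm)))
  expect_true(all(cm[cbind(1:(nrow(cm) - 1), 2:nrow(cm))]))  # chain neighbours touch
  # brute-force oracle
  cb <- atom_coords(s, "CB"); ca <- atom_coords(s, "CA")
  cb[is.na(cb[, 1]), ] <- ca[is.na(cb[, 1]), ]
  n <- nrow(cb)
  ref <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) ref[i, j] <- sqrt(sum((cb[i, ] - cb[j, ])^2)) < 8
  }
  expect_equal(unname(cm), ref)
})

test_that("pLDDT quality classes use strict band boundaries", {
  expect_identical(quality_class(95), "high")
  expect_identical(quality_class(80), "confident")
  expect_identical(quality_class(90), "confident")
  expect_identical(quality_class(70), "low")
  expect_identical(quality_class(50), "very_low")
})

test_that("IDR detection follows the window-averaged pLDDT rule", {
  hi <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 60, plddt = 90)), seed = 1)
  expect_equal(idr_fraction(hi), 0)
  lo <- make_ideal_structure(
    structure_spec(data.frame(type = "coil", length = 60, plddt = 60)), seed = 1)
  expect_equal(idr_fraction(lo), 1)

  # 60 disordered residues at the start of a 200-residue chain
  s <- make_ideal_structure(
    structure_spec(data.frame(type = c("coil", "helix"), length = c(60, 140),
                              plddt = c(40, 90))), seed = 2)
  regs <- idr_regions(s)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start, 1)
  expect_lt(abs(regs$end - 60), 13)  # half-window blurring at the boundary
  expect_lt(abs(idr_fraction(s) - 0.3), 0.07)
  # oracle: direct window means
  p <- residue_plddt(s)
  wm <- vapply(seq_along(p), function(i) {
    mean(p[max(1, i - 12):min(length(p), i + 12)])
  }, numeric(1))
  expect_equal(regs$end, max(which(wm < 70)))
})

test_that("isolated helices require both length and exposure", {
  lone <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 30, plddt = 90),
                   sequence = strrep("A", 30)), seed = 1)
  ih <- isolated_helices(lone)
  expect_equal(nrow(ih), 1)
  expect_gte(ih$end[1] - ih$start[1] + 1, 21)
  short <- make_ideal_structure(
    structure_spec(data.frame(type = "helix", length = 15, plddt = 90),
                   sequence = strrep("A", 15)), seed = 1)
  expect_equal(nrow(isolated_helices(short)), 0)
})

test_that("pair reports subtract isoform minus reference and are antisymmetric", {
  s <- mixed_structure()
  m <- structure_metrics(s)
  same <- pair_report(m, m, tm = 1)
  expect_equal(same$d_surface_charge, 0)
  expect_equal(unname(same$d_ss_percent), c(0, 0, 0))
  expect_equal(same$d_rg, 0)

  s2 <- make_ideal_structure(
    structure_spec(data.frame(type = c("helix", "coil"), length = c(15, 10),
                              plddt = 80)), seed = 9)
  m2 <- structure_metrics(s2)
  fwd <- pair_report(m, m2, tm = 0.7)
  rev <- pair_report(m2, m, tm = 0.7)
  expect_equal(fwd$d_rg, -rev$d_rg)
  expect_equal(fwd$d_surface_charge, -rev$d_surface_charge)
  expect_equal(fwd$d_plddt, -rev$d_plddt)
})

test_that("quartile outlier rule matches direct quantile computation", {
  v <- c(1:9, 100)
  b <- outlier_bounds(v)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(unname(b), c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)))
  cls <- classify_outliers(v)
  expect_identical(cls[10], "positive")
  expect_true(all(cls[1:9] == "inlier"))
  expect_true(all(classify_outliers(rep(3, 8)) == "inlier"))
  sym <- c(-5, -2, -1, 0, 1, 2, 5)
  bs <- outlier_bounds(sym)
  expect_equal(unname(bs["low"]), -unname(bs["high"]))
})

test_that("top event types rank splicing events among outliers", {
  es1 <- compare_exon_chains(make_transcript_pair("ES")$ref, make_transcript_pair("ES")$iso)
  es2 <- compare_exon_chains(make_transcript_pair("ALE")$ref, make_transcript_pair("ALE")$iso)
  sets <- list(i1 = es1, i2 = es1, i3 = es2)
  cls <- c(i1 = "positive", i2 = "positive", i3 = "negative")
  tab <- top_event_types(cls, sets)
  expect_identical(tab$type[tab$sign == "positive"][1], "ES")
  expect_equal(tab$count[tab$sign == "positive"][1], 2)
  expect_identical(tab$type[tab$sign == "negative"], "ALE")
  empty <- top_event_types(character(0), sets)
  expect_equal(nrow(empty), 0)
})
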