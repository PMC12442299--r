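# PTM site mapping and exposure-fate classification.

test_that("site mapping shifts indices across indels and is an involution", {
  aln <- align_from_strings("ACDEFGHIKL", "ACD---HIKL")
  expect_equal(map_site(2, aln, "ref_to_iso"), 2)
  expect_true(is.na(map_site(5, aln, "ref_to_iso")))   # inside the deletion
  expect_equal(map_site(8, aln, "ref_to_iso"), 5)      # shifted by the indel
  expect_equal(map_site(map_site(8, aln, "ref_to_iso"), aln, "iso_to_ref"), 8)
  expect_error(map_site(40, aln, "ref_to_iso"), "outside")
})

test_that("planted burial edits classify with full agreement to the truth", {
  bp <- make_burial_pair()
  ref_sasa <- relative_accessibility(shrake_rupley_sasa(bp$ref))
  iso_sasa <- relative_accessibility(shrake_rupley_sasa(bp$iso))
  # construction guarantees: exposed on the lone helix, buried under the
  # packed helix
  expect_gt(ref_sasa$residue_rsa[bp$site_pos], 0.25)
  expect_lt(iso_sasa$residue_rsa[bp$site_pos], 0.25)

  site <- list(protein_id = "ref", position = bp$site_pos, residue = "S",
               ptm_type = "phosphorylation")
  cls <- classify_ptm(site, bp$ref, bp$iso, bp$aln,
                      ref_sasa = ref_sasa, iso_sasa = iso_sasa)
  expect_identical(cls$category, "exposed_to_buried")
  expect_false(cls$flagged)

  # swapping the roles yields the mirrored category
  cls_rev <- classify_ptm(site, bp$iso, bp$ref, swap_alignment(bp$aln),
                          ref_sasa = iso_sasa, iso_sasa = ref_sasa)
  expect_identical(cls_rev$category, "buried_to_exposed")

  # a site far from the packed helix keeps its exposure
  site2 <- list(protein_id = "ref", position = 2L, residue = "A",
                ptm_type = "acetylation")
  cls2 <- classify_ptm(site2, bp$ref, bp$iso, bp$aln,
                       ref_sasa = ref_sasa, iso_sasa = iso_sasa)
  expect_identical(cls2$category, "unchanged")
})

test_that("spliced-out and spliced-in sites come from alignment gaps", {
  spec <- structure_spec(data.frame(type = c("helix", "coil", "helix"),
                                    length = c(20, 10, 20), plddt = 90))
  pr <- make_structure_pair(spec, edit = list(delete = list(c(21, 30))), seed = 7)
  aln <- global_align(pr$truth$ref_sequence, pr$truth$iso_sequence)
  ref_seq <- strsplit(pr$truth$ref_sequence, "")[[1]]
  site <- list(protein_id = "ref", position = 25L, residue = ref_seq[25],
               ptm_type = "phosphorylation")
  cls <- classify_ptm(site, pr$ref, pr$iso, aln)
  expect_identical(cls$category, "spliced_out")
  expect_true(is.na(cls$iso_sasa))

  pri <- make_structure_pair(spec,
    edit = list(insert = list(list(pos = 25,
      segment = data.frame(type = "coil", length = 8, plddt = 70)))), seed = 7)
  alni <- global_align(pri$truth$ref_sequence, pri$truth$iso_sequence)
  iso_seq <- strsplit(pri$truth$iso_sequence, "")[[1]]
  ins_pos <- pri$truth$inserted_iso_positions[3]
  site_i <- list(protein_id = "iso", position = ins_pos,
                 residue = iso_seq[ins_pos], ptm_type = "ubiquitination")
  cls_i <- classify_ptm(site_i, pri$ref, pri$iso, alni, side = "isoform")
  expect_identical(cls_i$category, "spliced_in")
  expect_true(is.na(cls_i$ref_sasa))
})

test_that("classification is rigid-motion invariant and flags bad records", {
  bp <- make_burial_pair()
  site <- list(protein_id = "ref", position = bp$site_pos, residue = "S",
               ptm_type = "phosphorylation")
  base <- classify_ptm(site, bp$ref, bp$iso, bp$aln)
  moved <- transform_structure(bp$iso, rotation_about(c(1, 1, 0), 119), c(7, 7, -7))
  again <- classify_ptm(site, bp$ref, moved, bp$aln)
  expect_identical(again$category, base$category)
  expect_equal(again$iso_rsa, base$iso_rsa, tolerance = 1e-9)

  badsite <- list(protein_id = "ref", position = bp$site_pos, residue = "K",
                  ptm_type = "phosphorylation")
  expect_warning(flg <- classify_ptm(badsite, bp$ref, bp$iso, bp$aln), "mismatch")
  expect_true(flg$flagged)
})

test_that("summaries tabulate categories by modification type and preserve totals", {
  rows <- data.frame(
    position = 1:4, ptm_type = c("phosphorylation", "phosphorylation",
                                 "acetylation", "sumoylation"),
    category = c("unchanged", "spliced_out", "exposed_to_buried", "unchanged"),
    flagged = c(FALSE, FALSE, FALSE, TRUE)
  )
  tab <- ptm_summary(rows)
  expect_equal(sum(tab), 3)   # the flagged record is excluded
  expect_equal(unname(tab["unchanged", "phosphorylation"]), 1)
  expect_equal(unname(tab["spliced_out", "phosphorylation"]), 1)
  expect_equal(unname(tab["exposed_to_buried", "acetylation"]), 1)
  empty <- ptm_summary(rows[0, , drop = FALSE])
  expect_equal(sum(empty), 0)
})
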