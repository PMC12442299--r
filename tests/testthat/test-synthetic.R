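# Synthetic generators: ideal-geometry structures, structure pairs with
# known edits, MSAs, expression matrices and regression datasets.

test_that("ideal helix geometry: peptide spacing, determinism, helical assignment", {
  spec <- structure_spec(data.frame(type = "helix", length = 30, plddt = 90))
  s <- make_ideal_structure(spec, seed = 1)
  expect_equal(n_residues(s), 30)
  ca <- atom_coords(s, "CA")
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  # interior residues assign helical
  ss <- secondary_structure(s)
  expect_gte(mean(ss[3:28] == "H"), 0.8)
  s2 <- make_ideal_structure(spec, seed = 1)
  expect_identical(s$atoms, s2$atoms)
  s3 <- make_ideal_structure(spec, seed = 2)
  expect_false(identical(structure_sequence(s), structure_sequence(s3)))
})

test_that("structure specs validate segment types, lengths and pLDDT", {
  expect_error(structure_spec(data.frame(type = "spiral", length = 5, plddt = 50)), "type")
  expect_error(structure_spec(data.frame(type = "coil", length = 0, plddt = 50)), "length")
  expect_error(structure_spec(data.frame(type = "coil", length = 5, plddt = 120)), "plddt")
  expect_error(structure_spec(data.frame(type = "coil", length = 5, plddt = 50),
                              sequence = "AC"), "sequence length")
})

test_that("structure pairs carry exact edit truth", {
  spec <- structure_spec(data.frame(type = c("helix", "coil", "helix"),
                                    length = c(20, 10, 20), plddt = 90))
  pr <- make_structure_pair(spec, edit = list(delete = list(c(21, 30))), seed = 7)
  expect_equal(n_residues(pr$iso), 40)
  expect_equal(pr$truth$deleted_ref_positions, 21:30)

  # empty edit reproduces the reference exactly
  pr0 <- make_structure_pair(spec, edit = list(), seed = 7)
  aln0 <- global_align(pr0$truth$ref_sequence, pr0$truth$iso_sequence)
  expect_equal(sequence_identity(aln0), 1.0)
  expect_equal(tm_score(pr0$ref, pr0$iso, aln0), 1.0, tolerance = 1e-9)

  # deletion truth matches the alignment's "missing" label set
  aln <- global_align(pr$truth$ref_sequence, pr$truth$iso_sequence)
  lab <- label_regions(aln)
  expect_setequal(lab$ref_pos[lab$label == "missing"], pr$truth$deleted_ref_positions)

  expect_error(make_structure_pair(spec, edit = list(delete = list(c(5, 10), c(8, 12)))),
               "overlap")
  expect_error(make_structure_pair(spec, edit = list(delete = list(c(40, 60)))),
               "outside")
})

test_that("generated MSAs hit the requested redundancy structure", {
  # full identity: all rows redundant
  expect_equal(effective_msa_depth(make_msa(5, 1.0, seed = 2)), 1.0)
  expect_equal(effective_msa_depth(make_msa(1, 0.5, seed = 2)), 1.0)
  # low identity: verify via the pairwise identity matrix that no pair
  # reaches 0.8, hence Neff = N
  m <- make_msa(5, 0.3, seed = 2)
  chars <- do.call(rbind, strsplit(m$rows, ""))
  ids <- utils::combn(5, 2, function(p) mean(chars[p[1], ] == chars[p[2], ]))
  expect_true(all(ids < 0.8))
  expect_equal(effective_msa_depth(m), 5.0)
})

test_that("expression generator is seeded and shaped by its spec", {
  sp <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                    effect = 5, noise_sd = 0.5, n_cells = 50)
  ex1 <- make_expression(sp, seed = 4)
  ex2 <- make_expression(sp, seed = 4)
  expect_identical(ex1$counts, ex2$counts)
  expect_equal(dim(ex1$counts), c(100, 2))
  expect_equal(unname(ex1$tx2gene), rep("g1", 2))
  # planted signal present: preferred cells express far more
  a_cells <- ex1$metadata$cell_type == "A"
  expect_gt(mean(ex1$counts[a_cells, "t1"]), 8 * mean(ex1$counts[!a_cells, "t1"]))
  expect_error(switch_spec("g", c("t1", "t2"), c("A"), c(t1 = "A", t2 = "A")),
               "distinct")
})

test_that("regression datasets recover their effects and flag collinearity", {
  beta <- c(a = 2, b = -1, c = 0.5)
  d <- make_regression_dataset(beta, n = 60, noise_sd = 0, seed = 3)
  fit <- suppressWarnings(fit_ols(list(features = d$design, outcome = d$outcome)))
  expect_lt(max(abs(fit$effect - beta)), 1e-8)

  X <- cbind(d$design, a_dup = d$design[, "a"])
  expect_error(fit_ols(list(features = X, outcome = d$outcome)), "collinear")
  expect_error(make_regression_dataset(beta, n = 3), "exceed")
})

test_that("hit tables drive the channel scores to their closed forms", {
  all_q <- make_hit_table(10, 1, seed = 5)
  expect_equal(unname(cscore_sequence(all_q, "GO:QUERY")), 1.0)
  none_q <- make_hit_table(10, 0, seed = 5)
  expect_equal(unname(cscore_sequence(none_q, "GO:QUERY")), 0.0)
  mixed <- make_hit_table(20, 0.5, seed = 6)
  w <- mixed$identity * mixed$bitscore
  expected <- sum(w[mixed$has_term]) / sum(w)
  expect_equal(unname(cscore_sequence(mixed, "GO:QUERY")), expected)
  expected_s <- sum((w * mixed$tm)[mixed$has_term]) / sum(w * mixed$tm)
  expect_equal(unname(cscore_structure(mixed, "GO:QUERY")), expected_s)
})
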