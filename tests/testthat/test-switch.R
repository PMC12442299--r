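# TPM normalisation, gene aggregation and isoform-switch detection.

make_x <- function(spec, seed = 1) {
  ex <- make_expression(spec, seed = seed)
  expression_matrix(ex$counts, ex$lengths, ex$tx2gene, ex$metadata)
}

test_that("TPM divides by length, rescales to a million, and ignores depth", {
  counts <- matrix(c(10, 30), 1, 2, dimnames = list("c1", c("a", "b")))
  tpm <- tpm_normalize(counts, lengths = c(a = 1000, b = 3000))
  expect_equal(unname(tpm[1, ]), c(5e5, 5e5))

  single <- matrix(7, 1, 1, dimnames = list("c1", "a"))
  expect_equal(unname(tpm_normalize(single, lengths = c(a = 500))[1, 1]), 1e6)

  expect_equal(tpm_normalize(counts * 2, lengths = c(a = 1000, b = 3000)), tpm)

  set.seed(3)
  m <- matrix(rpois(50, 20), 10, 5,
              dimnames = list(paste0("c", 1:10), paste0("t", 1:5)))
  m[4, ] <- 0
  tp <- tpm_normalize(m, lengths = setNames(c(500, 1000, 1500, 2000, 800),
                                            colnames(m)))
  sums <- rowSums(tp)
  expect_true(all(abs(sums[-4] - 1e6) / 1e6 < 1e-9))
  expect_equal(unname(sums[4]), 0)
})

test_that("gene aggregation sums transcript columns and conserves totals", {
  sp <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                    n_cells = 5)
  x <- make_x(sp)
  g <- aggregate_gene(x)
  expect_equal(dim(g), c(10, 1))
  expect_equal(unname(g[, 1]), unname(rowSums(x$counts)))
  # one transcript per gene: identity
  x1 <- x; x1$tx2gene <- setNames(c("gA", "gB"), c("t1", "t2"))
  g2 <- aggregate_gene(x1)
  expect_equal(unname(g2[, "gA"]), unname(x$counts[, "t1"]))
  expect_equal(sum(g2), sum(x$counts))
})

test_that("a planted switch is flagged and opposite preferences are required", {
  sp <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                    effect = 5, noise_sd = 0.5, n_cells = 100)
  x <- make_x(sp, seed = 2)
  r <- switch_test("g1", x)
  expect_true(r$switch)
  expect_setequal(r$isoforms$preferred, c("A", "B"))
  expect_true(all(r$isoforms$p_corrected < 0.05))
  expect_gt(max(r$isoforms$fold_change), 4)

  # both isoforms upregulated in the same cell type: not a switch
  set.seed(10)
  a_cells <- x$metadata$cell_type == "A"
  log_same <- cbind(
    t1 = ifelse(a_cells, 10, 5) + rnorm(nrow(x$counts), 0, 0.3),
    t2 = ifelse(a_cells, 9, 4) + rnorm(nrow(x$counts), 0, 0.3)
  )
  rownames(log_same) <- rownames(x$counts)
  r_same <- switch_test("g1", x, log_tpm = log_same)
  expect_true(all(r_same$isoforms$significant))
  expect_false(r_same$switch)
  expect_equal(length(unique(r_same$isoforms$preferred)), 1)
})

test_that("cell types below 30 cells are excluded before testing", {
  sp29 <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                      n_cells = c(29, 100))
  x29 <- make_x(sp29, seed = 3)
  expect_null(switch_test("g1", x29))   # only one eligible group remains

  sp30 <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                      n_cells = c(30, 100))
  x30 <- make_x(sp30, seed = 3)
  expect_s3_class(switch_test("g1", x30), "switch_result")

  # three groups, one too small: the small one is dropped, testing proceeds
  sp3 <- switch_spec("g1", c("t1", "t2"), c("A", "B", "C"),
                     c(t1 = "A", t2 = "B"), n_cells = c(60, 60, 10))
  x3 <- make_x(sp3, seed = 4)
  r3 <- switch_test("g1", x3)
  expect_false("C" %in% r3$isoforms$preferred)
})

test_that("Bonferroni correction never lowers a p-value and ranking sorts by fold change", {
  sp <- switch_spec("g1", c("t1", "t2"), c("A", "B"), c(t1 = "A", t2 = "B"),
                    effect = 2, noise_sd = 1, n_cells = 50)
  x <- make_x(sp, seed = 5)
  r <- switch_test("g1", x, bonferroni_n = 40)
  expect_true(all(r$isoforms$p_corrected >= r$isoforms$p_raw))

  # two genes in one run
  ex1 <- make_expression(sp, seed = 6)
  sp2 <- switch_spec("g2", c("u1", "u2"), c("A", "B"), c(u1 = "A", u2 = "B"),
                     effect = 5, noise_sd = 0.5, n_cells = 50)
  ex2 <- make_expression(sp2, seed = 7)
  counts <- cbind(ex1$counts, ex2$counts)
  x2 <- expression_matrix(counts, c(ex1$lengths, ex2$lengths),
                          c(ex1$tx2gene, ex2$tx2gene), ex1$metadata)
  fs <- filter_switches(x2)
  expect_setequal(names(fs$results), c("g1", "g2"))
  expect_equal(fs$summary$max_fold_change, sort(fs$summary$max_fold_change,
                                                decreasing = TRUE))
  expect_true(fs$results$g2$switch)
})

test_that("the cross-tissue variant detects tissue-specific usage within a cell type", {
  sp <- switch_spec("g1", c("t1", "t2"), c("A", "A2"), c(t1 = "A", t2 = "A2"),
                    effect = 5, noise_sd = 0.5, n_cells = 60,
                    tissues = c("lung", "blood"))
  ex <- make_expression(sp, seed = 8)
  # both groups are the same cell type in different tissues
  ex$metadata$cell_type <- "monocyte"
  x <- expression_matrix(ex$counts, ex$lengths, ex$tx2gene, ex$metadata)
  r <- cross_tissue_switch("g1", x, "monocyte")
  expect_true(r$switch)
  expect_setequal(r$isoforms$preferred, c("lung", "blood"))
  expect_null(cross_tissue_switch("g1", x, "absent_type"))
  # a single tissue cannot be tested
  ex$metadata$tissue <- "lung"
  x1 <- expression_matrix(ex$counts, ex$lengths, ex$tx2gene, ex$metadata)
  expect_null(cross_tissue_switch("g1", x1, "monocyte"))
})
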