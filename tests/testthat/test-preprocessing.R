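mk_cm <- function(genes, samples, vals) {
  as_count_matrix(matrix(as.integer(vals), length(genes), length(samples),
                         dimnames = list(genes, samples)))
}

test_that("integrate_by_gene intersects genes and concatenates samples", {
  m1 <- mk_cm(c("A", "B", "C"), c("s1", "s2"), 1:6)
  m2 <- mk_cm(c("B", "C", "D"), c("s3", "s4"), 7:12)
  out <- integrate_by_gene(list(m1, m2))
  expect_identical(rownames(out), c("B", "C"))
  expect_identical(colnames(out), c("s1", "s2", "s3", "s4"))
  ## single input: identity; idempotence
  expect_identical(integrate_by_gene(list(m1)), m1)
  expect_identical(integrate_by_gene(list(out)), out)
  ## nested gene sets vs brute-force set oracle
  g <- paste0("G", 1:8)
  mats <- list(mk_cm(g, "x1", 1:8), mk_cm(g[1:6], "x2", 1:6),
               mk_cm(g[2:5], "x3", 1:4))
  expected <- g[g %in% g[1:8] & g %in% g[1:6] & g %in% g[2:5]]
  expect_identical(rownames(integrate_by_gene(mats)), expected)
  expect_error(integrate_by_gene(list(m1, mk_cm("Z", "s9", 5))), "intersection")
  expect_error(integrate_by_gene(list(m1, mk_cm("A", "s1", 5))), "duplicate")
})

test_that("grubbs_test follows the stated formula and flags the planted outlier", {
  x <- c(1:9, 50)
  g <- grubbs_test(x, 0.05)
  ## independent recomputation of G and its critical value
  G_oracle <- max(abs(x - mean(x))) / sd(x)
  t <- qt(1 - 0.05 / (2 * 10), df = 8)
  crit_oracle <- (9 / sqrt(10)) * sqrt(t^2 / (8 + t^2))
  expect_equal(g$G, G_oracle, tolerance = 1e-12)
  expect_equal(g$G_crit, crit_oracle, tolerance = 1e-12)
  expect_equal(g$outlier_index, 10L)
  expect_warning(gz <- grubbs_test(rep(2, 5)), "zero variance")
  expect_equal(gz$G, 0)
  expect_true(is.na(gz$outlier_index))
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
})

test_that("screen_outliers removes exactly the flagged case sample", {
  genes <- paste0("g", 1:4)
  samples <- paste0("s", 1:10)
  cm <- mk_cm(genes, samples, rep(5L, 40))
  meta <- data.frame(sample = samples,
                     diagnosis = c(rep("PD", 7), rep("NC", 3)),
                     batch = 1,
                     age_death = c(70, 72, 71, 69, 73, 74, 120, 70, 71, 72),
                     sex = "M", braak = 3)
  sc <- screen_outliers(cm, meta)
  expect_identical(sc$removed, "s7")
  expect_equal(ncol(sc$counts), 9)
  expect_false("s7" %in% sc$meta$sample)
})

test_that("filter_low_counts uses the interpolated percentile with strict removal", {
  cm <- mk_cm(paste0("g", 1:10), "s1", 1:10)
  out <- filter_low_counts(cm, 15)
  ## threshold 2.35 by hand: genes with totals 1 and 2 removed
  expect_equal(nrow(out), 8)
  expect_false(any(c("g1", "g2") %in% rownames(out)))
  expect_identical(filter_low_counts(cm, 0), cm)
  const <- mk_cm(paste0("g", 1:5), "s1", rep(4L, 5))
  expect_identical(filter_low_counts(const, 15), const)
  ## monotonicity: lower percentile never removes more genes
  counts <- mk_cm(paste0("g", 1:50), paste0("s", 1:3),
                  rpois(150, 20))
  kept <- vapply(c(40, 25, 10, 0), function(p)
    nrow(filter_low_counts(counts, p)), numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("log2_cpm matches the closed form and is scale invariant", {
  cm <- mk_cm(c("a", "b"), "s", c(100L, 999899L))  # libsize 999999
  expect_equal(log2_cpm(cm)[1, 1], log2(100.5), tolerance = 1e-12)
  ## all-zero gene: constant value per sample
  cm2 <- mk_cm(c("a", "b"), c("s1", "s2"), c(0L, 1000L, 0L, 2000L))
  e <- log2_cpm(cm2)
  expect_equal(e[1, 1], log2(0.5 / 1001 * 1e6))
  ## doubling counts and libsizes barely moves values for counts >> prior
  big <- mk_cm(paste0("g", 1:3), "s", c(5000L, 8000L, 7000L))
  d <- abs(log2_cpm(big) - log2_cpm(as_count_matrix(big * 2L)))
  expect_lt(max(d), 1e-3)
  expect_error(log2_cpm(mk_cm("a", "s", 0L)), "library size")
})

test_that("batch_adjust is the identity for a single batch and near-identity without batch effect", {
  set.seed(5)
  cm <- as_count_matrix(matrix(rnbinom(50 * 20, mu = 60, size = 5), 50, 20,
                               dimnames = list(paste0("g", 1:50), paste0("s", 1:20))))
  expect_identical(batch_adjust(cm, rep(1, 20)), cm)
  ## two batches with identical NB parameters: only quantile-midpoint jitter
  ## plus parameter-estimation noise, which shrinks with the batch size
  set.seed(7)
  cm2 <- as_count_matrix(matrix(rnbinom(100 * 200, mu = 20, size = 10), 100, 200,
                                dimnames = list(paste0("g", 1:100),
                                                paste0("s", 1:200))))
  adj <- batch_adjust(cm2, rep(1:2, each = 100))
  expect_lte(mean(abs(adj - cm2)), 1)
  expect_true(all(adj >= 0))
  expect_equal(dim(adj), dim(cm2))
  expect_error(batch_adjust(cm, rep(1:2, each = 10), rep(c("A", "B"), each = 10)),
               "confounded")
})

test_that("batch_adjust removes a planted batch shift and preserves group effects", {
  w <- planted_batch_world(6)
  adj <- batch_adjust(w$cm, w$bat, w$grp)
  expect_lt(abs(batch_gap(adj, w)), 0.2 * abs(batch_gap(w$cm, w)))
  expect_lt(abs(group_lfc(adj, w) - 1), 0.25)
})
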