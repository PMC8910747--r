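test_that("simulate_cohort is deterministic and validates its config", {
  cfg <- simulation_config(n_genes = 80, n_pd1 = 8, n_pd2 = 8, n_nc = 8,
                           n_de_subtype = 10, n_de_disease = 10, seed = 12345)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$counts), c(80L, 24L))
  expect_setequal(names(a$truth$subtype_labels),
                  a$meta$sample[a$meta$diagnosis == "PD"])
  expect_error(simulation_config(n_pd1 = 1), "group sizes")
  expect_error(simulation_config(n_genes = 10, n_de_subtype = 8,
                                 n_de_disease = 8), "disjoint")
  expect_error(simulation_config(corr_block_spec = list(
    list(genes = "NOPE", group = "PDC1", loading = 0.8))), "unknown genes")
})

test_that("counts match NB moments and batches are exchangeable without batch effect", {
  cfg <- simulation_config(n_genes = 30, n_pd1 = 350, n_pd2 = 350, n_nc = 300,
                           n_batches = 2, batch_effect_sd = 0,
                           n_de_subtype = 0, n_de_disease = 0,
                           corr_block_spec = list(), nb_dispersion = 0.2,
                           seed = 11)
  sim <- simulate_cohort(cfg)
  x <- sim$counts
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  ## var = mu + phi mu^2, SE of the sample variance of an NB via 4th moment
  n <- ncol(x)
  for (g in seq_len(nrow(x))) {
    expected <- m[g] + 0.2 * m[g]^2
    mu4 <- mean((x[g, ] - m[g])^4)
    se <- sqrt((mu4 - v[g]^2 * (n - 3) / (n - 1)) / n)
    expect_lt(abs(v[g] - expected), 3 * se + 3 * expected / sqrt(n))
  }
  ## no batch effect: per-gene distributions indistinguishable across batches
  b <- sim$truth$batch_assignment[colnames(x)]
  ks <- suppressWarnings(ks.test(x[1, b == 1], x[1, b == 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("latent-factor blocks give within-block correlation, little leakage", {
  ## homogeneous moderate abundance isolates the latent-factor mechanism:
  ## at a handful of counts the NB/log floor noise dilutes any correlation
  ## (a real effect, noted in the vignette), which would confound this check
  ## 200 genes so the 8-gene block is a small library-size share (CPM couples
  ## genes through the library total otherwise)
  genes <- sprintf("G%04d", 1:200)
  cfg <- simulation_config(n_genes = 200, n_pd1 = 100, n_pd2 = 10, n_nc = 10,
                           batch_effect_sd = 0, n_de_subtype = 0,
                           n_de_disease = 0,
                           nb_mu_log_mean = 5, nb_mu_log_sd = 0.3,
                           nb_dispersion = 0.05,
                           corr_block_spec = list(
                             list(genes = genes[1:8], group = "PDC1",
                                  loading = 0.8)),
                           seed = 21)
  sim <- simulate_cohort(cfg)
  pd1 <- names(sim$truth$subtype_labels)[sim$truth$subtype_labels == "PDC1"]
  E <- log2_cpm(sim$counts[, pd1])
  R <- cor(t(E))
  within <- abs(R[1:8, 1:8][upper.tri(matrix(0, 8, 8))])
  out <- abs(R[1:8, 100:200])
  expect_gte(mean(within), 0.5)
  expect_lte(mean(out), 0.2)
  ## the block is silent in the group without the factor
  pd2 <- names(sim$truth$subtype_labels)[sim$truth$subtype_labels == "PDC2"]
  R2 <- cor(t(log2_cpm(sim$counts[, pd2])))
  expect_lte(mean(abs(R2[1:8, 1:8][upper.tri(matrix(0, 8, 8))])), 0.4)
})

test_that("drug fixture reproduces the sequential filter arithmetic", {
  fx <- make_drug_fixture(42, 16, 5, 2, 10)
  expect_equal(nrow(fx), 42)
  res <- filter_compounds(fx)
  expect_equal(unname(res$log$removed),
               c(16L, 5L, 2L, 10L))
  expect_equal(res$log$final, 9L)
  expect_identical(make_drug_fixture(0, 0, 0, 0, 0),
                   make_drug_fixture(0, 0, 0, 0, 0))
  expect_equal(nrow(make_drug_fixture(0, 0, 0, 0, 0)), 0)
  expect_error(make_drug_fixture(5, -1, 0, 0, 0), "negative")
  expect_error(make_drug_fixture(5, 0, 4, 1, 1), "exceed")
})

test_that("a record both duplicated and unknown-MoA is disposed at the first stage", {
  fx <- make_drug_fixture(5, 1, 1, 0, 1, overlap_duplicate_unknown = TRUE)
  res <- filter_compounds(fx)
  ## the duplicate copy of the unknown-MoA record counts as duplicated only
  expect_equal(unname(res$log$removed), c(1L, 1L, 0L, 1L))
  expect_equal(res$log$final, 2L)
  expect_equal(res$log$initial - sum(res$log$removed), res$log$final)
})

test_that("gene-set fixture plants an enrichable set and sizes the TF list", {
  uni <- paste0("g", 1:20)
  fx <- make_gene_set_fixture(n_sets = 4, set_size_range = c(5, 5),
                              universe = uni, planted_query = uni[1:5],
                              tf_fraction = 0.1, seed = 3)
  tab <- ora(uni[1:5], fx$collection, uni)
  expect_equal(tab$p[tab$set == "PLANTED"], 1 / choose(20, 5))
  fx100 <- make_gene_set_fixture(universe = paste0("g", 1:100),
                                 tf_fraction = 0.1, seed = 4)
  expect_length(fx100$tf_list, 10)
  expect_error(make_gene_set_fixture(set_size_range = c(5, 30),
                                     universe = uni), "exceeds")
})

test_that("without planting, ORA stays null across seeds", {
  uni <- paste0("g", 1:60)
  hits <- vapply(1:40, function(s) {
    fx <- make_gene_set_fixture(n_sets = 8, set_size_range = c(5, 10),
                                universe = uni, seed = s)
    set.seed(s + 500)
    q <- sample(uni, 8)
    min(ora(q, fx$collection, uni)$q)
  }, numeric(1))
  expect_gte(mean(hits > 0.05), 0.95)
})
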