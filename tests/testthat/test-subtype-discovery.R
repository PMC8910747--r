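blobs <- function(n_per, centers, sd = 1, d = 2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(c0)
    matrix(rnorm(n_per * d, c0, sd), n_per, d)))
}

test_that("distance_matrix implements the metrics and their properties", {
  X <- rbind(c(0, 0), c(3, 4))
  expect_equal(distance_matrix(X, "euclidean")[1, 2], 5)
  expect_equal(distance_matrix(X, "manhattan")[1, 2], 7)
  expect_equal(distance_matrix(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  set.seed(2)
  Y <- matrix(rnorm(30), 10, 3)
  for (metric in c("euclidean", "manhattan")) {
    D <- distance_matrix(Y, metric)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (trip in replicate(20, sample(10, 3), simplify = FALSE))
      expect_lte(D[trip[1], trip[3]],
                 D[trip[1], trip[2]] + D[trip[2], trip[3]] + 1e-12)
  }
  expect_error(distance_matrix(Y, "cosine"))
})

test_that("hopkins detects structure and errors on degenerate input", {
  X <- blobs(60, c(0, 10), sd = 1, seed = 3)
  hits <- vapply(1:20, function(s) hopkins(X, m = 20, seed = s)$H, numeric(1))
  expect_gte(mean(hits < 0.25), 0.95)
  expect_error(hopkins(matrix(1, 10, 2), m = 3), "bounding box")
  expect_error(hopkins(matrix(rnorm(20), 10, 2), m = 10), "m < n")
})

test_that("estimate_best_k recovers planted k for 2 and 3 blobs", {
  X2 <- blobs(25, c(0, 12), seed = 4)
  expect_equal(estimate_best_k(X2, 2:6)$best_k, 2L)
  X3 <- blobs(20, c(0, 12, 24), seed = 5)
  bk3 <- estimate_best_k(X3, 2:6)
  expect_equal(bk3$best_k, 3L)
  expect_true(all(bk3$votes %in% 2:6))
  expect_error(estimate_best_k(matrix(1, 10, 2), 2:3), "identical")
  expect_error(estimate_best_k(X2, k_range = 2), "at least 2")
})

test_that("internal_validation matches hand computation and brute force", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  D <- distance_matrix(X)
  iv <- internal_validation(c(1, 1, 2, 2), D)
  expect_equal(iv$silhouette, c(0.8181818, 0.7777778, 0.7777778, 0.8181818),
               tolerance = 1e-6)
  expect_equal(iv$silhouette_avg, mean(iv$silhouette))
  expect_equal(iv$dunn, 4)
  ## degenerate: two distant zero-diameter clusters
  Xd <- matrix(c(0, 0, 9, 9), ncol = 1)
  ivd <- internal_validation(c(1, 1, 2, 2), distance_matrix(Xd))
  expect_equal(ivd$silhouette_avg, 1)
  expect_equal(ivd$dunn, 1e12)
  ## brute-force agreement on random small instances
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:20, 1)
    Xr <- matrix(rnorm(n * 3), n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    Dr <- distance_matrix(Xr)
    ivr <- internal_validation(lab, Dr)
    expect_equal(ivr$silhouette, oracle_silhouette(lab, Dr), tolerance = 1e-12)
    expect_equal(ivr$dunn, oracle_dunn(lab, Dr), tolerance = 1e-12)
  }
  ## random labels on uniform data hover near zero silhouette
  avg <- vapply(1:50, function(s) {
    set.seed(s)
    Xu <- matrix(runif(60), 30, 2)
    internal_validation(sample(1:2, 30, replace = TRUE),
                        distance_matrix(Xu))$silhouette_avg
  }, numeric(1))
  expect_lt(abs(mean(avg)), 0.1)
})

test_that("the portfolio recovers separable blobs and is deterministic", {
  X <- blobs(15, c(0, 20), seed = 6)
  rownames(X) <- paste0("s", 1:30)
  truth <- rep(1:2, each = 15)
  models <- run_portfolio(X, 2, seed = 99)
  ok <- Filter(function(m) m$ok, models)
  expect_gte(length(ok), 10)
  for (m in ok) expect_equal(adjusted_rand_index(m$labels, truth), 1)
  models2 <- run_portfolio(X, 2, seed = 99)
  for (i in seq_along(models))
    expect_identical(models[[i]]$labels, models2[[i]]$labels)
  ## kmeans/manhattan is skipped with a log entry
  expect_true(any(grepl("skipped kmeans/manhattan", attr(models, "log"))))
})

test_that("select_best_model maximizes silhouette with deterministic tie-breaks", {
  mk <- function(alg, sil, dunn) structure(
    list(algorithm = alg, metric = "euclidean", linkage = "centroid", k = 2,
         labels = c(1L, 2L), silhouette_avg = sil, dunn = dunn, seed = 1,
         ok = TRUE), class = "cluster_model")
  expect_equal(select_best_model(list(mk("a", 0.2, 1), mk("b", 0.4, 1),
                                      mk("c", 0.3, 1)))$algorithm, "b")
  expect_equal(select_best_model(list(mk("a", 0.4, 0.05),
                                      mk("b", 0.4, 0.10)))$algorithm, "b")
  expect_equal(select_best_model(list(mk("b", 0.4, 0.1),
                                      mk("a", 0.4, 0.1)))$algorithm, "a")
  expect_error(select_best_model(list()), "no successful model")
})

test_that("portfolio plus selection recovers planted subtypes across seeds", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_cohort(simulation_config(
      n_genes = 150, n_pd1 = 40, n_pd2 = 40, n_nc = 4, n_batches = 1,
      batch_effect_sd = 0, n_de_subtype = 50, n_de_disease = 0,
      lfc_mean = 1.5, lfc_sd = 0.2, corr_block_spec = list(), seed = s))
    pd <- sim$meta$sample[sim$meta$diagnosis == "PD"]
    X <- t(log2_cpm(sim$counts[, pd]))
    X <- scale(X[, apply(X, 2, sd) > 0, drop = FALSE])
    best <- select_best_model(run_portfolio(X, 2, seed = s))
    ari <- adjusted_rand_index(best$labels[names(sim$truth$subtype_labels)],
                               sim$truth$subtype_labels)
    hits <- hits + (ari >= 0.9)
  }
  expect_gte(hits, 9)
})

test_that("compare_clinical reproduces exact test values", {
  meta <- data.frame(sample = paste0("s", 1:8),
                     diagnosis = "PD", batch = 1,
                     age_death = c(1, 2, 70, 71, 3, 4, 72, 73),
                     sex = c("M", "M", "M", "F", "F", "F", "F", "M"),
                     braak = c(1, 1, 1, 2, 2, 2, 2, 1))
  labels <- setNames(rep(c(1L, 2L), each = 4), meta$sample)
  ## x = {1,2}, y = {3,4}: exact two-sided Wilcoxon p = 1/3 by enumeration
  expect_equal(wilcox.test(c(1, 2), c(3, 4), exact = TRUE)$p.value, 1 / 3)
  cc <- compare_clinical(meta, labels)
  expect_true(cc$wilcoxon$exact)
  ## sex table is [[3,1],[1,3]]: Fisher two-sided p = 34/70
  expect_equal(cc$fisher$sex$p, 34 / 70, tolerance = 1e-12)
  expect_equal(cc$fisher$braak$p, 34 / 70, tolerance = 1e-12)
  ## identical groups: all exact p = 1
  meta2 <- meta
  meta2$age_death <- rep(c(60, 61, 62, 63), 2)
  meta2$sex <- rep(c("M", "F", "M", "F"), 2)
  meta2$braak <- rep(c(1, 2, 1, 2), 2)
  cc2 <- compare_clinical(meta2, labels)
  expect_equal(cc2$fisher$sex$p, 1)
  expect_equal(cc2$fisher$braak$p, 1)
  expect_error(compare_clinical(meta, setNames(rep(1L, 8), meta$sample)),
               "exactly 2")
})
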