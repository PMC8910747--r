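path_net <- function() {
  m <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  m[1, 2] <- m[2, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
  build_network(c("A", "B", "C"), m > 0, m)
}

test_that("pearson_matrix matches the textbook formula and handles degeneracy", {
  set.seed(1)
  E <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  R <- pearson_matrix(E)
  for (i in 1:4) for (j in (i + 1):5) {
    x <- E[i, ]; y <- E[j, ]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(R[i, j], r_oracle, tolerance = 1e-12)
  }
  Ed <- rbind(E, g6 = E[1, ])
  expect_equal(pearson_matrix(Ed)["g1", "g6"], 1)
  Ez <- rbind(E, gz = rep(3, 6))
  expect_warning(Rz <- pearson_matrix(Ez), "zero-variance")
  expect_true(all(Rz["gz", colnames(Rz) != "gz"] == 0))
  ## independent genes: mostly small correlations
  set.seed(2)
  Rn <- pearson_matrix(matrix(rnorm(10 * 1000), 10))
  expect_lt(median(abs(Rn[upper.tri(Rn)])), 0.1)
})

test_that("pcit partial correlation follows the closed form", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.8
  R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.5
  ## r_xy.z = (0.8 - 0.25) / 0.75
  expect_equal((0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25)),
               0.55 / 0.75)
  pm <- pcit_mask(R)
  expect_equal(pm$mask, oracle_pcit_mask(R), ignore_attr = TRUE)
})

test_that("pcit_mask equals the brute-force trio oracle and is permutation equivariant", {
  for (s in 1:15) {
    n <- sample(8:12, 1)
    R <- rand_corr(n, n_samples = 6, seed = s)
    pm <- pcit_mask(R)
    expect_equal(unname(pm$mask), unname(oracle_pcit_mask(R)))
    expect_equal(pm$weights, ifelse(pm$mask, R, 0), ignore_attr = TRUE)
    perm <- sample(n)
    pm_p <- pcit_mask(R[perm, perm])
    expect_equal(unname(pm_p$mask), unname(pm$mask[perm, perm]))
  }
  expect_equal(sum(pcit_mask(diag(4))$mask), 0)
  bad <- diag(3); bad[1, 2] <- 2; bad[2, 1] <- 2
  expect_error(pcit_mask(bad), "> 1")
})

test_that("build_network prunes loops and isolated nodes conservatively", {
  n <- 5
  mask <- matrix(FALSE, n, n)
  w <- matrix(0, n, n)
  ## star on 1..4 plus isolated node 5, with a self-loop planted
  for (j in 2:4) { mask[1, j] <- mask[j, 1] <- TRUE; w[1, j] <- w[j, 1] <- 0.5 }
  mask[2, 2] <- TRUE
  net <- build_network(paste0("g", 1:5), mask, w)
  expect_setequal(net$nodes, paste0("g", 1:4))
  expect_identical(net$pruned, "g5")
  expect_equal(length(net$nodes) + length(net$pruned), 5)
  expect_true(all(diag(net$mask) == FALSE))
})

test_that("label propagation finds planted communities", {
  ## two disconnected 4-cliques
  A <- matrix(FALSE, 8, 8)
  A[1:4, 1:4] <- TRUE; A[5:8, 5:8] <- TRUE; diag(A) <- FALSE
  net <- build_network(paste0("g", 1:8), A, A * 0.9)
  cm <- detect_communities(net, seed = 7)
  expect_equal(cm$n_communities, 2)
  expect_equal(length(unique(cm$membership[1:4])), 1)
  ## single clique: one community
  A1 <- matrix(TRUE, 5, 5); diag(A1) <- FALSE
  net1 <- build_network(paste0("g", 1:5), A1, A1 * 0.8)
  expect_equal(detect_communities(net1, seed = 8)$n_communities, 1)
  ## planted partition p_in = .9, p_out = .05, 2 x 15 nodes
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 30; truth <- rep(1:2, each = 15)
    P <- ifelse(outer(truth, truth, "=="), 0.9, 0.05)
    A <- matrix(runif(n * n) < P, n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- FALSE
    net <- build_network(paste0("g", 1:n), A, A * 0.7)
    cm <- detect_communities(net, seed = s)
    keep <- match(net$nodes, paste0("g", 1:n))
    hits <- hits + (adjusted_rand_index(cm$membership, truth[keep]) >= 0.9)
  }
  expect_gte(hits, 9)
})

test_that("centralities match hand computations and the eigen oracle", {
  ct <- centralities(path_net(), weighted = FALSE)
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$betweenness_z, c(-0.5773503, 1.1547005, -0.5773503),
               tolerance = 1e-6)
  expect_equal(ct$authority, c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-8)
  ## star: leaves equal by symmetry
  n <- 6
  mask <- matrix(FALSE, n, n); mask[1, 2:n] <- mask[2:n, 1] <- TRUE
  net <- build_network(paste0("g", 1:n), mask, mask * 0.6)
  ct_star <- centralities(net)
  expect_equal(length(unique(round(ct_star$authority[-1], 10))), 1)
  ## authority equals the dense principal eigenvector on random networks
  for (s in 1:5) {
    R <- rand_corr(20, n_samples = 8, seed = s + 40)
    pm <- pcit_mask(R)
    net <- build_network(rownames(R), pm$mask, pm$weights)
    if (length(net$nodes) < 3) next
    ct <- centralities(net)
    W <- abs(net$weights)
    ev <- eigen(W, symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    ## compare within the dominant component
    dom <- v > 1e-8
    expect_equal(ct$authority[dom] / max(ct$authority[dom]),
                 v[dom] / max(v[dom]), tolerance = 1e-6)
  }
})

test_that("delta_betweenness is antisymmetric and flags hub changes", {
  net <- path_net()
  d0 <- delta_betweenness(net, net)
  expect_true(all(d0$delta == 0))
  ## hub only in net1: path A-B-C vs edgeless pair A-C
  m2 <- matrix(0, 2, 2, dimnames = rep(list(c("A", "C")), 2))
  m2[1, 2] <- m2[2, 1] <- 1
  net2 <- build_network(c("A", "C"), m2 > 0, m2)
  d <- delta_betweenness(net, net2)
  expect_equal(d$gene[1], "B")   # max |delta| first
  dswap <- delta_betweenness(net2, net)
  expect_equal(d$delta, -dswap$delta[match(d$gene, dswap$gene)])
})
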