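## Independent brute-force oracles. These deliberately use naive scalar
## loops and enumeration, separate from the vectorized implementation paths
## they check.

## PCIT by explicit trio enumeration
oracle_pcit_mask <- function(R) {
  n <- nrow(R)
  keep <- matrix(TRUE, n, n)
  partial <- function(a, b, c) {
    den <- sqrt(max((1 - R[a, c]^2) * (1 - R[b, c]^2), 0))
    (R[a, b] - R[a, c] * R[b, c]) / max(den, 1e-12)
  }
  rat <- function(p, d) if (abs(d) > 0) p / d else 0
  for (x in seq_len(n - 1)) for (y in seq.int(x + 1, n)) {
    for (z in seq_len(n)) {
      if (z == x || z == y) next
      tol <- (rat(partial(x, y, z), R[x, y]) +
                rat(partial(x, z, y), R[x, z]) +
                rat(partial(y, z, x), R[y, z])) / 3
      if (abs(R[x, y]) < tol * abs(R[x, z]) &&
          abs(R[x, y]) < tol * abs(R[y, z])) {
        keep[x, y] <- keep[y, x] <- FALSE
        break
      }
    }
  }
  keep & abs(R) > 0 & row(R) != col(R)
}

## Benjamini-Hochberg by literal step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i, 1)
    q_sorted[i] <- val
    prev <- val
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

## silhouette and Dunn by naive loops
oracle_silhouette <- function(labels, D) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) D[i, j]))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(sapply(which(labels == cl), function(j) D[i, j])))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

oracle_dunn <- function(labels, D) {
  cls <- unique(labels)
  diam <- 0
  for (cl in cls) {
    ix <- which(labels == cl)
    for (i in ix) for (j in ix) diam <- max(diam, D[i, j])
  }
  inter <- Inf
  for (a in cls) for (b in cls) {
    if (a == b) next
    for (i in which(labels == a)) for (j in which(labels == b))
      inter <- min(inter, D[i, j])
  }
  if (diam == 0) 1e12 else inter / diam
}

## upper-tail hypergeometric by direct summation
oracle_hyper_upper <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## exhaustive NCT enumeration on a tiny instance (own stat code)
oracle_nct_exact <- function(E1, E2, network_fn) {
  E <- cbind(E1, E2)
  n <- ncol(E); n1 <- ncol(E1)
  strength <- function(W) sum(abs(W[upper.tri(W)]))
  Wo1 <- network_fn(E1); Wo2 <- network_fn(E2)
  S_obs <- abs(strength(Wo1) - strength(Wo2))
  M_obs <- max(abs((Wo1 - Wo2)[upper.tri(Wo1)]))
  combs <- utils::combn(n, n1, simplify = FALSE)
  S_null <- M_null <- numeric(length(combs))
  for (i in seq_along(combs)) {
    a <- combs[[i]]
    Wa <- network_fn(E[, a, drop = FALSE])
    Wb <- network_fn(E[, -a, drop = FALSE])
    S_null[i] <- abs(strength(Wa) - strength(Wb))
    M_null[i] <- max(abs((Wa - Wb)[upper.tri(Wa)]))
  }
  list(S_obs = S_obs, M_obs = M_obs,
       p_S = mean(S_null >= S_obs - 1e-12),
       p_M = mean(M_null >= M_obs - 1e-12))
}

## small helpers shared by tests
rand_corr <- function(n_genes, n_samples = 6, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)), NULL))
  stats::cor(t(E))
}

## two-group NB counts (group A carries the planted lfc), as log2-CPM
nb_log2cpm_groups <- function(n_genes, n_per_group, lfc = numeric(n_genes),
                              mu = 100, phi = 0.2, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  mk <- function(gene_lfc, prefix) {
    m <- matrix(rnbinom(n_genes * n_per_group,
                        mu = rep(mu * 2^gene_lfc, n_per_group),
                        size = 1 / phi),
                n_genes, n_per_group,
                dimnames = list(genes, paste0(prefix, seq_len(n_per_group))))
    m
  }
  cm <- cbind(mk(lfc, "a"), mk(numeric(n_genes), "b"))
  list(expr = log2_cpm(as_count_matrix(cm)),
       group = rep(c("A", "B"), each = n_per_group))
}

## Planted-batch-effect world for the batch-adjustment recovery checks.
## A batch factor hitting every gene equally is indistinguishable from a
## library-size difference, so the 2x shift goes on half the genes and the
## batch gap is measured relative to the unshifted half.
planted_batch_world <- function(seed) {
  set.seed(seed)
  n_g <- 200; n_per <- 40
  lfc <- rep(c(0, 1), each = n_g / 2)          # planted group effect, log2
  shifted <- rep(c(TRUE, FALSE), n_g / 2)      # genes carrying the batch shift
  grp <- rep(rep(c("A", "B"), each = n_per / 2), 2)
  bat <- rep(c(1, 2), each = n_per)
  mu <- outer(rep(80, n_g), rep(1, 2 * n_per)) *
    2^outer(lfc, as.numeric(grp == "A"))
  mu[shifted, bat == 2] <- mu[shifted, bat == 2] * 2
  cm <- as_count_matrix(matrix(rnbinom(length(mu), mu = mu, size = 5), n_g,
                               dimnames = list(paste0("g", 1:n_g),
                                               paste0("s", 1:(2 * n_per)))))
  list(cm = cm, bat = bat, grp = grp, lfc = lfc, shifted = shifted)
}

batch_gap <- function(m, w) {
  d <- log(rowMeans(m[, w$bat == 2] + 0.5)) -
    log(rowMeans(m[, w$bat == 1] + 0.5))
  mean(d[w$shifted]) - mean(d[!w$shifted])
}

group_lfc <- function(m, w) {
  de <- log2(rowMeans(m[, w$grp == "A"] + 0.5)) -
    log2(rowMeans(m[, w$grp == "B"] + 0.5))
  mean(de[w$lfc == 1]) - mean(de[w$lfc == 0])
}
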