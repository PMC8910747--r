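## Subtype discovery: clusterability (Hopkins), best-k vote, a portfolio of
## clustering algorithms over distance metrics, internal validity scoring
## (average silhouette width, Dunn index), model selection, and comparison of
## clinical variables between the selected clusters.

#' Distance matrix under a named metric
#'
#' @param X samples x features numeric matrix.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return dense symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(X, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in X")
  as.matrix(stats::dist(X, method = metric))
}

#' Hopkins statistic for clustering tendency
#'
#' Compares nearest-neighbour distances of `m` sampled data points (to the
#' rest of the data) with those of `m` uniform points drawn in the data's
#' bounding box. Convention: H near 0 indicates clusterable data, H near 0.5
#' indicates spatial randomness.
#'
#' @param X samples x features matrix.
#' @param m subsample size (default `min(n - 1, ceiling(n / 10))`, at least 1).
#' @param seed RNG seed.
#' @param threshold verdict threshold: clusterable iff H < threshold.
#' @return list `H`, `m`, `seed`, `clusterable`.
#' @export
hopkins <- function(X, m = NULL, seed = 12345, threshold = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- m %||% max(1L, min(n - 1L, ceiling(n / 10)))
  if (m < 1 || m >= n) stop("need 1 <= m < n")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  if (all(hi - lo < .Machine$double.eps)) stop("degenerate (zero-extent) bounding box")
  set.seed(seed)
  idx <- sample.int(n, m)
  U <- matrix(stats::runif(m * ncol(X), rep(lo, each = m), rep(hi, each = m)), m)
  nn_to <- function(P, Q) {        # for each row of P, min distance to rows of Q
    vapply(seq_len(nrow(P)), function(i) {
      d2 <- colSums((t(Q) - P[i, ])^2)
      sqrt(min(d2))
    }, numeric(1))
  }
  w <- vapply(seq_along(idx), function(i) {
    d2 <- colSums((t(X[-idx[i], , drop = FALSE]) - X[idx[i], ])^2)
    sqrt(min(d2))
  }, numeric(1))
  u <- nn_to(U, X)
  H <- sum(w) / (sum(u) + sum(w))
  list(H = H, m = m, seed = seed, clusterable = H < threshold)
}

## within-cluster sum of squares (euclidean, on the feature matrix)
within_ss <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(ix) {
    Xi <- X[ix, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, numeric(1)))
}

#' Estimate the best number of clusters by an index ensemble vote
#'
#' A reference agglomerative clustering (average linkage by default) is cut
#' at each candidate k and scored by average silhouette, Calinski-Harabasz,
#' Dunn, Davies-Bouldin, and the Hartigan within-SS elbow rule; the winner is
#' the majority vote over per-index best k, ties broken toward the smallest k.
#'
#' @param X samples x features matrix.
#' @param k_range candidate k values (>= 2 entries, within `[2, n-1]`).
#' @param indices subset of `c("silhouette","ch","dunn","db","hartigan")`.
#' @param metric distance metric for the reference tree and silhouette/Dunn.
#' @param linkage hclust linkage for the reference tree.
#' @param seed unused by the deterministic reference path; kept for interface
#'   stability.
#' @return list `k_range`, `votes` (per-index best k), `best_k`, `tie_break`.
#' @export
estimate_best_k <- function(X, k_range = 2:10,
                            indices = c("silhouette", "ch", "dunn", "db", "hartigan"),
                            metric = "euclidean", linkage = "average",
                            seed = 12345) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2) stop("need at least 2 candidate k")
  if (min(k_range) < 2 || max(k_range) > n - 1) stop("k_range outside [2, n-1]")
  D <- distance_matrix(X, metric)
  if (max(D) < .Machine$double.eps) stop("degenerate geometry: all points identical")
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  ks_ext <- c(k_range, max(k_range) + 1L)
  cuts <- lapply(ks_ext, function(k) stats::cutree(tree, k))
  names(cuts) <- ks_ext
  W <- vapply(cuts, function(l) within_ss(X, l), numeric(1))

  score_one <- function(k) {
    l <- cuts[[as.character(k)]]
    iv <- internal_validation(l, D)
    centroids <- do.call(rbind, lapply(split(seq_len(n), l), function(ix)
      colMeans(X[ix, , drop = FALSE])))
    sizes <- table(l)
    Bss <- sum(sizes * rowSums(sweep(centroids, 2, colMeans(X))^2))
    Wss <- W[[as.character(k)]]
    ch <- (Bss / (k - 1)) / (Wss / (n - k))
    ## Davies-Bouldin with euclidean centroid scatter
    s_i <- vapply(seq_len(k), function(i) {
      ix <- which(l == i)
      mean(sqrt(rowSums(sweep(X[ix, , drop = FALSE], 2, centroids[i, ])^2)))
    }, numeric(1))
    cd <- as.matrix(stats::dist(centroids))
    db <- mean(vapply(seq_len(k), function(i) {
      max(vapply(seq_len(k)[-i], function(j) (s_i[i] + s_i[j]) / max(cd[i, j], 1e-12),
                 numeric(1)))
    }, numeric(1)))
    c(silhouette = iv$silhouette_avg, dunn = iv$dunn, ch = ch, db = db)
  }
  sc <- vapply(k_range, score_one, numeric(4))
  colnames(sc) <- k_range
  hartigan_best <- {
    H <- vapply(seq_along(k_range), function(i) {
      k <- k_range[i]
      Wk <- W[[as.character(k)]]; Wk1 <- W[[as.character(k + 1L)]]
      if (Wk1 <= 0) 0 else (Wk / Wk1 - 1) * (n - k - 1)
    }, numeric(1))
    ok <- which(H <= 10)
    if (length(ok)) k_range[min(ok)] else k_range[which.max(-H)]
  }
  votes <- c(silhouette = k_range[which.max(sc["silhouette", ])],
             ch = k_range[which.max(sc["ch", ])],
             dunn = k_range[which.max(sc["dunn", ])],
             db = k_range[which.min(sc["db", ])],
             hartigan = hartigan_best)
  votes <- votes[names(votes) %in% indices]
  tab <- table(factor(votes, levels = k_range))
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k_range = k_range, votes = votes, best_k = min(winners),
       tie_break = length(winners) > 1, scores = sc)
}

#' Internal cluster validity: silhouette and Dunn
#'
#' Silhouette: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean
#' intra-cluster distance and `b` the minimum over other clusters of the mean
#' distance; singletons get `s = 0`. Dunn: minimum inter-cluster point-pair
#' distance over maximum intra-cluster diameter (zero diameter guarded with a
#' large sentinel, 1e12).
#'
#' @param labels integer cluster labels.
#' @param D square distance matrix.
#' @return list `silhouette_avg`, `dunn`, `silhouette` (per sample).
#' @export
internal_validation <- function(labels, D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need >= 2 non-empty clusters")
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { sil[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(c2)
      mean(D[i, labels == c2]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  max_diam <- max(vapply(cl, function(c1) {
    ix <- which(labels == c1)
    if (length(ix) < 2) 0 else max(D[ix, ix])
  }, numeric(1)))
  min_inter <- min(vapply(utils::combn(seq_along(cl), 2, simplify = FALSE),
                          function(p) {
    min(D[labels == cl[p[1]], labels == cl[p[2]], drop = FALSE])
  }, numeric(1)))
  dunn <- if (max_diam < .Machine$double.eps) 1e12 else min_inter / max_diam
  list(silhouette_avg = mean(sil), dunn = dunn, silhouette = sil)
}

fit_one_model <- function(X, D, k, algorithm, metric, linkage, seed) {
  n <- nrow(X)
  set.seed(seed)
  labels <- suppressWarnings(switch(algorithm,
    kmeans = {
      if (metric != "euclidean") return(NULL)   # skipped pair, logged upstream
      stats::kmeans(X, centers = k, nstart = 25, iter.max = 100)$cluster
    },
    hierarchical_kmeans = {
      tree <- stats::hclust(stats::as.dist(D), method = linkage)
      init <- stats::cutree(tree, k)
      centers <- do.call(rbind, lapply(split(seq_len(n), init), function(ix)
        colMeans(X[ix, , drop = FALSE])))
      stats::kmeans(X, centers = centers, iter.max = 100)$cluster
    },
    hclust = {
      tree <- stats::hclust(stats::as.dist(D), method = linkage)
      stats::cutree(tree, k)
    },
    pam = cluster::pam(stats::as.dist(D), k, cluster.only = TRUE),
    clara = {
      sampsize <- min(n, max(40 + 2 * k, ceiling(n / 5)))
      cluster::clara(X, k, metric = metric, samples = 5,
                     sampsize = sampsize, rngR = TRUE)$clustering
    },
    agnes = {
      ## agnes has no centroid linkage; average linkage used for this backend
      ag <- cluster::agnes(stats::as.dist(D), method = "average")
      stats::cutree(stats::as.hclust(ag), k)
    },
    diana = {
      di <- cluster::diana(stats::as.dist(D))
      stats::cutree(stats::as.hclust(di), k)
    },
    fuzzy = {
      fa <- cluster::fanny(stats::as.dist(D), k, memb.exp = 1.2)
      apply(fa$membership, 1, which.max)
    },
    stop("unknown algorithm: ", algorithm)))
  as.integer(labels)
}

#' Run the clustering-algorithm portfolio
#'
#' Fits up to 8 algorithms (`kmeans`, `hierarchical_kmeans`, `pam`, `clara`,
#' `agnes`, `diana`, `fuzzy`, `hclust`) over the requested distance metrics;
#' each fitted model carries its average silhouette and Dunn index computed
#' on the model's own metric. Unsupported pairs (k-means with a non-euclidean
#' metric) are skipped with a log entry; a model whose refinement yields an
#' empty cluster is re-seeded once and then reported failed.
#'
#' @param X samples x features matrix (rows are the units being clustered).
#' @param k number of clusters (>= 2).
#' @param algorithms character vector of algorithm names.
#' @param metrics distance metrics to cross with the algorithms.
#' @param linkage linkage for tree-based algorithms (default `"centroid"`,
#'   applied through the generalized Lance-Williams update on the chosen
#'   metric's distances).
#' @param min_cluster_size smallest admissible cluster (default 4, the
#'   minimum group size usable by the downstream correlation-network and
#'   clinical-comparison stages). Average-silhouette selection otherwise
#'   rewards pathological n-1/1 splits under weak separation; models
#'   producing a smaller cluster are re-seeded once and then reported failed.
#' @param seed master seed; each fit gets a derived seed.
#' @return list of model records (class `cluster_model`): `algorithm`,
#'   `metric`, `linkage`, `k`, `labels`, `silhouette_avg`, `dunn`, `seed`,
#'   `ok`, plus a `log` attribute of skip/failure messages.
#' @export
run_portfolio <- function(X, k,
                          algorithms = c("kmeans", "hierarchical_kmeans", "pam",
                                         "clara", "agnes", "diana", "fuzzy",
                                         "hclust"),
                          metrics = c("euclidean", "manhattan"),
                          linkage = "centroid", min_cluster_size = 4,
                          seed = 12345) {
  X <- as.matrix(X)
  if (k < 2) stop("k must be >= 2")
  min_cluster_size <- min(min_cluster_size, floor(nrow(X) / k))
  Ds <- lapply(stats::setNames(metrics, metrics), function(m) distance_matrix(X, m))
  models <- list(); log <- character(0)
  i <- 0L
  for (alg in algorithms) for (met in metrics) {
    i <- i + 1L
    if (alg == "kmeans" && met != "euclidean") {
      log <- c(log, sprintf("skipped %s/%s: metric unsupported", alg, met))
      next
    }
    fit_seed <- derive_seed(seed, i)
    labels <- tryCatch(fit_one_model(X, Ds[[met]], k, alg, met, linkage, fit_seed),
                       error = function(e) e)
    retry <- function(l) inherits(l, "error") || is.null(l) ||
      length(unique(l)) != k || min(table(l)) < min_cluster_size
    if (retry(labels)) {
      fit_seed <- derive_seed(seed, i + 10000L)
      labels <- tryCatch(fit_one_model(X, Ds[[met]], k, alg, met, linkage, fit_seed),
                         error = function(e) e)
    }
    if (retry(labels)) {
      log <- c(log, sprintf("failed %s/%s: %s", alg, met,
                            if (inherits(labels, "error")) conditionMessage(labels)
                            else "empty or undersized cluster"))
      models[[length(models) + 1L]] <- structure(
        list(algorithm = alg, metric = met, linkage = linkage, k = k,
             labels = NULL, silhouette_avg = NA_real_, dunn = NA_real_,
             seed = fit_seed, ok = FALSE), class = "cluster_model")
      next
    }
    names(labels) <- rownames(X)
    iv <- internal_validation(labels, Ds[[met]])
    models[[length(models) + 1L]] <- structure(
      list(algorithm = alg, metric = met, linkage = linkage, k = k,
           labels = labels, silhouette_avg = iv$silhouette_avg,
           dunn = iv$dunn, seed = fit_seed, ok = TRUE),
      class = "cluster_model")
  }
  attr(models, "log") <- log
  models
}

#' Select the best cluster model by internal validity
#'
#' Maximum average silhouette width; ties broken by larger Dunn index, then
#' lexicographic algorithm name (deterministic).
#'
#' @param models list of `cluster_model` records from [run_portfolio()].
#' @return the winning `cluster_model`.
#' @export
select_best_model <- function(models) {
  ok <- Filter(function(m) isTRUE(m$ok), models)
  if (!length(ok)) stop("no successful model")
  sil <- vapply(ok, `[[`, numeric(1), "silhouette_avg")
  dun <- vapply(ok, `[[`, numeric(1), "dunn")
  alg <- vapply(ok, `[[`, character(1), "algorithm")
  ord <- order(-sil, -dun, alg)
  ok[[ord[1]]]
}

#' Compare clinical variables between two clusters
#'
#' Wilcoxon rank-sum on age at death (exact for combined n <= 50 without
#' ties, normal approximation with continuity and tie correction otherwise);
#' Fisher exact tests on sex (2x2) and Braak stage (2xR; exact for small
#' tables, Monte Carlo with >= 1e5 draws and a fixed seed otherwise).
#'
#' @param meta SampleTable.
#' @param labels named integer vector of cluster labels (exactly 2 clusters),
#'   names = sample ids.
#' @param seed seed for Monte-Carlo Fisher p-values.
#' @return list `wilcoxon`, `fisher`, `summaries`, `skipped`.
#' @export
compare_clinical <- function(meta, labels, seed = 12345) {
  if (length(unique(labels)) != 2) stop("labels must define exactly 2 clusters")
  meta <- meta[match(names(labels), meta$sample), , drop = FALSE]
  cl <- factor(labels)
  out <- list(wilcoxon = NULL, fisher = list(), summaries = list(),
              skipped = character(0))
  enough <- function(v) all(tapply(!is.na(v), cl, sum) >= 3)
  if (!is.null(meta$age_death) && enough(meta$age_death)) {
    x <- meta$age_death[cl == levels(cl)[1]]
    y <- meta$age_death[cl == levels(cl)[2]]
    exact <- (length(x) + length(y) <= 50) && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    out$wilcoxon <- list(variable = "age_death", W = unname(wt$statistic),
                         p = wt$p.value, exact = exact)
    out$summaries$age_death <- tapply(meta$age_death, cl, mean, na.rm = TRUE)
  } else out$skipped <- c(out$skipped, "age_death")
  fisher_on <- function(v, name) {
    tab <- table(cl, v)
    if (any(dim(tab) < 2)) {
      out$skipped <<- c(out$skipped, name)
      return(invisible(NULL))
    }
    small <- sum(tab) <= 200 && ncol(tab) <= 7
    ft <- if (small) stats::fisher.test(tab) else {
      set.seed(seed)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
    }
    out$fisher[[name]] <<- list(variable = name, table = tab, p = ft$p.value,
                                exact = small)
  }
  if (!is.null(meta$sex) && enough(meta$sex)) fisher_on(meta$sex, "sex")
  else out$skipped <- c(out$skipped, "sex")
  if (!is.null(meta$braak) && enough(meta$braak)) fisher_on(meta$braak, "braak")
  else out$skipped <- c(out$skipped, "braak")
  out
}
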