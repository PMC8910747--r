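## Count preprocessing: gene-wise integration of study matrices, demographic
## outlier screening (Grubbs), low-count filtering at a percentile of per-gene
## totals, NB-regression quantile-mapping batch adjustment, and log2-CPM.

#' Integrate count matrices by gene
#'
#' Gene set = intersection of the inputs' gene sets in first-input order;
#' sample columns are concatenated.
#'
#' @param matrices list of CountMatrix objects with globally unique samples.
#' @return CountMatrix over the common genes.
#' @export
integrate_by_gene <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  matrices <- lapply(matrices, as_count_matrix)
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples)) stop("duplicate sample id across inputs")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("empty gene intersection")
  common <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% common]
  do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Grubbs test for a single outlier
#'
#' Two-sided single-pass Grubbs test: G = max |x - mean| / sd, compared to
#' the critical value at level `alpha` based on the Student-t quantile at
#' alpha/(2n) on n-2 degrees of freedom.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `G`, `G_crit`, `outlier_index` (NA if none), `alpha`,
#'   `n`, `zero_variance` flag.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s < .Machine$double.eps) {
    warning("zero variance: no outlier detectable")
    return(list(G = 0, G_crit = NA_real_, outlier_index = NA_integer_,
                alpha = alpha, n = n, zero_variance = TRUE))
  }
  dev <- abs(values - mean(values)) / s
  G <- max(dev)
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  G_crit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
  list(G = G, G_crit = G_crit,
       outlier_index = if (G > G_crit) which.max(dev) else NA_integer_,
       alpha = alpha, n = n, zero_variance = FALSE)
}

#' Screen demographic outliers and drop the flagged sample
#'
#' Runs a single-pass Grubbs test on one metadata variable within a subgroup
#' (default: age at death among cases) and removes the flagged sample from
#' counts and metadata. Iterative removal is available behind `iterate`.
#'
#' @param counts CountMatrix.
#' @param meta SampleTable.
#' @param variable metadata column to screen.
#' @param subset logical vector or NULL; which samples to screen (default PD).
#' @param alpha level for the Grubbs test.
#' @param iterate if TRUE, repeat until no outlier remains.
#' @return list `counts`, `meta`, `removed` (sample ids), `tests`.
#' @export
screen_outliers <- function(counts, meta, variable = "age_death",
                            subset = NULL, alpha = 0.05, iterate = FALSE) {
  meta <- as_sample_table(meta, counts)
  removed <- character(0); tests <- list()
  repeat {
    keep <- !(meta$sample %in% removed)
    sub <- if (is.null(subset)) meta$diagnosis == "PD" else subset[match(meta$sample, meta$sample)]
    idx <- which(keep & sub & !is.na(meta[[variable]]))
    if (length(idx) < 3) break
    gt <- grubbs_test(meta[[variable]][idx], alpha)
    tests[[length(tests) + 1L]] <- gt
    if (is.na(gt$outlier_index)) break
    removed <- c(removed, meta$sample[idx[gt$outlier_index]])
    if (!iterate) break
  }
  keep <- !(meta$sample %in% removed)
  list(counts = counts[, meta$sample[keep], drop = FALSE],
       meta = meta[keep, , drop = FALSE],
       removed = removed, tests = tests)
}

#' Remove genes with low total counts
#'
#' The threshold is the type-7 (linear interpolation) percentile of per-gene
#' total counts; genes strictly below it are removed.
#'
#' @param counts CountMatrix.
#' @param percentile percentile in \[0, 100).
#' @return filtered CountMatrix.
#' @export
filter_low_counts <- function(counts, percentile = 15) {
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  totals <- rowSums(counts)
  thr <- stats::quantile(totals, percentile / 100, type = 7, names = FALSE)
  keep <- totals >= thr
  if (!any(keep)) stop("all genes removed by low-count filter")
  counts[keep, , drop = FALSE]
}

## Method-of-moments NB dispersion given per-observation means:
## Var(x/mu) = 1/mu + phi, so phi = mean[(x/mu - 1)^2] - mean[1/mu].
## Floored at 1e-8 so the quantile map degrades gracefully to near-Poisson.
nb_dispersion_mom <- function(x, mu) {
  ok <- mu > 0
  if (sum(ok) < 2) return(1e-8)
  max(mean((x[ok] / mu[ok] - 1)^2) - mean(1 / mu[ok]), 1e-8)
}

#' Adjust batch effects by negative-binomial quantile mapping
#'
#' Per gene, batch-specific NB distributions (library-size-offset means,
#' moment dispersions) are estimated; the batch-free target keeps the
#' biological group effect but drops the batch factor. Each observed count is
#' mapped through its batch CDF midpoint onto the target quantile, giving
#' integer counts >= 0. A faithful simplification of the NB-regression
#' quantile-mapping idea (no empirical-Bayes dispersion shrinkage).
#'
#' @param counts CountMatrix.
#' @param batch per-sample batch labels.
#' @param group optional per-sample biological group labels to preserve.
#' @return adjusted CountMatrix (same dimensions).
#' @export
batch_adjust <- function(counts, batch, group = NULL) {
  counts <- as_count_matrix(counts)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(counts))
  batches <- unique(batch)
  if (length(batches) < 2) return(counts)
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  if (!is.null(group)) {
    group <- as.character(group)
    tab <- table(batch, group)
    if (all(rowSums(tab > 0) == 1))
      stop("batch is confounded 1:1 with group; cannot adjust")
  } else {
    group <- rep("all", ncol(counts))
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size")
  sf <- libsize / mean(libsize)

  out <- counts
  eps <- 1e-10
  grp_levels <- unique(group)
  for (gi in seq_len(nrow(counts))) {
    x <- as.numeric(counts[gi, ])
    ## group effect pooled across batches (library-size offset regression)
    alpha_c <- vapply(grp_levels, function(g) {
      j <- group == g
      sum(x[j]) / sum(sf[j])
    }, numeric(1))
    names(alpha_c) <- grp_levels
    mu_free <- alpha_c[group] * sf          # batch-free expected means
    if (all(mu_free <= 0)) next
    ## batch factors as residual ratios against the batch-free fit
    beta_b <- vapply(batches, function(b) {
      j <- batch == b
      d <- sum(mu_free[j])
      if (d > 0) sum(x[j]) / d else 1
    }, numeric(1))
    names(beta_b) <- batches
    beta_b[!is.finite(beta_b) | beta_b <= 0] <- 1
    mu_full <- mu_free * beta_b[batch]      # with-batch expected means
    phi_pool <- nb_dispersion_mom(x, mu_full)
    for (b in batches) {
      j <- which(batch == b)
      phi_b <- nb_dispersion_mom(x[j], mu_full[j])
      mu_src <- pmax(mu_full[j], eps)
      mu_tgt <- pmax(mu_free[j], eps)
      u <- stats::pnbinom(x[j] - 1, mu = mu_src, size = 1 / phi_b) +
        0.5 * stats::dnbinom(x[j], mu = mu_src, size = 1 / phi_b)
      u <- pmin(pmax(u, eps), 1 - eps)
      xq <- stats::qnbinom(u, mu = mu_tgt, size = 1 / phi_pool)
      out[gi, j] <- as.integer(pmax(0, round(xq)))
    }
  }
  out
}

#' log2 counts per million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)` with the library
#' size taken as the per-sample column sum.
#'
#' @param counts CountMatrix.
#' @param prior pseudocount (default 0.5).
#' @return numeric matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, prior = 0.5) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size")
  t(log2(t(counts + prior) / (libsize + 2 * prior) * 1e6))
}
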