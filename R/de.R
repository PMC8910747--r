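## Moderated-t differential expression on log2-CPM: gene-wise ordinary least
## squares, empirical-Bayes shrinkage of the residual variances toward a
## scaled-F prior estimated by digamma/trigamma moment matching, moderated
## t-statistics, BH-FDR, and DEG calling at q <= 0.01.

#' Fit a gene-wise linear model
#'
#' Ordinary least squares per gene on a shared design matrix.
#'
#' @param E genes x samples expression matrix (log2-CPM).
#' @param design samples x covariates design matrix (full column rank).
#' @param coef name or index of the coefficient of interest (default: last
#'   column, conventionally the group indicator).
#' @return list `coefficients` (genes x covariates), `beta` (coefficient of
#'   interest), `sigma2` (residual variances), `df_residual`,
#'   `stdev_unscaled` (sqrt of the coefficient's (X'X)^-1 diagonal entry),
#'   `coef`.
#' @export
fit_linear_model <- function(E, design, coef = ncol(design)) {
  E <- as.matrix(E); design <- as.matrix(design)
  n <- ncol(E); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  qrX <- qr(design)
  if (qrX$rank < p) stop("design is rank deficient")
  if (n <= p) stop("need more samples than covariates")
  B <- t(qr.coef(qrX, t(E)))           # genes x p
  fitted <- B %*% t(design)
  res <- E - fitted
  d <- n - p
  sigma2 <- rowSums(res^2) / d
  XtXinv <- chol2inv(qr.R(qrX))
  ci <- if (is.character(coef)) match(coef, colnames(design)) else coef
  if (is.na(ci) || ci < 1 || ci > p) stop("unknown coefficient")
  list(coefficients = B, beta = B[, ci], sigma2 = sigma2, df_residual = d,
       stdev_unscaled = sqrt(XtXinv[ci, ci]), coef = ci)
}

## Newton inversion of the trigamma function (monotone decreasing on (0, inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' The prior (d0, s0^2) is estimated by matching the first two moments of
#' log(s_g^2) to a scaled-F distribution (digamma/trigamma inversion). The
#' posterior variance `(d0*s0^2 + d*s_g^2) / (d0 + d)` yields a moderated t
#' on `d0 + d` degrees of freedom. When the variance ensemble is consistent
#' with a point-mass prior the estimate degenerates to d0 = Inf (pooled
#' variance) with a warning.
#'
#' @param fit output of [fit_linear_model()].
#' @param proportion assumed prior proportion of DE genes for the log-odds B.
#' @return object of class `de_result`: per-gene `logFC`, `t`, `p`, `q`,
#'   `B`, `deg` (at alpha 0.01) plus `d0`, `s0_2`, `df_total`.
#' @export
ebayes_moderate <- function(fit, proportion = 0.01) {
  s2 <- fit$sigma2
  d <- fit$df_residual
  G <- length(s2)
  if (G < 10) stop("empirical Bayes moment estimation needs >= 10 genes")
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok)   # population moment
  rhs <- evar - trigamma(d / 2)
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    warning("variance prior degenerate; using pooled variance (d0 = Inf)")
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_2 + d * s2) / (d0 + d) else rep(s0_2, G)
  df_total <- d0 + d
  tstat <- fit$beta / (sqrt(s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = min(df_total, 1e6))
  q <- bh_adjust(p)
  ## log-odds of DE: posterior odds of beta ~ N(0, v0 * s2_post) vs beta = 0,
  ## with v0 (in unscaled-variance units) from a moment estimate on the
  ## top-|t| genes; descriptive output only, never used for DEG calls.
  u2 <- fit$stdev_unscaled^2
  ntop <- max(1L, ceiling(proportion * G))
  top <- order(abs(tstat), decreasing = TRUE)[seq_len(ntop)]
  v0 <- max(mean(fit$beta[top]^2 / s2_post[top]) - u2, 0)
  r <- (u2 + v0) / u2
  nu <- min(df_total, 1e6)
  B <- log(proportion / (1 - proportion)) - 0.5 * log(r) +
    (nu + 1) / 2 * (log(tstat^2 + nu) - log(tstat^2 / r + nu))
  structure(list(logFC = fit$beta, t = tstat, p = p, q = q, B = B,
                 deg = q <= 0.01, d0 = d0, s0_2 = s0_2, df_total = df_total,
                 genes = names(fit$beta)),
            class = "de_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\] (no NaN).
#' @return q-values, monotone in sorted p, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NaN/NA p-values")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param result a `de_result`.
#' @param alpha FDR threshold (default 0.01).
#' @return character vector of gene ids with q <= alpha.
#' @export
call_degs <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "de_result"))
  result$genes[result$q <= alpha]
}

#' Two-set Venn partition
#'
#' @param setA,setB character vectors.
#' @return list `unique_A`, `unique_B`, `common`.
#' @export
venn_partition <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  list(unique_A = setdiff(setA, setB),
       unique_B = setdiff(setB, setA),
       common = intersect(setA, setB))
}

#' Convenience two-group differential expression
#'
#' Builds the intercept + group-indicator design for two sample groups and
#' runs the OLS + empirical-Bayes path. logFC is group1 minus group2.
#'
#' @param E genes x samples log2-CPM matrix.
#' @param group per-sample labels with exactly two levels.
#' @param level1,level2 the two levels to contrast (`level1 - level2`);
#'   defaults to the levels in first-appearance order.
#' @param covariates optional samples x extra-covariates matrix.
#' @return a `de_result`.
#' @export
de_contrast <- function(E, group, level1 = NULL, level2 = NULL,
                        covariates = NULL) {
  lev <- unique(as.character(group))
  level1 <- level1 %||% lev[1]
  level2 <- level2 %||% lev[2]
  keep <- group %in% c(level1, level2)
  E <- E[, keep, drop = FALSE]
  g <- as.integer(group[keep] == level1)
  design <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) design <- cbind(design, covariates[keep, , drop = FALSE])
  fit <- fit_linear_model(E, design, coef = "group")
  fit$beta <- stats::setNames(fit$beta, rownames(E))
  ebayes_moderate(fit)
}
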