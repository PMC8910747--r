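## Permutation network comparison: global strength invariance, structure
## invariance (maximum edge difference), and per-edge strength invariance
## with BH-FDR, plus construction of the differential network.

#' Global strength of a network
#'
#' Sum of absolute edge weights over unique undirected edges.
#' @param net a `gene_network` (or a symmetric weight matrix).
#' @return non-negative scalar.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "gene_network")) net$weights else as.matrix(net)
  if (!length(W)) return(0)
  sum(abs(W[upper.tri(W)]))
}

## default network function for NCT: pearson -> PCIT, full-matrix form
pcit_weights <- function(E) {
  pcit_mask(pearson_matrix(E))$weights
}

#' Network comparison test between two groups
#'
#' The observed group networks are rebuilt by `network_fn` (default Pearson
#' correlation + PCIT) and compared by (i) the absolute global strength
#' difference S, (ii) the maximum absolute edge difference M, and (iii)
#' per-edge absolute differences over the union edge set. Null distributions
#' come from permuting the sample-to-group assignment (group sizes preserved)
#' and rebuilding both networks each time; p-values use the plus-one
#' convention `(1 + #{perm >= obs}) / (1 + n_perm)` and are therefore never
#' zero. With `exhaustive = TRUE` (or when all distinct assignments number at
#' most `n_perm`) every assignment is enumerated and p-values are exact
#' proportions over the enumeration (which includes the observed assignment).
#'
#' @param E1,E2 genes x samples expression matrices (same gene set, >= 4
#'   samples each).
#' @param n_perm number of permutations (warning below 100).
#' @param seed RNG seed.
#' @param network_fn function(E) -> symmetric weight matrix.
#' @param exhaustive force exhaustive enumeration of assignments.
#' @return object of class `nct_result`: `S_obs`, `p_S`, `M_obs`, `p_M`,
#'   `edges` (gene1, gene2, diff, p, q), `n_perm`, `seed`, `exhaustive`.
#' @export
nct <- function(E1, E2, n_perm = 1000, seed = 12345,
                network_fn = pcit_weights, exhaustive = FALSE) {
  E1 <- as.matrix(E1); E2 <- as.matrix(E2)
  if (!identical(rownames(E1), rownames(E2))) stop("gene sets must match")
  if (ncol(E1) < 4 || ncol(E2) < 4) stop("both groups need >= 4 samples")
  if (n_perm < 100) warning("n_perm < 100: p-values will be coarse")
  genes <- rownames(E1)
  W1 <- network_fn(E1); W2 <- network_fn(E2)
  D <- W1 - W2
  S_obs <- abs(global_strength(W1) - global_strength(W2))
  ut <- upper.tri(W1)
  M_obs <- if (any(ut)) max(abs(D[ut])) else 0
  edge_sel <- which(ut & (W1 != 0 | W2 != 0), arr.ind = TRUE)
  obs_edge <- abs(D[edge_sel])

  E <- cbind(E1, E2)
  n <- ncol(E); n1 <- ncol(E1)
  n_all <- choose(n, n1)
  use_exhaustive <- exhaustive || n_all <= n_perm
  assignments <- if (use_exhaustive) {
    utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
  eps <- 1e-12
  ge_S <- 0; ge_M <- 0
  ge_edge <- rep(0, length(obs_edge))
  for (a in assignments) {
    Wa <- network_fn(E[, a, drop = FALSE])
    Wb <- network_fn(E[, -a, drop = FALSE])
    Dp <- Wa - Wb
    Sp <- abs(global_strength(Wa) - global_strength(Wb))
    Mp <- if (any(ut)) max(abs(Dp[ut])) else 0
    ge_S <- ge_S + (Sp >= S_obs - eps)
    ge_M <- ge_M + (Mp >= M_obs - eps)
    if (length(obs_edge))
      ge_edge <- ge_edge + (abs(Dp[edge_sel]) >= obs_edge - eps)
  }
  nperm_eff <- length(assignments)
  if (use_exhaustive) {
    p_S <- ge_S / nperm_eff
    p_M <- ge_M / nperm_eff
    p_edge <- ge_edge / nperm_eff
  } else {
    p_S <- (1 + ge_S) / (1 + nperm_eff)
    p_M <- (1 + ge_M) / (1 + nperm_eff)
    p_edge <- (1 + ge_edge) / (1 + nperm_eff)
  }
  edges <- data.frame(gene1 = genes[edge_sel[, 1]],
                      gene2 = genes[edge_sel[, 2]],
                      diff = D[edge_sel],
                      p = p_edge,
                      q = if (length(p_edge)) bh_adjust(p_edge) else numeric(0),
                      stringsAsFactors = FALSE)
  structure(list(S_obs = S_obs, p_S = p_S, M_obs = M_obs, p_M = p_M,
                 edges = edges, n_perm = nperm_eff, seed = seed,
                 exhaustive = use_exhaustive, genes = genes),
            class = "nct_result")
}

#' Differential network from per-edge NCT results
#'
#' Keeps edges with BH q at or below the threshold, weighted by the observed
#' edge difference; isolated nodes are pruned.
#'
#' @param nct_res an `nct_result`.
#' @param q_threshold FDR threshold (default 0.01).
#' @return a `gene_network` (possibly empty, flagged via zero nodes).
#' @export
differential_network <- function(nct_res, q_threshold = 0.01) {
  stopifnot(inherits(nct_res, "nct_result"))
  genes <- nct_res$genes
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  M <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  keep <- nct_res$edges$q <= q_threshold
  if (any(keep)) {
    sel <- nct_res$edges[keep, , drop = FALSE]
    i <- match(sel$gene1, genes); j <- match(sel$gene2, genes)
    W[cbind(i, j)] <- sel$diff; W[cbind(j, i)] <- sel$diff
    M[cbind(i, j)] <- TRUE; M[cbind(j, i)] <- TRUE
  }
  build_network(genes, M, W, group = "differential")
}
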