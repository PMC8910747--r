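## Co-expression network inference over DEG nodes: Pearson correlation, the
## PCIT (partial correlation + information theory) trio-significance filter,
## pruning, label-propagation communities, and centrality scoring.

#' Pearson correlation matrix across samples
#'
#' @param E genes x samples expression matrix for one group (>= 4 samples,
#'   >= 3 genes).
#' @return genes x genes correlation matrix, unit diagonal; zero-variance
#'   genes get zero correlations with a warning.
#' @export
pearson_matrix <- function(E) {
  E <- as.matrix(E)
  if (ncol(E) < 4) stop("need >= 4 samples")
  if (nrow(E) < 3) stop("need >= 3 genes")
  sds <- apply(E, 1, stats::sd)
  R <- suppressWarnings(stats::cor(t(E)))
  if (any(sds < .Machine$double.eps)) {
    warning("zero-variance gene(s): correlations set to 0")
    bad <- sds < .Machine$double.eps
    R[bad, ] <- 0; R[, bad] <- 0
  }
  diag(R) <- 1
  R
}

#' PCIT significance mask
#'
#' For every gene trio (x, y, z) the three first-order partial correlations
#' are computed; the trio's tolerance is the mean ratio of partial to direct
#' correlation (a ratio is 0 when its direct correlation is 0; denominators
#' are guarded at 1e-12). The edge (x, y) is eliminated if some z satisfies
#' `|r_xy| < tol * |r_xz|` and `|r_xy| < tol * |r_yz|`. Surviving off-diagonal
#' pairs with nonzero correlation form the mask; weights carry the raw r.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @return list `mask` (logical), `weights` (R masked, zero elsewhere).
#' @export
pcit_mask <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n != ncol(R) || max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-8) stop("|r| > 1")
  R <- pmin(pmax(R, -1), 1)
  if (n < 3) {
    mask <- abs(R) > 0; diag(mask) <- FALSE
    return(list(mask = mask, weights = ifelse(mask, R, 0)))
  }
  ## partial[x, y, z] = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
  P <- array(0, c(n, n, n))
  for (z in seq_len(n)) {
    rz <- R[, z]
    den <- sqrt(pmax(outer(1 - rz^2, 1 - rz^2), 0))
    den <- pmax(den, 1e-12)
    P[, , z] <- (R - outer(rz, rz)) / den
  }
  ## ratio[x,y,z] = partial/direct, 0 where the direct correlation is 0
  ratio <- P / array(ifelse(abs(R) > 0, R, Inf), c(n, n, n))
  ## tol[x, y, z] = mean(ratio[x,y,z], ratio[x,z,y], ratio[y,z,x])
  tol <- (ratio + aperm(ratio, c(1, 3, 2)) + aperm(ratio, c(3, 1, 2))) / 3
  absR <- abs(R)
  Axy <- array(absR, c(n, n, n))                       # |r_xy| broadcast over z
  Axz <- aperm(array(absR, c(n, n, n)), c(1, 3, 2))    # |r_xz|
  Ayz <- aperm(array(absR, c(n, n, n)), c(3, 1, 2))    # |r_yz|
  elim <- (Axy < tol * Axz) & (Axy < tol * Ayz)
  ## trios must have three distinct members
  for (z in seq_len(n)) { elim[z, , z] <- FALSE; elim[, z, z] <- FALSE }
  killed <- apply(elim, c(1, 2), any)
  killed <- killed | t(killed)
  mask <- !killed & absR > 0
  diag(mask) <- FALSE
  list(mask = mask, weights = ifelse(mask, R, 0))
}

#' Build a pruned gene network
#'
#' Removes self-loops, enforces symmetric storage, and drops isolated
#' (degree-0) nodes, recording them.
#'
#' @param nodes gene ids (rownames of mask/weights).
#' @param mask logical adjacency.
#' @param weights numeric adjacency (Pearson r on significant edges).
#' @param group label for the network (e.g. cluster name).
#' @return object of class `gene_network`: `nodes`, `weights`, `mask`,
#'   `group`, `pruned` (dropped node ids).
#' @export
build_network <- function(nodes, mask, weights, group = "") {
  mask <- as.matrix(mask); weights <- as.matrix(weights)
  stopifnot(all(dim(mask) == length(nodes)), all(dim(weights) == length(nodes)))
  diag(mask) <- FALSE
  mask <- mask | t(mask)
  weights <- (weights + t(weights)) / 2
  weights[!mask] <- 0
  diag(weights) <- 0
  deg <- rowSums(mask)
  keep <- deg > 0
  pruned <- nodes[!keep]
  structure(list(nodes = nodes[keep],
                 weights = weights[keep, keep, drop = FALSE],
                 mask = mask[keep, keep, drop = FALSE],
                 group = group, pruned = pruned),
            class = "gene_network")
}

#' Infer a PCIT network for one group's expression
#'
#' Convenience wrapper: Pearson correlation, PCIT mask, pruning.
#' @param E genes x samples expression matrix.
#' @param group network label.
#' @return a `gene_network`.
#' @export
infer_network <- function(E, group = "") {
  R <- pearson_matrix(E)
  pc <- pcit_mask(R)
  build_network(rownames(E), pc$mask, pc$weights, group)
}

#' Label-propagation community detection
#'
#' Asynchronous label propagation on the unweighted mask: nodes are visited
#' in seeded random order and adopt the most frequent neighbour label, ties
#' broken uniformly at random; convergence when every node's label is a mode
#' of its neighbourhood. Run with `restarts` seeded restarts; the modal
#' partition (most frequently found, compared up to relabeling) is reported
#' with a stability estimate.
#'
#' @param net a `gene_network`.
#' @param seed master seed.
#' @param max_iter sweep limit per run.
#' @param restarts number of seeded restarts.
#' @return list `membership` (named, ids contiguous from 1),
#'   `n_communities`, `converged`, `stability` (fraction of restarts agreeing
#'   with the modal partition), `seed`.
#' @export
detect_communities <- function(net, seed = 12345, max_iter = 100, restarts = 20) {
  A <- net$mask
  n <- length(net$nodes)
  if (n == 0) stop("empty network")
  one_run <- function(run_seed) {
    set.seed(run_seed)
    lab <- seq_len(n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      changed <- FALSE
      for (i in sample.int(n)) {
        nb <- which(A[i, ])
        if (!length(nb)) next
        tab <- table(lab[nb])
        best <- as.integer(names(tab)[tab == max(tab)])
        new <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
        if (new != lab[i]) { lab[i] <- new; changed <- TRUE }
      }
      if (!changed) { converged <- TRUE; break }
    }
    list(lab = lab, converged = converged)
  }
  canon <- function(lab) as.integer(factor(lab, levels = unique(lab)))
  runs <- lapply(seq_len(restarts), function(r) one_run(derive_seed(seed, r)))
  keys <- vapply(runs, function(r) paste(canon(r$lab), collapse = ","), character(1))
  tab <- table(keys)
  modal_key <- names(tab)[which.max(tab)]
  modal <- runs[[match(modal_key, keys)]]
  membership <- canon(modal$lab)
  names(membership) <- net$nodes
  list(membership = membership,
       n_communities = max(membership),
       converged = modal$converged,
       stability = max(tab) / restarts,
       seed = seed)
}

## Principal eigenvector of a non-negative symmetric matrix by power
## iteration. A diagonal shift keeps the leading eigenvalue strictly
## dominant in magnitude (bipartite graphs have a -lambda_max twin that
## makes unshifted iteration oscillate); the shift leaves eigenvectors
## unchanged and is subtracted from the reported eigenvalue.
power_authority <- function(W, tol = 1e-10, max_iter = 10000) {
  n <- nrow(W)
  if (n == 1) return(list(vector = 1, value = W[1, 1]))
  shift <- max(rowSums(W)) / 2
  if (shift <= 0) return(list(vector = rep(0, n), value = 0))
  Ws <- W + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (i in seq_len(max_iter)) {
    v2 <- as.numeric(Ws %*% v)
    nrm <- sqrt(sum(v2^2))
    if (nrm < 1e-300) return(list(vector = rep(0, n), value = 0))
    v2 <- v2 / nrm
    if (sqrt(sum((v2 - v)^2)) < tol) { v <- v2; lambda <- nrm; break }
    v <- v2; lambda <- nrm
  }
  list(vector = abs(v), value = lambda - shift)
}

#' Betweenness and authority centralities
#'
#' Betweenness uses shortest paths with edge length `1 / |weight|` (or unit
#' lengths with `weighted = FALSE`) and is z-standardized across nodes.
#' Authority is the principal eigenvector of `|W|` (HITS authority equals
#' eigenvector centrality on a symmetric graph), computed per connected
#' component by power iteration to 1e-10, components scaled by their spectral
#' radius, and normalized to max 1.
#'
#' @param net a `gene_network`.
#' @param weighted use 1/|weight| path lengths (default TRUE).
#' @return data.frame `gene`, `betweenness`, `betweenness_z`, `authority`.
#' @export
centralities <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  if (n == 0) stop("empty network")
  W <- abs(net$weights)
  g <- igraph::graph_from_adjacency_matrix(net$mask * 1, mode = "undirected")
  btw <- if (weighted) {
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- 1 / W[el]
    igraph::betweenness(g, weights = w)
  } else igraph::betweenness(g)
  comp <- igraph::components(g)$membership
  auth <- numeric(n)
  vals <- numeric(max(comp))
  for (cc in seq_len(max(comp))) {
    ix <- which(comp == cc)
    pr <- power_authority(W[ix, ix, drop = FALSE])
    auth[ix] <- pr$vector
    vals[cc] <- pr$value
  }
  if (max(vals) > 0) {
    for (cc in seq_len(max(comp)))
      auth[comp == cc] <- auth[comp == cc] * vals[cc] / max(vals)
  }
  if (max(auth) > 0) auth <- auth / max(auth)
  data.frame(gene = net$nodes,
             betweenness = as.numeric(btw),
             betweenness_z = z_standardize(as.numeric(btw)),
             authority = auth,
             stringsAsFactors = FALSE)
}

#' Delta standardized betweenness between two networks
#'
#' Computed over the union node set; a node absent from a network gets raw
#' betweenness 0 before standardization. Result is `z1 - z2`, sorted by
#' absolute delta, descending.
#'
#' @param net1,net2 `gene_network` objects.
#' @param weighted passed to [centralities()].
#' @return data.frame `gene`, `z1`, `z2`, `delta`.
#' @export
delta_betweenness <- function(net1, net2, weighted = TRUE) {
  all_nodes <- sort(union(net1$nodes, net2$nodes))
  raw_of <- function(net) {
    out <- stats::setNames(rep(0, length(all_nodes)), all_nodes)
    if (length(net$nodes)) {
      ct <- centralities(net, weighted = weighted)
      out[ct$gene] <- ct$betweenness
    }
    out
  }
  b1 <- raw_of(net1); b2 <- raw_of(net2)
  z1 <- z_standardize(b1); z2 <- z_standardize(b2)
  df <- data.frame(gene = all_nodes, z1 = z1, z2 = z2, delta = z1 - z2,
                   stringsAsFactors = FALSE)
  df[order(-abs(df$delta), df$gene), , drop = FALSE]
}

#' Serialize a network as a weighted edge-list TSV
#'
#' Columns `gene1, gene2, weight, group` over the upper triangle.
#' @param net a `gene_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  ut <- which(upper.tri(net$mask) & net$mask, arr.ind = TRUE)
  df <- data.frame(gene1 = net$nodes[ut[, 1]], gene2 = net$nodes[ut[, 2]],
                   weight = net$weights[ut], group = net$group,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
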