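## Regulator ranking: TF identification among DEGs, phenotypic impact factor
## (PIF) weighting, regulatory impact factors RIF1 (differential wiring) and
## RIF2 (differential predictive ability), and the top-regulator union that
## feeds drug repurposing.

#' Identify transcription factors among a gene set
#'
#' Case-normalized intersection on gene symbols.
#' @param genes gene ids (e.g. DEGs).
#' @param tf_list curated TF symbols.
#' @return gene ids (as given in `genes`) present in the TF list.
#' @export
identify_tfs <- function(genes, tf_list) {
  if (!length(tf_list)) stop("tf_list must be nonempty")
  genes[toupper(genes) %in% toupper(tf_list)]
}

#' Regulatory impact factor scores
#'
#' With `e1_j`, `e2_j` the group-mean expression of DE gene j (log2-CPM) and
#' `r1_ij`, `r2_ij` the within-group Pearson correlation of TF i with DE gene
#' j:
#' \deqn{PIF_j = ((e1_j + e2_j)/2) (e1_j - e2_j)}
#' \deqn{RIF1_i = (1/n_{de}) \sum_j PIF_j (r1_{ij} - r2_{ij})^2}
#' \deqn{RIF2_i = (1/n_{de}) \sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2}
#' Both RIF columns are z-standardized across TFs (all zeros when
#' degenerate). A zero-variance TF gets zero correlations with a warning.
#'
#' @param E1,E2 genes x samples expression matrices for the two groups
#'   (>= 4 samples each), containing both TFs and DE genes.
#' @param tfs TF gene ids.
#' @param de_genes DE gene ids (the targets being predicted).
#' @return data.frame `tf`, `rif1`, `rif2` (z-scores), `rif1_raw`,
#'   `rif2_raw`, plus attribute `pif` (named per-DE-gene PIF).
#' @export
rif_scores <- function(E1, E2, tfs, de_genes) {
  if (!length(tfs) || !length(de_genes)) stop("tfs and de_genes must be nonempty")
  if (ncol(E1) < 4 || ncol(E2) < 4) stop("both groups need >= 4 samples")
  miss <- setdiff(c(tfs, de_genes), intersect(rownames(E1), rownames(E2)))
  if (length(miss)) stop("genes missing from expression: ", paste(miss, collapse = ", "))
  e1 <- rowMeans(E1[de_genes, , drop = FALSE])
  e2 <- rowMeans(E2[de_genes, , drop = FALSE])
  pif <- (e1 + e2) / 2 * (e1 - e2)
  cor_group <- function(E) {
    r <- suppressWarnings(stats::cor(t(E[tfs, , drop = FALSE]),
                                     t(E[de_genes, , drop = FALSE])))
    if (anyNA(r)) {
      warning("zero-variance TF or DE gene in a group: correlations set to 0")
      r[is.na(r)] <- 0
    }
    r
  }
  r1 <- cor_group(E1); r2 <- cor_group(E2)
  rif1 <- rowMeans(sweep((r1 - r2)^2, 2, pif, `*`))
  rif2 <- rowMeans(sweep(r1^2, 2, e1^2, `*`) - sweep(r2^2, 2, e2^2, `*`))
  out <- data.frame(tf = tfs,
                    rif1 = z_standardize(rif1),
                    rif2 = z_standardize(rif2),
                    rif1_raw = rif1, rif2_raw = rif2,
                    stringsAsFactors = FALSE)
  attr(out, "pif") <- pif
  out
}

#' Top regulator union across four rankings
#'
#' Union of the top-k genes by authority, |RIF1 z|, |RIF2 z|, and |delta
#' standardized betweenness|; ties broken deterministically by gene id.
#'
#' @param centrality data.frame from [centralities()] (authority ranking).
#' @param delta_b data.frame from [delta_betweenness()].
#' @param rif data.frame from [rif_scores()].
#' @param k per-ranking depth (default 5).
#' @return sorted character vector of regulator gene ids.
#' @export
top_regulators <- function(centrality, delta_b, rif, k = 5) {
  if (k < 1) stop("k must be >= 1")
  top_by <- function(ids, score) {
    ord <- order(-score, ids)
    ids[ord[seq_len(min(k, length(ids)))]]
  }
  sort(unique(c(top_by(centrality$gene, centrality$authority),
                top_by(rif$tf, abs(rif$rif1)),
                top_by(rif$tf, abs(rif$rif2)),
                top_by(delta_b$gene, abs(delta_b$delta)))))
}
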