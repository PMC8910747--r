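## Over-representation analysis against local gene-set collections (GMT) and
## a gene-disease association overlap, standing in for live GO/CORUM/KEGG/
## DisGeNET services with identical semantics.

#' Read a GMT gene-set file
#'
#' Each line: set name, description (field 2 verbatim, tabs not allowed by
#' the format), then tab-separated member genes.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: need name, description, members", i))
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("empty set at line %d", i))
    sets[[nm]] <- members
    descs[nm] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @param collection named list of gene-id vectors (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions") %||%
    stats::setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descs[[nm]] %||% "", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric)
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the query's overlap with
#' each set, BH-adjusted across tested sets. Query genes outside the
#' universe are dropped with a warning; sets are intersected with the
#' universe and those with fewer than `min_set_size` members are skipped.
#'
#' @param query character vector of genes of interest (e.g. DEGs).
#' @param collection named list of gene sets.
#' @param universe background gene ids (nonempty).
#' @param min_set_size minimum post-intersection set size (default 3).
#' @return data.frame `set`, `k` (overlap), `K` (set size), `n` (query
#'   size), `N` (universe size), `p`, `q`, `overlap_genes`.
#' @export
ora <- function(query, collection, universe, min_set_size = 3) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  drop <- setdiff(query, universe)
  if (length(drop))
    warning(length(drop), " query gene(s) outside the universe dropped")
  query <- unique(intersect(query, universe))
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = nq, N = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), overlap_genes = character(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), c("set", "k", "K", "n", "N", "p", "q", "overlap_genes")]
}

#' Gene-disease association overlap
#'
#' Fraction of the DEG set found in a curated disease-gene list.
#' @param degs nonempty DEG ids.
#' @param disease_genes disease-associated gene ids.
#' @return fraction in \[0, 1\].
#' @export
gda_overlap <- function(degs, disease_genes) {
  if (!length(degs)) stop("empty DEG set")
  degs <- unique(degs)
  length(intersect(toupper(degs), toupper(disease_genes))) / length(degs)
}
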