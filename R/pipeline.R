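## End-to-end orchestration: integrate -> outlier screen -> low-count filter
## -> batch adjust -> log2-CPM -> Hopkins -> best-k -> portfolio -> selection
## -> clinical comparison -> DE (3 contrasts) -> Venn -> per-cluster PCIT
## networks -> communities -> centralities -> NCT -> differential network ->
## TFs -> RIF -> top regulators -> ORA/GDA -> drug filter. All stage seeds
## derive deterministically from the master seed.

#' Assemble a pipeline configuration
#'
#' Either provide input paths (`counts`, `metadata`, ...) or a `simulate`
#' block ([simulation_config()]); stage parameters have the workflow's
#' defaults (15th-percentile low-count filter, Grubbs alpha 0.05, Hopkins
#' threshold 0.5, automatic k, FDR 0.01, NCT q 0.01, top-5 regulators, master
#' seed 12345).
#'
#' @param simulate optional `simulation_config` (or list of its arguments).
#' @param counts,metadata optional input paths (counts TSV(s), metadata CSV).
#' @param gmt,tf_list,disease_genes,drug_table optional fixture paths
#'   (GMT / one-symbol-per-line text / interaction CSV).
#' @param percentile low-count filter percentile.
#' @param grubbs_alpha outlier-screen level.
#' @param hopkins_threshold clusterability verdict threshold.
#' @param k `"auto"` or an integer.
#' @param algorithms,metrics,linkage clustering portfolio settings.
#' @param n_perm NCT permutations.
#' @param fdr DEG threshold; `q_nct` differential-edge threshold.
#' @param q_nct NCT per-edge FDR threshold.
#' @param top_k per-ranking regulator depth.
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, counts = NULL, metadata = NULL,
                            gmt = NULL, tf_list = NULL, disease_genes = NULL,
                            drug_table = NULL,
                            percentile = 15, grubbs_alpha = 0.05,
                            hopkins_threshold = 0.5, k = "auto",
                            algorithms = c("kmeans", "hierarchical_kmeans",
                                           "pam", "clara", "agnes", "diana",
                                           "fuzzy", "hclust"),
                            metrics = c("euclidean", "manhattan"),
                            linkage = "centroid",
                            n_perm = 200, fdr = 0.01, q_nct = 0.01,
                            top_k = 5, seed = 12345, out_dir = NULL) {
  if (is.null(simulate) && (is.null(counts) || is.null(metadata)))
    stop("either a simulate block or counts + metadata paths are required")
  if (!is.null(simulate) && !inherits(simulate, "simulation_config"))
    simulate <- do.call(simulation_config, as.list(simulate))
  if (!identical(k, "auto") && (!is.numeric(k) || k < 2)) stop("k must be 'auto' or >= 2")
  stopifnot(percentile >= 0, percentile < 100, fdr > 0, fdr <= 1,
            q_nct > 0, q_nct <= 1, top_k >= 1)
  structure(list(simulate = simulate, counts = counts, metadata = metadata,
                 gmt = gmt, tf_list = tf_list, disease_genes = disease_genes,
                 drug_table = drug_table, percentile = percentile,
                 grubbs_alpha = grubbs_alpha,
                 hopkins_threshold = hopkins_threshold, k = k,
                 algorithms = algorithms, metrics = metrics, linkage = linkage,
                 n_perm = n_perm, fdr = fdr, q_nct = q_nct, top_k = top_k,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_artifact <- function(bundle, name, writer) {
  if (is.null(bundle$out_dir)) return(bundle)
  path <- file.path(bundle$out_dir, name)
  writer(path)
  bundle$files <- c(bundle$files, path)
  bundle
}

#' Run the full subtyping pipeline
#'
#' Executes every stage in order and returns a report bundle. If the Hopkins
#' verdict is negative the pipeline stops after the clusterability stage with
#' `status = "no_cluster_structure"` (completed artifacts retained); a stage
#' error is caught, recorded in `errors`, and aborts dependent stages with
#' `status = "stage_failure"`.
#'
#' @param config a [pipeline_config()].
#' @return report bundle (list) with stage artifacts, `status`, `errors`,
#'   and a `manifest` of emitted files with md5 checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  bundle <- list(config = config, status = "ok", errors = list(),
                 files = character(0), out_dir = config$out_dir)
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  finish <- function(bundle) {
    if (!is.null(bundle$out_dir)) {
      files <- bundle$files
      bundle$manifest <- data.frame(
        file = basename(files),
        md5 = unname(tools::md5sum(files)),
        stringsAsFactors = FALSE)
      jsonlite::write_json(
        list(seed = seed, status = bundle$status,
             files = bundle$manifest,
             generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        file.path(bundle$out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA)
    }
    bundle
  }
  fail <- function(bundle, stage, e) {
    bundle$errors[[stage]] <- conditionMessage(e)
    bundle$status <- "stage_failure"
    finish(bundle)
  }

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate)
    counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
    bundle$truth <- truth
  } else {
    paths <- config$counts
    mats <- lapply(paths, read_counts)
    counts <- integrate_by_gene(mats)
    meta <- read_sample_table(config$metadata)
    truth <- NULL
  }
  meta <- as_sample_table(meta, counts)

  ## ---- preprocessing ----
  pre <- tryCatch({
    sc <- screen_outliers(counts, meta, alpha = config$grubbs_alpha)
    filtered <- filter_low_counts(sc$counts, config$percentile)
    adjusted <- batch_adjust(filtered, sc$meta$batch, sc$meta$diagnosis)
    list(meta = sc$meta, removed = sc$removed, grubbs = sc$tests,
         counts = adjusted, expr = log2_cpm(adjusted))
  }, error = function(e) e)
  if (inherits(pre, "error")) return(fail(bundle, "preprocessing", pre))
  meta <- pre$meta
  bundle$preprocessing <- list(removed = pre$removed,
                               n_genes = nrow(pre$counts),
                               grubbs = pre$grubbs)
  expr <- pre$expr
  bundle <- write_artifact(bundle, "counts_adjusted.tsv",
                           function(p) write_counts(pre$counts, p))

  ## ---- subtype discovery (cases only, gene-standardized log2-CPM) ----
  pd <- meta$sample[meta$diagnosis == "PD"]
  X <- t(expr[, pd, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  hop <- tryCatch(hopkins(X, m = max(2L, ceiling(nrow(X) / 10)),
                          seed = derive_seed(seed, 1),
                          threshold = config$hopkins_threshold),
                  error = function(e) e)
  if (inherits(hop, "error")) return(fail(bundle, "hopkins", hop))
  bundle$hopkins <- hop
  if (!hop$clusterable) {
    bundle$status <- "no_cluster_structure"
    return(finish(bundle))
  }
  clus <- tryCatch({
    bk <- NULL
    k <- if (identical(config$k, "auto")) {
      bk <- estimate_best_k(X, 2:min(10, nrow(X) - 1), seed = derive_seed(seed, 2))
      bk$best_k
    } else as.integer(config$k)
    models <- run_portfolio(X, k, config$algorithms, config$metrics,
                            config$linkage, seed = derive_seed(seed, 3))
    best <- select_best_model(models)
    list(k = k, best_k = bk, models = models, best = best)
  }, error = function(e) e)
  if (inherits(clus, "error")) return(fail(bundle, "clustering", clus))
  bundle$best_k <- clus$best_k
  bundle$cluster <- clus
  labels <- clus$best$labels
  subtype <- stats::setNames(paste0("PDC", labels), names(labels))
  bundle$subtype <- subtype
  bundle <- write_artifact(bundle, "labels.csv", function(p)
    utils::write.csv(data.frame(sample = names(subtype), cluster = unname(subtype)),
                     p, row.names = FALSE, quote = FALSE))
  clin <- tryCatch(compare_clinical(meta, labels, seed = derive_seed(seed, 4)),
                   error = function(e) e)
  if (inherits(clin, "error")) {
    bundle$errors$clinical <- conditionMessage(clin)
    clin <- NULL
  }
  bundle$clinical <- clin

  ## ---- differential expression, three contrasts ----
  grp <- stats::setNames(meta$diagnosis, meta$sample)
  grp[names(subtype)] <- subtype
  de <- tryCatch({
    lv <- sort(unique(subtype))
    if (length(lv) != 2) stop("expected exactly 2 subtypes for contrasts")
    list(
      subtype = de_contrast(expr, grp[colnames(expr)], lv[1], lv[2]),
      pdc1_nc = de_contrast(expr, grp[colnames(expr)], lv[1], "NC"),
      pdc2_nc = de_contrast(expr, grp[colnames(expr)], lv[2], "NC"))
  }, error = function(e) e)
  if (inherits(de, "error")) return(fail(bundle, "differential_expression", de))
  degs <- lapply(de, call_degs, alpha = config$fdr)
  bundle$de <- de
  bundle$degs <- degs
  bundle$venn <- venn_partition(degs$pdc1_nc, degs$pdc2_nc)
  for (nm in names(de)) {
    r <- de[[nm]]
    bundle <- write_artifact(bundle, paste0("de_", nm, ".tsv"), function(p)
      utils::write.table(data.frame(gene = r$genes, logFC = r$logFC, t = r$t,
                                    P.Value = r$p, adj.P.Val = r$q, B = r$B,
                                    deg = r$q <= config$fdr),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## ---- fixtures (local stand-ins for curated resources) ----
  universe <- rownames(expr)
  fixtures <- list(
    collection = if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL,
    tf_list = if (!is.null(config$tf_list)) readLines(config$tf_list) else NULL,
    disease = if (!is.null(config$disease_genes)) readLines(config$disease_genes) else NULL)
  if (is.null(fixtures$collection) || is.null(fixtures$disease)) {
    gs <- make_gene_set_fixture(
      n_sets = 10, set_size_range = c(5, 25), universe = universe,
      planted_query = if (length(degs$subtype) >= 3) degs$subtype else NULL,
      seed = derive_seed(seed, 5))
    fixtures$collection <- fixtures$collection %||% gs$collection
    fixtures$disease <- fixtures$disease %||% gs$disease_genes
  }
  if (is.null(fixtures$tf_list))
    fixtures$tf_list <- if (!is.null(truth)) truth$tf_ids else
      make_gene_set_fixture(universe = universe,
                            seed = derive_seed(seed, 6))$tf_list

  ## ---- network stages over the subtype DEG node set ----
  node_set <- degs$subtype
  net_ok <- length(node_set) >= 3
  if (net_ok) {
    nets <- tryCatch({
      lv <- sort(unique(subtype))
      s1 <- names(subtype)[subtype == lv[1]]
      s2 <- names(subtype)[subtype == lv[2]]
      E1 <- expr[node_set, s1, drop = FALSE]
      E2 <- expr[node_set, s2, drop = FALSE]
      net1 <- infer_network(E1, group = lv[1])
      net2 <- infer_network(E2, group = lv[2])
      comm1 <- if (length(net1$nodes)) detect_communities(net1, derive_seed(seed, 7)) else NULL
      comm2 <- if (length(net2$nodes)) detect_communities(net2, derive_seed(seed, 8)) else NULL
      nct_res <- nct(E1, E2, n_perm = config$n_perm, seed = derive_seed(seed, 9))
      dnet <- differential_network(nct_res, config$q_nct)
      db <- delta_betweenness(net1, net2)
      cent_ref <- if (length(dnet$nodes) >= 2) dnet else net1
      cent <- centralities(cent_ref)
      list(net1 = net1, net2 = net2, comm1 = comm1, comm2 = comm2,
           nct = nct_res, dnet = dnet, delta_b = db, centrality = cent,
           E1 = E1, E2 = E2)
    }, error = function(e) e)
    if (inherits(nets, "error")) return(fail(bundle, "networks", nets))
    bundle$networks <- nets[c("net1", "net2", "comm1", "comm2", "dnet")]
    bundle$nct <- nets$nct
    bundle$delta_betweenness <- nets$delta_b
    bundle$centrality <- nets$centrality
    bundle <- write_artifact(bundle, "network_pdc1.tsv",
                             function(p) write_network(nets$net1, p))
    bundle <- write_artifact(bundle, "network_pdc2.tsv",
                             function(p) write_network(nets$net2, p))
    bundle <- write_artifact(bundle, "nct.json", function(p)
      jsonlite::write_json(list(S_obs = nets$nct$S_obs, p_S = nets$nct$p_S,
                                M_obs = nets$nct$M_obs, p_M = nets$nct$p_M,
                                n_perm = nets$nct$n_perm),
                           p, auto_unbox = TRUE, digits = NA))

    ## ---- regulators ----
    reg <- tryCatch({
      tfs <- identify_tfs(node_set, fixtures$tf_list)
      rif <- if (length(tfs))
        rif_scores(nets$E1, nets$E2, tfs, node_set) else NULL
      tops <- if (!is.null(rif))
        top_regulators(nets$centrality, nets$delta_b, rif, config$top_k)
      else unique(c(
        nets$centrality$gene[order(-nets$centrality$authority)][seq_len(min(config$top_k, nrow(nets$centrality)))],
        nets$delta_b$gene[seq_len(min(config$top_k, nrow(nets$delta_b)))]))
      list(tfs = tfs, rif = rif, top = tops)
    }, error = function(e) e)
    if (inherits(reg, "error")) return(fail(bundle, "regulators", reg))
    bundle$tfs <- reg$tfs
    bundle$rif <- reg$rif
    bundle$top_regulators <- reg$top
    if (!is.null(reg$rif))
      bundle <- write_artifact(bundle, "rif.csv", function(p)
        utils::write.csv(reg$rif, p, row.names = FALSE, quote = FALSE))
  } else {
    bundle$errors$networks <- "fewer than 3 subtype DEGs; network stages skipped"
    bundle$top_regulators <- character(0)
  }

  ## ---- annotation ----
  ann <- tryCatch({
    list(ora = if (length(degs$subtype))
           ora(degs$subtype, fixtures$collection, universe) else NULL,
         gda = if (length(degs$subtype))
           gda_overlap(degs$subtype, fixtures$disease) else NA_real_)
  }, error = function(e) e)
  if (inherits(ann, "error")) return(fail(bundle, "annotation", ann))
  bundle$ora <- ann$ora
  bundle$gda <- ann$gda
  if (!is.null(ann$ora))
    bundle <- write_artifact(bundle, "ora.csv", function(p)
      utils::write.csv(ann$ora, p, row.names = FALSE))

  ## ---- drug repurposing ----
  if (length(bundle$top_regulators)) {
    drugs <- tryCatch({
      table <- if (!is.null(config$drug_table)) read_interactions(config$drug_table)
      else make_drug_fixture(
        genes = utils::head(bundle$top_regulators, 2),
        seed = derive_seed(seed, 10))
      hits <- query_interactions(bundle$top_regulators, table)
      flt <- filter_compounds(hits)
      list(queried = nrow(hits), filter_log = flt$log,
           report = drug_report(flt$records))
    }, error = function(e) e)
    if (inherits(drugs, "error")) return(fail(bundle, "drugs", drugs))
    bundle$drugs <- drugs
    bundle <- write_artifact(bundle, "drug_report.csv", function(p)
      utils::write.csv(drugs$report, p, row.names = FALSE, quote = FALSE))
    bundle <- write_artifact(bundle, "filter_log.json", function(p)
      jsonlite::write_json(list(initial = drugs$filter_log$initial,
                                removed = as.list(drugs$filter_log$removed),
                                final = drugs$filter_log$final),
                           p, auto_unbox = TRUE, digits = NA))
  }
  finish(bundle)
}
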