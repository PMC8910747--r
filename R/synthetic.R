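## Synthetic cohort generator.
##
## The simulated world mirrors the data regime of the post-mortem brain
## RNA-seq cohort the workflow targets: two case subtypes (PDC1 n = 50,
## PDC2 n = 65) and a control group (NC n = 94) spread over several study
## batches, negative-binomial counts with gene-specific baseline abundance,
## multiplicative batch effects on the mean, a planted block of
## subtype-discriminating DE genes (default 42, of which 6 are designated
## transcription factors), disease-vs-control DE genes, and group-specific
## gene-gene correlation induced by shared latent factors on the log-mean
## scale.

#' Build and validate a simulation configuration
#'
#' Defaults state the simulated world once: group sizes 50/65/94, 3 study
#' batches, 42 subtype DE genes (6 designated TFs), planted |log2FC| drawn
#' from N(lfc_mean, lfc_sd) with random sign, NB dispersion 0.2, and two
#' latent-factor correlation blocks active only in the PDC1 group (loading
#' 0.8), so the PDC1 network has community structure while PDC2 does not.
#'
#' @param n_genes number of genes.
#' @param n_pd1,n_pd2,n_nc group sizes (each >= 2).
#' @param n_batches number of batches (>= 1).
#' @param batch_effect_sd SD of the per-(batch, gene) log2 multiplicative
#'   batch factor.
#' @param n_de_subtype,n_de_disease numbers of planted DE genes for the
#'   subtype (PDC1 vs PDC2) and disease (PD vs NC) contrasts; blocks are
#'   disjoint.
#' @param lfc_mean,lfc_sd planted log2-fold-change magnitude distribution.
#' @param nb_mu_log_mean,nb_mu_log_sd log-normal baseline mean abundance.
#' @param nb_dispersion NB dispersion phi (scalar or per-gene vector);
#'   var = mu + phi * mu^2.
#' @param corr_block_spec list of `list(genes =, group =, loading =)` entries;
#'   `NULL` uses the default two PDC1 blocks over the subtype DE genes.
#' @param tf_fraction fraction of genes designated transcription factors.
#' @param age_shift additional mean years of survival for PDC2 vs PDC1.
#' @param braak_shift downward shift in PDC2 modal Braak stage vs PDC1.
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              n_pd1 = 50, n_pd2 = 65, n_nc = 94,
                              n_batches = 3,
                              batch_effect_sd = 0.5,
                              n_de_subtype = 42, n_de_disease = 150,
                              lfc_mean = 2, lfc_sd = 0.5,
                              nb_mu_log_mean = 4, nb_mu_log_sd = 1.5,
                              nb_dispersion = 0.2,
                              corr_block_spec = NULL,
                              tf_fraction = 0.1,
                              age_shift = 5, braak_shift = 1,
                              seed = 12345) {
  cfg <- list(n_genes = n_genes, n_pd1 = n_pd1, n_pd2 = n_pd2, n_nc = n_nc,
              n_batches = n_batches, batch_effect_sd = batch_effect_sd,
              n_de_subtype = n_de_subtype, n_de_disease = n_de_disease,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              nb_mu_log_mean = nb_mu_log_mean, nb_mu_log_sd = nb_mu_log_sd,
              nb_dispersion = nb_dispersion,
              corr_block_spec = corr_block_spec,
              tf_fraction = tf_fraction,
              age_shift = age_shift, braak_shift = braak_shift,
              seed = as.integer(seed))
  if (any(c(n_pd1, n_pd2, n_nc) < 2)) stop("group sizes must be >= 2")
  if (n_genes < 1 || n_batches < 1) stop("n_genes and n_batches must be positive")
  if (batch_effect_sd < 0) stop("batch_effect_sd must be non-negative")
  if (n_de_subtype + n_de_disease > n_genes)
    stop("DE gene blocks overlap or exceed n_genes: subtype and disease blocks must be disjoint")
  if (tf_fraction <= 0 || tf_fraction >= 1) stop("tf_fraction must be in (0,1)")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(corr_block_spec)) {
    for (b in corr_block_spec) {
      if (!all(b$genes %in% gene_ids)) stop("corr block references unknown genes")
      if (is.null(b$loading) || is.null(b$group)) stop("corr block needs group and loading")
    }
  }
  cfg$gene_ids <- gene_ids
  class(cfg) <- "simulation_config"
  cfg
}

default_corr_blocks <- function(cfg) {
  ## Two latent-factor blocks active only in PDC1, carved from the subtype DE
  ## genes, so the PDC1 co-expression network segregates into 2 communities.
  n_block <- min(15L, max(2L, cfg$n_de_subtype %/% 3L))
  if (cfg$n_de_subtype < 4L) return(list())
  de <- cfg$gene_ids[seq_len(cfg$n_de_subtype)]
  b1 <- de[seq_len(n_block)]
  b2 <- de[seq.int(n_block + 1L, min(2L * n_block, length(de)))]
  list(list(genes = b1, group = "PDC1", loading = 0.8),
       list(genes = b2, group = "PDC1", loading = 0.8))
}

#' Simulate a cohort with known ground truth
#'
#' Counts are NB with mean `mu_g * 2^(lfc + batch + latent)` and dispersion
#' `phi_g`; the same seed gives bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (CountMatrix), `meta` (SampleTable) and
#'   `truth` (subtype labels, signed planted fold changes, batch assignment,
#'   per-group correlated edges, TF ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- cfg$gene_ids
  G <- cfg$n_genes
  groups <- c(rep("PDC1", cfg$n_pd1), rep("PDC2", cfg$n_pd2), rep("NC", cfg$n_nc))
  S <- length(groups)
  samples <- sprintf("S%03d", seq_len(S))

  ## batch: round-robin within group so batch is never confounded with group
  batch <- integer(S)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    batch[idx] <- rep_len(seq_len(cfg$n_batches), length(idx))
  }

  ## gene roles
  de_sub <- genes[seq_len(cfg$n_de_subtype)]
  de_dis <- if (cfg$n_de_disease > 0)
    genes[cfg$n_de_subtype + seq_len(cfg$n_de_disease)] else character(0)
  n_tf <- max(1L, ceiling(cfg$tf_fraction * G))
  ## TFs wired into the subtype DE block (6 by default), rest from background
  n_tf_de <- min(6L, n_tf, length(de_sub))
  tf_ids <- de_sub[seq_len(n_tf_de)]
  if (n_tf > n_tf_de) {
    bg <- setdiff(genes, c(de_sub, de_dis))
    tf_ids <- c(tf_ids, sample(bg, n_tf - n_tf_de))
  }

  ## planted effects (log2 scale, random sign)
  lfc_sub <- stats::rnorm(length(de_sub), cfg$lfc_mean, cfg$lfc_sd) *
    sample(c(-1, 1), length(de_sub), replace = TRUE)
  names(lfc_sub) <- de_sub
  lfc_dis <- stats::rnorm(length(de_dis), cfg$lfc_mean, cfg$lfc_sd) *
    sample(c(-1, 1), length(de_dis), replace = TRUE)
  names(lfc_dis) <- de_dis

  mu <- exp(stats::rnorm(G, cfg$nb_mu_log_mean, cfg$nb_mu_log_sd))
  phi <- rep_len(cfg$nb_dispersion, G)

  ## log2 mean offsets
  off <- matrix(0, G, S, dimnames = list(genes, samples))
  off[de_sub, groups == "PDC1"] <- off[de_sub, groups == "PDC1"] + lfc_sub
  if (length(de_dis))
    off[de_dis, groups != "NC"] <- off[de_dis, groups != "NC"] + lfc_dis
  bfac <- matrix(stats::rnorm(cfg$n_batches * G, 0, cfg$batch_effect_sd),
                 G, cfg$n_batches)
  off <- off + bfac[, batch, drop = FALSE]

  blocks <- cfg$corr_block_spec %||% default_corr_blocks(cfg)
  edges <- list()
  for (b in blocks) {
    in_group <- if (identical(b$group, "all")) rep(TRUE, S) else groups == b$group
    f <- stats::rnorm(sum(in_group))
    off[b$genes, in_group] <- off[b$genes, in_group] +
      matrix(rep(b$loading * f, each = length(b$genes)), length(b$genes))
    pair_idx <- utils::combn(sort(b$genes), 2)
    edges[[length(edges) + 1L]] <- data.frame(
      gene1 = pair_idx[1, ], gene2 = pair_idx[2, ],
      group = b$group, loading = b$loading, stringsAsFactors = FALSE)
  }
  true_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene1 = character(0), gene2 = character(0),
               group = character(0), loading = numeric(0))

  mu_gs <- mu * 2^off
  counts <- matrix(stats::rnbinom(G * S, mu = mu_gs, size = rep(1 / phi, S)),
                   G, S, dimnames = list(genes, samples))

  ## clinical metadata with a configurable subtype signal
  age <- numeric(S)
  age[groups == "PDC1"] <- stats::rnorm(cfg$n_pd1, 76, 6)
  age[groups == "PDC2"] <- stats::rnorm(cfg$n_pd2, 76 + cfg$age_shift, 6)
  age[groups == "NC"] <- stats::rnorm(cfg$n_nc, 78, 6)
  braak <- integer(S)
  braak[groups == "NC"] <- sample(0:2, cfg$n_nc, replace = TRUE, prob = c(.6, .3, .1))
  braak[groups == "PDC1"] <- pmin(6L, pmax(1L, round(stats::rnorm(cfg$n_pd1, 4.5, 1))))
  braak[groups == "PDC2"] <- pmin(6L, pmax(1L, round(stats::rnorm(cfg$n_pd2, 4.5 - cfg$braak_shift, 1))))
  sex <- sample(c("M", "F"), S, replace = TRUE)

  meta <- data.frame(sample = samples,
                     diagnosis = ifelse(groups == "NC", "NC", "PD"),
                     batch = batch,
                     age_death = round(age, 1),
                     sex = sex,
                     braak = braak,
                     stringsAsFactors = FALSE)
  subtype <- groups[groups != "NC"]
  names(subtype) <- samples[groups != "NC"]

  truth <- list(subtype_labels = subtype,
                de_genes_subtype = lfc_sub,
                de_genes_disease = lfc_dis,
                batch_assignment = stats::setNames(batch, samples),
                true_edges_per_group = true_edges,
                tf_ids = sort(tf_ids))
  list(counts = as_count_matrix(counts),
       meta = as_sample_table(meta),
       truth = truth)
}

#' Serialize simulation truth as JSON
#' @param truth truth component of [simulate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a drug-gene interaction fixture with known filter arithmetic
#'
#' Builds `n_total` interaction records of which `n_duplicated` are exact
#' repeats of earlier (compound, gene) pairs and, among the unique records,
#' `n_inefficacious` fail clinical-trial efficacy, `n_side_effect` carry
#' memory/excitotoxicity side-effect flags and `n_unknown_moa` have an empty
#' modality of action.  With non-overlapping categories the sequential filter
#' retains `n_total - n_duplicated - n_inefficacious - n_side_effect -
#' n_unknown_moa` records.
#'
#' @param n_total,n_duplicated,n_inefficacious,n_side_effect,n_unknown_moa
#'   category counts (all >= 0; categories beyond duplication apply to the
#'   unique records and must fit inside them).
#' @param genes target gene symbols the records map to.
#' @param overlap_duplicate_unknown if `TRUE` one duplicated record is a copy
#'   of an unknown-MoA record (so it is both), to exercise first-failing-stage
#'   disposition.
#' @param seed RNG seed.
#' @return data.frame with columns `compound_id, compound_name, gene, moa,
#'   phase, efficacious, side_effect_memory, side_effect_excitotoxicity`.
#' @export
make_drug_fixture <- function(n_total = 42, n_duplicated = 16,
                              n_inefficacious = 5, n_side_effect = 2,
                              n_unknown_moa = 10,
                              genes = c("NEUROD1", "GRM2"),
                              overlap_duplicate_unknown = FALSE,
                              seed = 1L) {
  cnt <- c(n_total, n_duplicated, n_inefficacious, n_side_effect, n_unknown_moa)
  if (any(cnt < 0)) stop("negative counts")
  n_unique <- n_total - n_duplicated
  if (n_unique < 0) stop("more duplicates than records")
  if (n_inefficacious + n_side_effect + n_unknown_moa > n_unique)
    stop("flagged categories exceed the unique records")
  if (n_total == 0)
    return(data.frame(compound_id = character(0), compound_name = character(0),
                      gene = character(0), moa = character(0),
                      phase = character(0), efficacious = logical(0),
                      side_effect_memory = logical(0),
                      side_effect_excitotoxicity = logical(0)))
  set.seed(seed)
  moas <- c("receptor agonist", "pathway inhibitor",
            "positive allosteric modulator", "iron chelator",
            "neural stem cell inducer")
  phases <- c("Preclinical", "Phase 1", "Phase 2", "Launched")
  rec <- data.frame(
    compound_id = sprintf("CHEMBL%05d", seq_len(n_unique)),
    compound_name = sprintf("CPD%03d", seq_len(n_unique)),
    gene = rep_len(genes, n_unique),
    moa = sample(moas, n_unique, replace = TRUE),
    phase = sample(phases, n_unique, replace = TRUE),
    efficacious = TRUE,
    side_effect_memory = FALSE,
    side_effect_excitotoxicity = FALSE,
    stringsAsFactors = FALSE)
  i <- 0L
  if (n_inefficacious) rec$efficacious[i + seq_len(n_inefficacious)] <- FALSE
  i <- i + n_inefficacious
  if (n_side_effect) {
    half <- seq_len(n_side_effect) %% 2L == 0L
    rec$side_effect_memory[i + which(!half)] <- TRUE
    rec$side_effect_excitotoxicity[i + which(half)] <- TRUE
  }
  i <- i + n_side_effect
  if (n_unknown_moa) rec$moa[i + seq_len(n_unknown_moa)] <- ""
  if (n_duplicated > 0) {
    src <- if (overlap_duplicate_unknown && n_unknown_moa > 0) {
      unk <- which(rec$moa == "")
      c(unk[1L], sample(seq_len(n_unique), n_duplicated - 1L, replace = TRUE))
    } else {
      sample(seq_len(n_unique), n_duplicated, replace = TRUE)
    }
    rec <- rbind(rec, rec[src, , drop = FALSE])
  }
  rownames(rec) <- NULL
  rec
}

#' Generate a local gene-set collection fixture (GO/CORUM/KEGG stand-in)
#'
#' Random sets drawn from `universe`; optionally plants one set equal to (or
#' overlapping) a query so over-representation analysis has a known positive.
#' Also returns a TF list and a disease-gene list for the annotation stages.
#'
#' @param n_sets number of gene sets.
#' @param set_size_range integer range `c(min, max)` of set sizes.
#' @param universe character vector of gene ids.
#' @param planted_query optional character vector; if given, the first set is
#'   exactly this query (named `PLANTED`).
#' @param tf_fraction fraction of the universe designated TFs.
#' @param disease_fraction fraction of the universe put in the disease list.
#' @param seed RNG seed.
#' @return list with `collection` (named list of gene-id vectors, with a
#'   `descriptions` attribute), `tf_list`, `disease_genes`.
#' @export
make_gene_set_fixture <- function(n_sets = 10, set_size_range = c(5, 25),
                                  universe, planted_query = NULL,
                                  tf_fraction = 0.1, disease_fraction = 0.1,
                                  seed = 1L) {
  if (!length(universe)) stop("universe must be nonempty")
  if (max(set_size_range) > length(universe))
    stop("set size exceeds universe")
  set.seed(seed)
  sets <- list()
  descs <- character(0)
  if (!is.null(planted_query)) {
    if (!all(planted_query %in% universe)) stop("planted query outside universe")
    sets$PLANTED <- planted_query
    descs["PLANTED"] <- "planted enriched set"
  }
  n_random <- n_sets - length(sets)
  for (j in seq_len(max(0L, n_random))) {
    nm <- sprintf("SET%03d", j)
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sets[[nm]] <- sort(sample(universe, sz))
    descs[nm] <- "random fixture set"
  }
  attr(sets, "descriptions") <- descs
  n_tf <- max(1L, ceiling(tf_fraction * length(universe)))
  n_dis <- max(1L, ceiling(disease_fraction * length(universe)))
  list(collection = sets,
       tf_list = sort(sample(universe, n_tf)),
       disease_genes = sort(sample(universe, n_dis)))
}
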