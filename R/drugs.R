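## Drug repurposing: join candidate regulator genes against a local
## drug-gene interaction table and apply the sequential exclusion filters
## (duplicated -> inefficacious -> memory/excitotoxicity side effects ->
## unknown modality of action), keeping an auditable per-record log.

#' Read a drug-gene interaction table CSV
#'
#' Columns: `compound_id, compound_name, gene, moa, phase, efficacious,
#' side_effect_memory, side_effect_excitotoxicity`.
#' @param path CSV path.
#' @return data.frame of interaction records.
#' @export
read_interactions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "compound_name", "gene", "moa", "phase",
           "efficacious", "side_effect_memory", "side_effect_excitotoxicity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("interaction table missing columns: ",
                         paste(miss, collapse = ", "))
  df$moa[is.na(df$moa)] <- ""
  df
}

#' Query interaction records for a gene set
#'
#' Case-normalized join on the gene symbol; original record order preserved.
#' @param genes nonempty character vector of target genes.
#' @param table interaction table (see [read_interactions()]).
#' @return matching records (possibly zero rows).
#' @export
query_interactions <- function(genes, table) {
  if (!length(genes)) stop("genes must be nonempty")
  table[toupper(table$gene) %in% toupper(genes), , drop = FALSE]
}

#' Sequentially filter compounds
#'
#' Stages, in order: (1) deduplicate on (compound id, gene), keeping the
#' first occurrence; (2) drop records failing clinical-trial efficacy;
#' (3) drop records with memory or excitotoxicity side-effect flags;
#' (4) drop records with an empty/unknown modality of action. Each record is
#' disposed exactly once, at its first failing stage.
#'
#' @param records interaction records.
#' @return list `records` (survivors) and `log` (class `filter_log`):
#'   `initial`, `removed` (named stage counts), `final`, `disposition`
#'   (per input record: `kept` or the removing stage).
#' @export
filter_compounds <- function(records) {
  n <- nrow(records)
  disposition <- rep("kept", n)
  if (n) {
    key <- paste(records$compound_id, toupper(records$gene), sep = "\r")
    dup <- duplicated(key)
    disposition[dup] <- "duplicated"
    stage2 <- !dup & !as.logical(records$efficacious)
    disposition[stage2] <- "inefficacious"
    stage3 <- disposition == "kept" &
      (as.logical(records$side_effect_memory) |
         as.logical(records$side_effect_excitotoxicity))
    disposition[stage3] <- "side_effects"
    stage4 <- disposition == "kept" & !nzchar(trimws(records$moa))
    disposition[stage4] <- "unknown_moa"
  }
  removed <- vapply(c("duplicated", "inefficacious", "side_effects", "unknown_moa"),
                    function(s) sum(disposition == s), integer(1))
  log <- structure(list(initial = n, removed = removed,
                        final = sum(disposition == "kept"),
                        disposition = disposition),
                   class = "filter_log")
  stopifnot(log$initial - sum(log$removed) == log$final)
  list(records = records[disposition == "kept", , drop = FALSE], log = log)
}

#' Gene-to-drug report
#'
#' One row per surviving record, grouped by target gene, deterministic
#' ordering (gene, then drug name).
#'
#' @param records surviving interaction records.
#' @return data.frame `gene`, `drug`, `compound_id`, `phase`, `moa`.
#' @export
drug_report <- function(records) {
  out <- data.frame(gene = records$gene, drug = records$compound_name,
                    compound_id = records$compound_id, phase = records$phase,
                    moa = records$moa, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
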