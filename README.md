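# netsubtype

Data-driven discovery of transcriptomic disease subtypes from bulk RNA-seq
counts, with network-level characterization and drug-repurposing candidate
selection. The package was built around the analysis problem posed by
post-mortem brain RNA-seq in Parkinson's disease — a clinically heterogeneous
disease whose molecular subtypes are unknown — but every stage is generic:
give it a gene × sample count matrix and a metadata table (diagnosis, batch,
age at death, sex, Braak stage) and it will

1. **Preprocess**: integrate count matrices by gene, screen demographic
   outliers with a two-sided Grubbs test, drop genes below the 15th
   percentile of total counts, remove batch effects by negative-binomial
   quantile mapping, and compute log2-CPM.
2. **Discover subtypes**: confirm clustering tendency with the Hopkins
   statistic *H* (near 0 ⇒ clusterable), vote on the number of clusters *k*
   across five internal indices, fit a portfolio of 8 clustering algorithms
   (k-means, hierarchical k-means, PAM, CLARA, AGNES, DIANA, fuzzy, hclust)
   over euclidean and manhattan distances, and select the model maximizing
   the average silhouette width
   s(i) = (b(i) − a(i)) / max(a(i), b(i)), with the Dunn index as
   tie-breaker. Clinical differences between clusters are tested with
   Wilcoxon rank-sum (age at death) and Fisher exact tests (sex, Braak).
3. **Differential expression**: gene-wise linear models on log2-CPM with
   empirical-Bayes variance moderation — the posterior variance
   s̃²_g = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g) gives a moderated t on d₀ + d_g
   degrees of freedom — and Benjamini–Hochberg FDR; genes with q ≤ 0.01 are
   DEGs.
4. **Network inference**: per-subtype co-expression networks over the DEG
   nodes using the PCIT algorithm — for every gene trio (x, y, z) the
   first-order partial correlation
   r_xy·z = (r_xy − r_xz·r_yz)/√((1−r²_xz)(1−r²_yz)) defines a local
   tolerance ε (mean ratio of partial to direct correlation) and the edge
   (x,y) is dropped if |r_xy| < ε·|r_xz| and |r_xy| < ε·|r_yz| for some z —
   plus label-propagation communities, betweenness and authority
   (eigenvector) centralities.
5. **Network comparison**: permutation tests (NCT) for global strength
   invariance S, structure invariance M = max edge difference, and per-edge
   strength invariance with BH-FDR; significant edges form the differential
   network.
6. **Regulator ranking**: transcription factors among the DEGs scored by
   regulatory impact factors,
   RIF1ᵢ = (1/n) Σⱼ PIFⱼ (r1ᵢⱼ − r2ᵢⱼ)² and
   RIF2ᵢ = (1/n) Σⱼ (e1ⱼ r1ᵢⱼ)² − (e2ⱼ r2ᵢⱼ)², with
   PIFⱼ = ((e1ⱼ+e2ⱼ)/2)(e1ⱼ−e2ⱼ); the top-5 genes by authority, |RIF1|,
   |RIF2| and |Δ standardized betweenness| are pooled as drug targets.
7. **Annotation & repurposing**: hypergeometric over-representation analysis
   against local GMT gene-set collections, gene–disease association overlap,
   and a sequential drug–gene interaction filter (duplicated → inefficacious
   → memory/excitotoxicity side effects → unknown modality of action) with a
   fully audited filter log.

A negative-binomial cohort simulator with planted subtypes, batch effects and
group-specific latent-factor correlation blocks provides ground truth, so the
entire pipeline is testable offline.

## Worked example

```r
library(netsubtype)

cfg <- pipeline_config(
  simulate = simulation_config(n_genes = 400, n_pd1 = 40, n_pd2 = 40,
                               n_nc = 20, n_de_subtype = 50,
                               n_de_disease = 40, seed = 11),
  n_perm = 100, seed = 11)
bundle <- run_pipeline(cfg)
```

Output of the summary lines (exactly as printed by the code above):

```
status: ok
Hopkins H: 0.428
best k: 2  votes: 2,2,10,10,2
selected model: agnes / manhattan (silhouette = 0.10, Dunn = 0.768)
cluster sizes: 40 / 40
ARI vs planted truth: 1
subtype DEGs (q<=0.01): 48
communities: 2 (PDC1) vs 1 (PDC2)
NCT: S = 56.60 (p = 0.158), M = 0.92 (p = 0.010)
TFs among DEGs: 7  top regulators: 14
GDA overlap: 0.104
drug filter: 42 -> 9
```

Reading: H = 0.43 < 0.5 confirms clustering tendency; the index vote picks
k = 2; the selected model splits the 80 cases into two 40-sample clusters
that match the planted subtypes exactly (adjusted Rand index 1). The subtype
contrast yields 48 DEGs at FDR ≤ 0.01 (50 were planted). The subtype carrying
the planted correlation blocks segregates into 2 network communities while
the other stays unstructured; the NCT finds no global-strength difference
(p = 0.16) but a significant structural difference (p = 0.01). The drug
filter reduces 42 candidate compounds to 9, attributing every exclusion to
its first failing stage.

## Command line

```sh
Rscript inst/cli/netsubtype.R run --config cfg.yaml --seed 12345 --out out/
```

Subcommands: `run`, `simulate`, `cluster`, `de`, `nct`, `enrich`, `drugs`.
Exit codes: 0 success, 2 invalid configuration, 3 no cluster structure
(Hopkins verdict), 4 stage failure.

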