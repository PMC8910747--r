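---
title: "netsubtype: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netsubtype: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery behind `netsubtype`, the
choices that were genuinely open when the package was designed, and what the
synthetic-data tests do and do not establish. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The problem

Bulk RNA-seq of post-mortem brain tissue from a clinically heterogeneous
disease (the motivating case is Parkinson's disease, cases vs. normal
controls pooled from several public studies) is mined for *molecular
subtypes*: the pipeline clusters case samples on expression alone, then asks
how the resulting subtypes differ — in survival and pathology staging, in
differential expression, in co-expression network wiring, and finally in
which regulator genes and interacting compounds might be subtype-relevant.

## Synthetic cohort generator

`simulate_cohort()` draws counts gene-wise from a negative binomial with

$$\mu_{gs} = \mu_g \cdot 2^{\mathrm{lfc}_g I[s \in \text{affected}] +
  \beta_{b(s),g} + \sum_k \lambda_k f_{ks}}, \qquad
  \mathrm{Var} = \mu + \phi\,\mu^2,$$

where $\mu_g$ is log-normal (`nb_mu_log_mean = 4`, `nb_mu_log_sd = 1.5`,
i.e., median ≈ 55 counts with a realistic heavy right tail), $\phi = 0.2$ is
a typical bulk-tissue dispersion, $\beta$ are per-(batch, gene) Normal(0,
`batch_effect_sd` = 0.5) log2 factors, and $f_k$ are standard-normal latent
factors shared by a gene block within one group (default: two blocks with
loading 0.8, active only in the first case subtype, carved from the subtype
DE genes). Defaults mirror the motivating cohort: subtype sizes 50/65,
94 controls (the source reports 94 and 95 in different places; 94 was
chosen), 3 study batches assigned round-robin within each group so batch is
never confounded with diagnosis, 42 subtype-DE genes of which 6 are
designated transcription factors, and planted |log2FC| ~ N(2, 0.5) with
random sign. Age at death and Braak stage are simulated with configurable
subtype shifts (`age_shift = 5` years, `braak_shift = 1` stage) so the
clinical-comparison stage has signal; the source reports such differences
but no generative model, and these magnitudes are plausible clinical
effect sizes.

What the generator does *not* emulate: gene-length effects, sample-quality
gradients, RNA composition shifts beyond those implied by the planted DE
genes, zero inflation, or correlated batch-by-group structure. Two
consequences surfaced during development and are worth knowing:

* **Library-size confounding.** A batch factor multiplying *every* gene is
  mathematically indistinguishable from a sequencing-depth difference, and
  is silently absorbed by CPM normalization; batch-recovery tests therefore
  plant shifts on a subset of genes.
* **CPM composition coupling.** When a large fraction of genes (or of the
  library mass) is DE or co-regulated, CPM normalization couples all genes
  through the library total — spurious logFC and correlations appear. At
  realistic gene counts (hundreds to tens of thousands with a small DE
  fraction) the effect is negligible; tests use such regimes. No TMM-style
  correction is applied because log2-CPM is the stated expression scale.
* **Noise floors.** Near-zero-count genes and large dispersions bound the
  attainable log-scale correlation regardless of the latent-factor loading;
  the factor-mechanism test therefore uses homogeneous moderate abundance.

A green synthetic test establishes that the *machinery* is correct and that
recovery works in the stated regime; it does not certify performance on any
particular real cohort.

## Preprocessing

* **Integration** keeps the intersection of gene sets (first-input order)
  and concatenates samples.
* **Grubbs screening** is a single-pass two-sided test at α = 0.05 on one
  demographic variable among cases (age at death by default):
  $G = \max_i |x_i - \bar x| / s$ against
  $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$ the upper
  $\alpha/(2n)$ Student-t quantile on $n-2$ df. Single-pass because the
  motivating analysis removed exactly one subject; `iterate = TRUE` exposes
  the sequential variant.
* **Low-count filter**: per-gene *totals* against the type-7 (linear
  interpolation) 15th percentile of the totals, strict inequality. The
  filter basis (totals vs. means vs. per-sample values) is not pinned down
  by the source; totals are the simplest reading consistent with one global
  threshold, and the percentile is configurable.
* **Batch adjustment** re-implements the NB quantile-mapping idea (the
  original analysis used ComBat-seq): per gene, group effects are estimated
  by library-size-offset regression pooling batches; batch factors are
  residual ratios against that fit; dispersions are method-of-moments
  (floored at 1e-8), per batch for the source distribution and pooled for
  the batch-free target. Each count maps through its batch CDF midpoint
  $u = F(x-1) + \tfrac12 f(x)$ to the target quantile, rounded,
  non-negative. Simplifications vs. ComBat-seq: moment dispersion estimates
  instead of empirical-Bayes shrinkage, and a multiplicative mean model.
  Batches perfectly confounded with groups are refused.
* **log2-CPM**: $\log_2\!\big((x + 0.5)/(\mathrm{lib} + 1)\cdot 10^6\big)$.

## Subtype discovery

Cases only are clustered (the control group is excluded, following the
phrase "clustering tendency of the PD gene-expression data"), on
gene-standardized log2-CPM of the batch-adjusted counts.

* **Hopkins statistic** with the bounding-box uniform reference; H near 0 ⇒
  clusterable, early-stop threshold default 0.5 (configurable). A
  calibration caveat: on Gaussian-like high-dimensional data H sits
  noticeably *below* 0.5 even without cluster structure (the uniform
  reference is more dispersed than the data), so the default threshold
  almost never triggers an early stop on expression data; a user wanting a
  calibrated gate should set the threshold from a permutation/reference
  null for their data regime.
* **Best k** by majority vote of average silhouette, Calinski–Harabasz,
  Dunn, Davies–Bouldin and the Hartigan rule (H(k) ≤ 10), each scoring
  average-linkage cuts of one reference tree; ties go to the smallest k.
  The referenced tooling computes ~30 indices; this five-index default
  covers the main families (cohesion/separation, variance ratio, elbow) and
  is configurable.
* **Portfolio**: 8 algorithms × {euclidean, manhattan}. `hierarchical_kmeans`
  cuts a centroid-linkage tree and refines with k-means from the cut means.
  "Centroid linkage with manhattan distance" is formally inconsistent
  (centroid linkage presumes squared-Euclidean geometry); the tree is built
  by the generalized Lance–Williams update on the chosen metric's distances,
  which is what common implementations do — documented caveat. The k-means
  refinement uses Euclidean updates regardless of the tree metric. CLARA
  uses 5 subsamples of size max(40 + 2k, n/5). k-means with a non-Euclidean
  metric is skipped with a log entry.
* **Validity and selection**: silhouette (singletons score 0) and Dunn
  (min inter-cluster gap / max intra-cluster diameter, zero diameter guarded
  by the sentinel 1e12), each on the model's own metric; selection is argmax
  silhouette, ties by Dunn then algorithm name. One guard was added after
  observing a failure mode: under weak separation, centroid-linkage cuts
  produce (n−1)/1 splits whose *average* silhouette beats the true
  partition. A cluster smaller than `min_cluster_size = 4` (the smallest
  group usable by the downstream correlation and clinical stages) marks the
  model failed rather than selectable.
* **Clinical comparison**: Wilcoxon rank-sum on age at death (exact when
  combined n ≤ 50 without ties), Fisher exact on sex and on Braak
  (Monte-Carlo with 1e5 draws and a fixed seed for large tables).

## Differential expression

Per-gene OLS on log2-CPM with design intercept + group indicator (no
covariate adjustment by default — the source does not state any; a
covariates argument exists). The variance prior $(d_0, s_0^2)$ is estimated
by matching the first two moments of $\log s_g^2$ to a scaled-F via
digamma/trigamma inversion; a non-positive trigamma moment falls back to
$d_0 = \infty$ (pooled variance) with a warning. Moderated
$t = \hat\beta/(\tilde s_g \sqrt{v})$ on $d_0 + d$ df, BH-FDR, DEG at
q ≤ 0.01. The log-odds B uses the standard posterior-odds formula with prior
DE proportion 0.01 and a simple moment estimate of the coefficient prior
variance from the top-|t| genes (not the quantile-matching estimator of the
reference implementation); B is descriptive output and never feeds DEG
calls. Contrasts: subtype1 vs subtype2, and each subtype vs controls, with
the Venn partition of the latter two.

## Networks

Nodes are the subtype-contrast DEGs; edges come from Pearson correlation
within each subtype's samples (log2-CPM; the source's scale is unstated and
log2-CPM keeps the DE and network stages consistent) filtered by PCIT: for
every trio, first-order partials define the tolerance ε = mean(partial /
direct) (a ratio is 0 where the direct correlation is 0; partial
denominators guarded at 1e-12), and edge (x,y) dies if some z gives
|r_xy| < ε|r_xz| and |r_xy| < ε|r_yz|. Surviving edges keep the raw r as
weight; pairs with r = 0 are never edges (a zero correlation cannot be a
significant association — this also makes the identity matrix yield the
empty network). Self-loops are dropped and isolated nodes pruned.

Communities: asynchronous label propagation on the unweighted mask, seeded
visiting order, uniform tie-breaks, 20 seeded restarts with the modal
partition and a stability fraction reported (single runs are
order-dependent). Betweenness uses 1/|w| edge lengths (the graphs are
weighted; unweighted mode is a flag) and is z-standardized; authority is the
principal eigenvector of |W| per connected component (power iteration to
1e-10 with a diagonal shift — bipartite components otherwise oscillate —
components scaled by spectral radius, global max 1). The delta standardized
betweenness between the two subtype networks is computed over the union node
set with absent nodes scored 0 before standardization.

## Network comparison (NCT)

Group labels are permuted (sizes preserved) and the entire network pipeline
is rebuilt inside every permutation; statistics are the absolute global
strength difference S, the maximum absolute edge difference M, and per-edge
absolute differences over the union edge set (the BH multiplicity universe —
the source is silent on this). Sampled permutations use the plus-one
convention p = (1 + #{≥ obs})/(1 + n), so p is never 0; when all
$\binom{n}{n_1}$ assignments fit the budget the test enumerates exhaustively
and reports exact proportions. Rebuilding inside permutations is
O(n_perm · n³) — fine at DEG-sized node sets (~42 genes); the pipeline
default is n_perm = 200.

## Regulators and drugs

TFs are DEGs present in a curated TF list (case-normalized symbols). RIF
formulas (PIF-weighted squared differential wiring for RIF1; differential
predictive ability for RIF2) follow the published RIF method that the
source's scoring package implements, with group-mean log2-CPM as the
expression values; both are z-standardized across TFs and ranked by
|z| (extremes in either direction are influential; the source does not say
signed or absolute). Note that RIF1 changes sign when the groups swap
(PIF does); only |RIF1| is swap-invariant, which is what the ranking uses.
The drug-target set is the union of top-5 genes by authority (computed on
the differential network when it is non-empty, else the first subtype
network), |RIF1|, |RIF2| and |Δ betweenness|, ties broken by gene id. The
interaction-table join is case-normalized; the sequential filter disposes
each record at its *first* failing stage (duplicated → inefficacious →
memory/excitotoxicity side effects → unknown modality of action), so the
log satisfies initial − Σ removed = final under arbitrary flag overlap.

## Annotation

ORA is the upper-tail hypergeometric P(X ≥ k) against user-supplied GMT
collections, sets intersected with the universe (genes surviving the
low-count filter — the most defensible background), sets under 3 members
skipped, BH across tested sets using the same routine as the DE stage.
Live GO/CORUM/KEGG/DisGeNET/pathway-map services are replaced by local
GMT/list fixtures with identical semantics. GDA is the fraction of DEGs in
a disease-gene list.

## Pipeline, seeding, and reproducibility

`run_pipeline()` executes the stages in a fixed order; every stochastic
stage receives a seed derived deterministically from the master seed
(default 12345, matching the source's stated seed). Runs with the same
configuration are identical. Artifacts are written with an md5 manifest;
a stage error is recorded and aborts only its dependents.

## Known limitations

* No gene-length normalization, no TMM, no voom-style precision weights.
* Batch adjustment uses moment dispersion estimates (no shrinkage) and
  cannot, by construction, separate an all-gene batch factor from
  sequencing depth.
* Hopkins' default 0.5 threshold is a convention, not a calibrated null for
  expression data (see above).
* Authority scaling across disconnected components (spectral-radius
  weighting) is one defensible choice among several; rankings within a
  component are unaffected.
* The acceptance quantities tied to the motivating study's preprocessed
  expression matrix cannot be recomputed offline; the synthetic analogues
  in `tests/testthat/test-acceptance.R` exercise the same code paths with
  known ground truth instead.
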