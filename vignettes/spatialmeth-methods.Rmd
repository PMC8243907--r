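---
title: "Methods: methylation-based spatial mapping of tumor progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-based spatial mapping of tumor progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis model

`spatialmeth` treats a multi-region tumor methylation study as a
phylogenetic problem. Each sample is a mixture of a tumor subclone and
normal stromal cells; subclones inherit the methylation state of their
ancestor and accumulate heritable changes at a sparse set of CpG probes.
Under that model, distances between samples computed over the most
variable probes approximate clonal divergence, hierarchical clustering
recovers the clonal partition, and a neighbor-joining tree rooted at the
primary sample orders divergence events. Combining the tree with the
anatomical coordinates of each sampling site yields a directional,
hypothesis-generating account of how the tumor spread — not a causal
reconstruction, since methylation distance and physical migration are
only correlated through clonal history.

Two transforms matter throughout. Beta values (methylated fraction, in
[0,1]) are what arrays report and what humans read; M values
(`log2((beta+eps)/(1-beta+eps))`) stabilize variance and are used for
distances and test statistics. Effect sizes are always reported in beta
units, statistics computed in M units. The offset `eps` defaults to 0.01
(keeps fully methylated/unmethylated probes finite); at `eps = 0` the
transform is exactly invertible, which the tests exploit.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| top-variable probes `k` | 10,000 | probes | standard choice for methylation-based tumor clustering; enough probes to smooth technical noise while concentrating clonal signal |
| selection criterion | SD of beta | — | "most variable" convention; MAD available for heavy-tailed noise |
| clustering metric / linkage | Euclidean / Ward | — | the default pairing for continuous array profiles |
| clustering space | M values | — | variance stabilization; beta-space mode retained because the convention differs between pipelines |
| number of clusters | automatic (silhouette over k = 2..6) | — | k is a finding, not an assumption; a fixed `k_clusters` reproduces a known structure |
| DMP FDR threshold | q < 0.01 | — | strict control appropriate for 850k-scale testing |
| singleton-cluster SD floor | 0.1 | M units | a one-sample cluster is scored by z against the other cluster's spread; the floor stops near-constant probes from producing unbounded statistics |
| top genes per direction | 50 | genes | a reportable short list per comparison |
| upstream regulatory window | 1,500 | bp | proximal regulatory region upstream of the TSS, strand-aware |
| CNV bin size | 50 | probes | "low-resolution" profile; median per bin resists outlier probes |
| split test | permutation, >= 1000 perms, alpha 0.01 | — | distribution-free acceptance of segment boundaries |
| amplification / gain / loss | +0.3 / +0.1 / -0.1 | log2 | the amplification bound is the conventional one; gain/loss defaults are symmetric and configurable because conventions differ |
| MGMT threshold | 0.35 | mean beta | separates the bimodal promoter states with margin on both sides; the probe list and threshold are fully configurable so a published two-probe logistic model can be layered on |
| GSEA weight `p` | 1 | — | classic weighted KS statistic; `p = 0` gives the unweighted KS statistic |

## The simulator and what it does (not) emulate

`default_cohort_config()` encodes the study conditions the pipeline is
validated against: nine anatomically annotated samples of one tumor
(one primary, eight autopsy regions), three clones with partition
{s1}, {s2,s3,s4,s9}, {s5,...,s8}, 50,000 probes, a bimodal baseline beta
mixture (55% Beta(1.5,8), 45% Beta(8,1.5)), 5% clone-defining drift
probes, drift SD 2.0 and technical noise SD 0.3 (M units), purity 0.7,
clone-specific CNV segments on the intensity channel, MGMT promoter
methylation lost in the contralateral clone, and stromal admixture over a
five-type signature with a fibroblast enrichment planted in that same
clone.

Design choices worth spelling out:

* **Drift acts in M space** and is mapped back to beta through the
  logistic, so values stay in [0,1] without truncation artifacts; a fixed
  drift-probe subset is shared across edges so clusters separate on a
  sparse signature.
* **Clone-tree edge lengths default to 24** (drift-length units) on both
  root edges. The choice was made by a design calculation, not by the
  paper: with drift SD 2.0 per unit length, edge length 24 gives
  clone-defining probes shifts of ~10 M units — full methylation-state
  switches — which after purity attenuation leaves bulk-level beta
  contrasts of ~0.5 between clones. That is the regime where the
  three-clone structure is recoverable by silhouette-selected k with a
  stable margin; shorter edges (below ~16) leave the singleton primary
  clone penalized enough by the silhouette convention (singletons score 0)
  that k = 2 wins. Symmetric edges reflect the observed geometry that the
  two recurrent clones resemble the primary more than each other.
* **Stroma follows the genome-wide baseline** (normal tissue), is
  MGMT-unmethylated, and follows the signature columns on the signature
  probes; mixing is linear in beta space at `1 - purity`.
* **MGMT promoter betas are a clone-state property** (one Beta-drawn
  profile per state, shared by samples in the same state, no technical
  noise added), reflecting that promoter methylation is inherited
  clonally.
* **CNV affects only the intensity channel**, not beta values; the two
  read-outs are treated as parallel, as array pipelines do.

The simulator does *not* model probe cross-reactivity, SNP-affected
probes, batch effects, bisulfite-conversion failure, purity variation
between samples, or spatially continuous (non-clonal) drift. Passing
tests therefore demonstrate that the pipeline recovers planted clonal
structure under realistic noise — not that any particular patient dataset
would yield the same clusters, gene lists or p-values. No quantitative
inter-sample methylation distances from real cohorts were available to
calibrate against, and the tests make no such claim.

## Numerical and procedural choices

* **Ties** are broken deterministically everywhere: probe selection by
  probe id, gene rankings by symbol, automatic k by the smaller k.
* **Missing betas** are imputed by probe-wise median after dropping
  probes missing in more than half the samples — deterministic and
  order-independent. Coordinates are 1-based and fully closed
  (array-manifest convention); upstream distance is strand-aware.
* **Singleton clusters in DMP**: the primary resection is its own cluster
  (n = 1), which no two-sample test handles. The z-against-cluster score
  with an SD floor is this package's documented choice, recorded in the
  output metadata (`attr(result, "test")`), not presented as a published
  method's behavior.
* **Neighbor joining** can produce slightly negative branch lengths;
  they are clamped to zero and the clamp is reported. The NJ tree (not
  the dendrogram) defines the phylogeny; the dendrogram is retained for
  the heatmap-style output. The tree is rooted on the edge adjacent to
  the primary sample, following the narrative that recurrences diverged
  from the original tumor.
* **Spread-path traversal** passes transparently through degree-2 nodes
  (artifacts of rooting on an edge) and visits shorter branches first;
  internal nodes inherit the centroid of their descendant leaves'
  coordinates.
* **Segmentation** is recursive binary splitting with a seeded
  permutation test on the maximal two-sample t statistic. The split
  search leaves at least `min_segment_bins` (default 3) bins on each
  side; segment means are probe-weighted so they reconstruct the binned
  series exactly.
* **Deconvolution** replaces a nu-SVR-based published tool with exact
  simplex-constrained least squares (active-set support enumeration):
  deterministic, dependency-light, and satisfying the same contract
  (non-negative, sum-to-one fractions with a reported residual). It is a
  stand-in with the same interface, not a reimplementation of that tool.
* **Enrichment p-values** use gene-label permutation: with one to four
  samples per cluster, sample permutation is degenerate. p-values are
  bounded below by `1/(n_perm+1)`; the whole-list gene set is defined to
  score 0.
* **Cell-type comparisons** are reported per type without multiplicity
  correction by default (mirroring per-type reporting conventions), with
  a BH option. Because fractions are compositional, an enrichment planted
  in one type necessarily depresses the others; perfectly separated types
  can tie the planted type's rank-test p-value.

## Problem sizes

Unit tests run on cohorts of 1,000–20,000 probes; recovery and
acceptance checks use the full default configuration (50,000 probes,
nine samples, 20 seeds), which simulates and clusters in about a second
per seed on a single core. The complete default pipeline — all stages
including 1,000-permutation segmentation and enrichment — finishes in a
few minutes on one core.

## Known limitations

* The spread path is a heuristic ordering of the phylogeny against
  anatomy; it does not model migration dynamics and has no uncertainty
  quantification (no bootstrap support values).
* With a single primary sample, rooting and all primary-versus-recurrence
  comparisons rest on one column of data; the z-score handling makes this
  explicit rather than solving it.
* Copy-number calls are not corrected for purity or ploidy and are
  relative to each sample's own median state.
* Automatic k by mean silhouette systematically penalizes singleton
  clusters (they contribute width 0); very small true clusters require
  strong separation before automatic selection finds them, which is why
  `k_clusters` can be fixed.
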