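# tpghallmarks

Reciprocal chromosomal translocations fuse a 5′ partner gene (contributing
promoter and upstream coding sequence) to a 3′ partner gene (contributing the
downstream coding sequence and its 3′-UTR), and such fusion genes drive many
hematological cancers. This package implements, as one tested pipeline, the
statistical characterization of translocation partner genes (TPGs): which
regulatory and genomic features distinguish 5′ from 3′ partners, which
functional domain combinations fusion proteins retain, and what role nuclear
organization and replication timing play in partner choice and clinical
recurrence.

It is written for computational biologists who have a table of translocation
breakpoints (transcript coordinates per partner), gene models, protein domain
annotations, and standard genomic tracks (peaks, signal, replication timing,
binned Hi-C contact matrices), and who want the full battery of comparisons
with calibrated permutation statistics. A synthetic-data module generates
every input with known planted effects, so each stage of the pipeline is
verifiable end to end without any external download.

## What it computes

* **Expression and regulation** — per-tissue and per-lineage (EPI/HEM/MES)
  expression aggregation; paired 5′−3′ Wilcoxon comparisons; Pol2 peak
  frequency in ±3 kb promoter windows (proportion of cell lines with a peak,
  z-normalized per cell-line group); strand-oriented H3K4me3 promoter
  meta-profiles; 3′-UTR length, conserved elements and microRNA target sites.
* **Fusion domain analysis** — breakpoints converted to amino-acid
  coordinates (`aa = floor((bp − cds_start)/3) + 1`); a domain is retained
  only if it lies entirely on the kept side of the junction. Retained domains
  map to five functional categories — D (DNA binding), P (protein
  interaction), H (histone modification), K (kinase), O (other), with N for
  no retained domain — and each fusion yields a 10-bit functional profile.
  The 6×6 category co-occurrence matrix is tested against the permutation
  null that shuffles 3′ category sets across fusions, with per-cell fold
  (observed / mean permuted count), add-one empirical p-values and
  Benjamini–Hochberg control at q = 0.10. Partner-type (type 1 = any of
  D/P/H/K, type 2 = O/N only) dependence by Fisher exact test, plus
  clustering of functional profiles with a mixture of independent Bernoulli
  components fitted by EM, the number of clusters selected by 10-fold
  cross-validated held-out likelihood.
* **Nuclear position (Hi-C)** — mean trans (interchromosomal) contact
  frequency of TPG pairs against four permutation nulls: shuffled pairing,
  one side replaced by random genes (either side), and both sides random;
  k-means partition of bins into central/peripheral compartments from
  trans-contact profiles; per-locus centrality (mean trans contact);
  lineage comparison of pair contacts between two cell lines’ matrices;
  chromosome-pair closeness from full trans blocks.
* **Replication timing** — LOESS smoothing of RT profiles, per-gene RT at the
  gene midpoint, early defined as RT > 0.5, and early/late enrichment of a
  gene set against background by exact binomial test.
* **Clinical recurrence** — rare (one report) vs frequent (more than one)
  fusions compared by Mann-Whitney on contact frequency, 5′ expression,
  3′ interaction-interface count, RT and centrality.

## Worked example

```r
library(tpghallmarks)

cfg <- simulation_config(seed = 1)        # the reference synthetic study
simulate_bundle(cfg, "results/bundle")    # writes all input files + truth.json

p <- pipeline_config("results/bundle", "results/out", seed = 7,
                     n_perm_domains = 2e4, n_perm_spatial = 2e3)
s <- run_pipeline(p)

s$expression$paired_median_diff
#> [1] 1.085931
s$domains$n_over
#> [1] 2
s$domains$t2t2_fraction
#> [1] 0.39
```

The paired median difference of 1.09 log2 units recovers the generator's
planted +1 hematopoietic expression shift of 5′ TPGs; the over-represented
co-occurrence cells include the planted 3-fold (O, K) pair; and 39% of
fusions have type-2 domains on both sides under this category frequency
profile. Stage tables (co-occurrence folds, q-values and directions, cluster
assignments, proximity p-values per scheme, bin partition BED, RT enrichment,
recurrence tests) land under `results/out/`, with headline statistics in
`summary.json`.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow over the reference bundle:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_expression_regulation.R   # ... through 06_recurrence.R
```

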