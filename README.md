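# lncDosage

Genomic-imbalance analysis of aneuploid transcriptomes, centred on the
lncRNA side of dosage regulation.

In an aneuploid genome — e.g. a metafemale fly (XXX; AA) — gene
expression can follow copy number (*dosage effect*, case/control ratio
3/2), return to diploid levels (*dosage compensation*, ratio 1), or be
repressed genome-wide by the stoichiometric imbalance of regulators
(*inverse dosage effect*, ratio 2/3; twice-hit genes show the *double
inverse* ratio (2/3)² ≈ 0.44). `lncDosage` implements the full analysis
chain used to detect and dissect these regimes from bulk RNA-seq counts,
for computational biologists who want the method reusable, testable, and
runnable without any data download:

* **Ratio-distribution analysis** — per-gene case/control CPM ratios,
  binned frequency distributions (0.05-wide bins centred on the canonical
  ratios), modal peaks, per-chromosome medians, and nearest-canonical
  dosage-class calls for the ratio set {0.44, 0.67, 1.0, 1.5}.
* **Differential expression** — an internal negative-binomial Wald test
  (log2FC of group-mean CPMs; `var = μ + αμ²` delta-method SE; shrunk
  moment dispersion) with BH correction and the strict screening rule
  |log2FC| > 1, padj < 0.05; external DE tables can be ingested instead.
* **lncRNA positional classes** — lincRNA / intronic / antisense / sense
  relative to coding genes (gene-level interval model).
* **Target prediction** — cis by co-location (gap ≤ 10 kb, closed
  1-based intervals), trans by co-expression (Pearson on log2(CPM+1)
  across all samples, |r| > 0.95 and p < 0.01, strict).
* **Network hub analysis** — bipartite lncRNA–mRNA graphs and an
  eleven-metric centrality table (MCC, DMNC, MNC, Degree, EPC,
  Bottleneck, Eccentricity, Closeness, Radiality, Betweenness, Stress),
  with hub selection by maximal clique centrality,
  `MCC(v) = Σ_{cliques C ∋ v} (|C|−1)!`.
* **Over-representation & motif screening** — hypergeometric ORA against
  user-supplied term↔gene tables; recovery-AUC motif scores standardized
  to NES, selected at NES > 3.
* **Synthetic-data generator** — seeded NB count matrices with planted
  dosage classes, cis neighbours, latent-factor trans partners and
  knockdown (global ratio shift) scenarios, emulating the two-group
  aneuploid design end to end.

## Worked example

Simulate the default metafemale-like dataset and walk the chain:

```r
library(lncDosage)

ds <- simulate_dataset(sim_config(seed = 42))
ds
#> sim_dataset: 1355 genes (228 lncRNA) on 7 chromosomes; 3+3 samples;
#>   20 planted cis, 20 planted trans

ratios <- expression_ratio(ds$counts, annotation = ds$annotation)
hX <- ratio_histogram(ratios$ratio[ratios$chrom == "X" &
                                   ratios$biotype == "coding"])
modal_bin(hX)
#> [1] 0.95
```

The X-linked peak sits at the compensation ratio (within one 0.05 bin —
the ratio-of-means statistic tilts its mode a few percent low at this
dispersion; see the vignette), while autosomal medians fall between the
inverse-effect ratio 0.67 and 1, chromosome 4 rises above 1, and X sits
just above 1:

```r
chromosome_medians(ratios)[1:6, ]
#>   chrom biotype   n median_ratio
#> 1    2L  coding 207        0.701
#> 2    2R  coding 199        0.710
#> 3    3L  coding 205        0.737
#> 4    3R  coding 210        0.719
#> 5     4  coding  33        1.192
#> 6     X  coding 258        1.049

de <- call_de(nb_wald_test(ds$counts, annotation = ds$annotation))
attr(de, "summary")
#>   biotype n_up n_down n_ns
#> 1  coding    6     97 1009
#> 2  lncRNA    2     23  203
#> 3    mito    2      3   10
```

Downregulation dominates (the autosomal inverse effect), and the lncRNA
fraction is hit relatively harder than mRNAs — the signature the method
is built to expose. A hub lncRNA connected to 30 targets in a bipartite
network scores exactly its degree under MCC:

```r
star <- build_network(data.frame(lncRNA_id = "lnc:hub",
                                 target_id = sprintf("m%02d", 1:30)))
mcc(star)[["lnc:hub"]]
#> [1] 30
```

The whole chain, with every intermediate written to disk plus a JSON
summary:

```r
res <- run_pipeline(pipeline_config(seed = 42), "out/")
```

A thin CLI wrapper is included at `inst/scripts/run_pipeline.R`.

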