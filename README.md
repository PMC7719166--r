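# skipmeth

Analysis of a two-condition (e.g. wild-type vs. knockout) methylome and
transcriptome comparison from aligned sequencing data, plus a fully
deterministic synthetic-data generator for validating every stage against
planted ground truth.

The package is aimed at epigenomics analysts who have (i) aligned
whole-genome bisulfite reads for two conditions, (ii) split-aligned RNA-seq
reads, and (iii) a per-gene expression table, and who want the standard
chain of derived quantities:

* **Per-CpG methylation calls** from the C>T transition frequency at each
  CpG (minus-strand G>A calls folded onto the plus-strand C), with a
  coverage threshold;
* **Global mCG percentage** (call-weighted) and per-region means
  (site-weighted);
* **Metagene profiles**: each promoter (2 kb upstream of the TSS), 5'UTR,
  exon, intron and 3'UTR scaled to 50 bins and averaged across genes;
* **DMRs** between the two methylomes from a Fisher-exact sliding window
  over co-covered CpGs (window of 5 CpGs, |Δ| ≥ 0.2, p < 0.01,
  Benjamini–Hochberg q-values over windows), merged into CpG-bounded
  regions, then filtered to hypomethylated regions strictly longer than
  200 bp and annotated to gene elements;
* **Exon-skipping rates** for a target exon from junction evidence,

  ```
  skipping rate = Rs / (Ri + Rs)
  ```

  where Ri counts reads proving inclusion and Rs reads proving skipping,
  reads overlapping intronic sequence are excluded, and samples with
  Ri + Rs = 0 are dropped; cohorts are compared with ANOVA + Tukey HSD;
* **Integration**: Spearman correlation between a gene's total gene-body
  DMR length and its expression log2 fold change;
* small utilities (caliper tumor volume `L × W² / 2`).

File formats go through the usual Bioconductor machinery: FASTA via
Biostrings, GTF/BED/bedGraph via rtracklayer, SAM/BAM via
Rsamtools/GenomicAlignments.

## Worked example

The whole pipeline runs end-to-end on synthetic data with recorded truth:

```r
library(skipmeth)

cfg <- synthetic_config(seed = 1)   # 400 kb, 20 genes, 30x, WT 76.9% mCG,
                                    # KO background 68.4% + 20 planted
                                    # hypomethylated gene-body DMRs (Δ -0.4)
res <- run_demo(cfg, outdir = "demo_out")
res$summary$global_mcg
```

prints (numbers from this exact run):

```
WT global mCG: 77.01% (truth 76.90%)
KO global mCG: 66.69% (truth 66.46%)
gap: 10.32 percentage points
```

The called, filtered DMRs recover the planted regions:

```r
res$filtered_dmrs[1:3, c("start", "end", "length", "n_cpgs",
                         "level_a", "level_b", "delta")]
#>   start   end length n_cpgs level_a level_b  delta
#> 1  6215  6813    599     64   0.768   0.384 -0.384
#> 2  7070  7837    768     83   0.764   0.396 -0.367
#> 3 25662 26639    978    104   0.775   0.392 -0.383
```

and the exon-skipping cohort (true group rates 5% and 30%, 10 samples of
500 reads each) comes back as:

```r
res$summary$skipping$group_means
#> $normal  0.0506
#> $tumor   0.3026
```

with Tukey-adjusted group separation at p < 1e-17, and the planted
DMR-length/fold-change coupling is detected (rho = 0.67, p = 0.004 over
the 16 DMR-carrying genes of this small genome). A single-sample skipping
estimate works directly from counts:

```r
skipping_rate(47, 3)
#> exon skipping rate 0.0600 (Rs=3, Ri=47; 95% CI 0.021-0.162)
```

`demo_out/` holds every stage artifact: `genome.fa`, `genes.gtf`,
`truth.json`, per-condition `*.bedgraph` methylation tracks,
`profile.tsv` (50-bin metagene table), `dmrs.bed`, `rates.tsv`,
`expression.tsv`, `corr.tsv` and `summary.json`, each stamped with the
package version, config hash and seed.

## Scope notes

Read alignment (bisulfite and RNA-seq) is upstream of this package; the
simulators emit pre-aligned reads for the same reason. Non-CG contexts,
smoothing/HMM DMR inference and replicate dispersion models are out of
scope; see the methods vignette (`vignettes/methylome-workflow.Rmd`) for
the full model description and design rationale.
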