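---
title: "Methylome and exon-skipping analysis with skipmeth"
author: "skipmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome and exon-skipping analysis with skipmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipmeth)
```

## What the package models

`skipmeth` implements the computational core of a two-condition
methylome/transcriptome comparison, of the kind used to characterise the
liver of a DNA-methyltransferase knockout against its wild-type control:

1. **Per-CpG methylation calling.** After bisulfite treatment an
   unmethylated cytosine reads as T while a methylated cytosine stays C, so
   the methylation level of a CpG is the frequency of retained C among
   informative reads — the C>T transition frequency at the locus. Reads on
   the minus strand are read out at the complementary G (G retained =
   methylated, G>A = converted) and folded onto the plus-strand C, the
   standard symmetric-CpG convention.
2. **Global and regional mCG summaries.** The genome-wide mCG percentage is
   call-weighted (total methylated calls over total calls), matching how
   global WGBS levels are conventionally reported; regional means over a
   single DMR are site-weighted (each covered CpG counts once), matching
   per-region validation figures. The two weightings answer different
   questions and are deliberately not interchangeable.
3. **Metagene profiles.** Each instance of each gene functional element
   (2 kb promoter upstream of the TSS, 5'UTR, exon, intron, 3'UTR) is
   scaled to 50 bins; covered CpGs contribute their level to the bin at
   their proportional position, and bins of minus-strand genes are reversed
   so bin 1 is always 5'.
4. **DMR calling.** A sliding window of consecutive co-covered CpGs is
   tested by Fisher's exact test on pooled methylated/unmethylated counts;
   significant, large-effect windows of the same sign merge into regions.
   Regions are then filtered by the workflow's length rule (strictly longer
   than 200 bp, the conventional lower bound for CpG-island-scale features)
   and by direction (hypomethylated in the second condition).
5. **Exon-skipping rate.** For a target exon, reads around it partition
   into inclusion evidence (Ri), skipping evidence (Rs: a junction joining
   an upstream to a downstream exon), excluded reads (any aligned block
   overlapping intronic sequence) and uninformative reads. The rate is
   Rs/(Ri+Rs); a sample with Ri+Rs = 0 is excluded from cohort summaries.
   Cohorts are compared by one-way ANOVA with Tukey's HSD.
6. **Methylome-transcriptome integration.** Per gene, the total length of
   filtered DMRs intersected with the gene body (exons plus introns) is
   correlated with the expression log2 fold change.

## The synthetic study and its ground truth

All statistical claims are validated against a generator
(`make_genome_and_annotation()` and friends) that emulates the study
design with recorded truth:

* A single-chromosome genome laid out as evenly spaced multi-exon genes on
  alternating strands. Sequence is uniform-random ACGT; CG dinucleotides
  are thinned ~7-fold in intergenic space and enriched (planted at an extra
  1/16 per bp, roughly doubling density) in gene bodies and promoters, so
  regional methylation signal concentrates on genes the way CpG-island and
  gene-body methylation does.
* The wild-type methylome is flat at `wt_mcg` (default 0.769, the scale of
  a mammalian liver methylome); the knockout is flat at `ko_background_mcg`
  plus planted contiguous hypomethylated regions of effect `delta`
  (default −0.4) placed inside CDS bounds so every planted base is exonic
  or intronic. The default background (0.684) makes the knockout's
  genome-wide truth mean land near 66%, a ~10.5-point contrast.
* Bisulfite reads are emitted pre-aligned (the workflow starts from mapped
  data; alignment is upstream of this package). At each CpG a covering
  read shows C with probability `m·ce + (1−ce)` where `ce` is the
  conversion efficiency (default 0.995, typical of commercial kits);
  non-CpG cytosines convert with probability `ce`. The caller reports raw
  transition frequency without conversion correction — the simulator knob
  exists to study the induced bias (at `ce = 0.995` the bias is
  `(1−m)·0.005`, well under a percentage point), not to remove it.
* Methylation states are drawn independently per site per read; no
  read-level haplotype correlation is modelled, because all downstream
  statistics use per-site aggregates only.
* Junction reads for a target exon are the skipping form with the
  configured probability, otherwise inclusion forms (contained in the
  target exon, or spanning an annotated adjacent junction); 5% decoy reads
  straddling an exon/intron boundary exercise the exclusion rule. Read
  names carry their generating class so tests can verify decoys never
  reach Ri or Rs.
* Expression tables couple the log2 fold change to planted gene-body DMR
  length with slope `fc_coupling` (default 0.001 per bp) plus Gaussian
  noise (SD 0.5).

Everything derives from one root seed through fixed per-stage substreams,
so identical configs give byte-identical outputs and each stage is
reproducible in isolation.

What the generator does **not** emulate: sequencing errors and quality
scores, PCR duplicates, M-bias, coverage biases, CHG/CHH contexts,
replicate-to-replicate biological dispersion, and realistic genome
composition. Passing tests therefore demonstrate correctness of the
implemented statistics under idealised sampling, not robustness to every
artefact of real WGBS libraries.

## Design choices in detail

**Coordinates.** Internally everything is 1-based closed, the native
convention of IRanges/GRanges; GTF shares it, and BED/bedGraph conversion
happens inside rtracklayer at the file boundary. A single internal
convention prevents off-by-one drift.

**Element priority.** A position covered by several genes' annotations
gets one label by priority promoter > 5'UTR > 3'UTR > exon > intron,
promoters first because promoter methylation is the usual interpretive
frame. Promoters truncated at a chromosome boundary are kept at reduced
length.

**DMR caller.** Defaults: window of 5 co-covered CpGs, `min_delta = 0.2`,
`alpha = 0.01` on the window p-value, regions need ≥ 4 CpGs, and marked
windows merge across gaps < 100 bp when no opposite-sign window
intervenes. The single-methylome-per-condition design pools counts; no
dispersion model is fitted, so p-values describe sampling noise, not
biological variability. Benjamini–Hochberg q-values are computed over all
tested windows and carried onto regions for null-calibration checks. DMR
length is last member CpG minus first plus one — CpG-bounded spans, which
is why lengths as short as ~50 bp can occur before filtering. The length
filter is strict ("longer than" 200 bp drops a region of exactly 200).
The Fisher p-value is computed vectorised from the hypergeometric density
and is checked against `stats::fisher.test` in the test suite.

**Detection operating point.** At 30x depth and the default window, a
planted −0.4 difference yields pooled Fisher p-values far below `alpha`,
giving recall and precision at or near 1 against planted truth with
boundary error within one window span; residual false positives are
CpG-bounded fragments shorter than 200 bp, which the length filter
removes. On null data (identical truth methylomes) the fraction of
windows with q < 0.05 sits at or near zero.

**Exon-skipping classification.** "Reads spanning introns" are excluded —
read as reads whose aligned blocks overlap intronic sequence
(intron-retention and boundary-straddling reads), since skipping reads
necessarily span introns via junctions and cannot be the excluded class.
Inclusion does not require a junction by default (a read fully contained
in the target exon counts as Ri; otherwise long exons would undercount
inclusion), with a `junction_only` mode for sensitivity analysis. The
neighbourhood inspected runs from the nearest upstream exon's start to the
nearest downstream exon's end. Wilson score intervals accompany each rate
but never drive exclusion; only Ri+Rs = 0 excludes a sample.

**Metagene averaging.** Bin means pool CpG observations across genes
(`pooled`), with a `per_gene` mode (average of per-gene means) provided
because aggregate-curve figures admit both readings; pooled is the default
as the more literal reading of averaging the site levels of corresponding
bins. A site exactly on an internal bin boundary goes downstream.

**Correlation.** Spearman by default — planted and real DMR-length
distributions are heavy-tailed — with Pearson behind a flag. The default
population is genes carrying at least one filtered DMR; zeros-included
mode exists for sensitivity. Fold changes are computed from the provided
expression values with an optional pseudocount (default 0; non-positive
values are flagged and dropped).

## Problem sizes used in validation

The shipped tests run the full chain at the scales the statistics need:
per-site calling checks at 100x on a 20 kb genome; global mCG at 30x on
50 kb (recovered within 1 percentage point of truth); the WT/KO contrast
emulation at 30x on 400 kb (truth means 76.9% / 66.4%); DMR recovery on a
1 Mb genome with 20 planted regions (filtered recall and precision ≥ 0.9
at 50% reciprocal overlap); metagene flatness on a uniform methylome over
100 compact genes; the expression coupling at 400 genes with a 100-seed
null sweep. A laptop-scale demo of the whole pipeline is
`run_demo(synthetic_config())`.

## Known limitations

* Single dominant transcript per gene; no isoform models, no GFF3.
* The methylation caller requires ungapped bisulfite alignments (M-only
  CIGARs) and calls the CG context only.
* No smoothing- or HMM-based DMR inference and no replicate dispersion
  model; with biological replicates a dispersion-aware caller would be
  preferred.
* FPKM or other expression units are consumed as given, never computed or
  re-normalised.
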