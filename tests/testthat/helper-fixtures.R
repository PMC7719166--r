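# Small builders shared across tests. Everything is constructed in code;
# no fixture files.

# A two-gene toy annotation on a 20 kb chromosome:
#   gA (+): exons 3001-3400, 4001-4400, 5001-5400, CDS 3101-5300
#   gB (-): exons 9001-9400, 10001-10400, 11001-11400, CDS 9101-11300
toy_genes <- function(chrom_length = 20000L) {
  list(
    gA = gene_model("gA", "chrT", "+",
                    c(3001, 4001, 5001), c(3400, 4400, 5400),
                    cds_start = 3101, cds_end = 5300,
                    chrom_length = chrom_length),
    gB = gene_model("gB", "chrT", "-",
                    c(9001, 10001, 11001), c(9400, 10400, 11400),
                    cds_start = 9101, cds_end = 11300,
                    chrom_length = chrom_length)
  )
}

# Per-base element labelling oracle: explicit interval checks per gene,
# applying the promoter > 5utr > 3utr > exon > intron priority by hand.
# Independent of element_ranges()/classify_position().
toy_label_oracle <- function(pos, genes) {
  vapply(pos, function(p) {
    cand <- character(0)
    for (g in genes) {
      es <- IRanges::start(g$exons); ee <- IRanges::end(g$exons)
      if (length(g$promoter) > 0 &&
          p >= IRanges::start(g$promoter) && p <= IRanges::end(g$promoter)) {
        cand <- c(cand, "promoter")
      }
      in_exon <- any(p >= es & p <= ee)
      in_span <- p >= min(es) && p <= max(ee)
      if (in_exon) {
        if (!is.na(g$cds_start) && p < g$cds_start) {
          cand <- c(cand, if (g$strand == "+") "5utr" else "3utr")
        } else if (!is.na(g$cds_end) && p > g$cds_end) {
          cand <- c(cand, if (g$strand == "+") "3utr" else "5utr")
        } else {
          cand <- c(cand, "exon")
        }
      } else if (in_span) {
        cand <- c(cand, "intron")
      }
    }
    prio <- c(promoter = 1, "5utr" = 2, "3utr" = 3, exon = 4, intron = 5)
    if (length(cand) == 0) "intergenic" else cand[which.min(prio[cand])]
  }, "")
}

# Build a methylome track directly from per-site counts.
make_track <- function(pos, n_meth, n_total, chrom = "chrT",
                       sample = "toy") {
  methylome_track(
    data.frame(chrom = chrom, pos = pos, n_meth = n_meth, n_total = n_total),
    sample = sample
  )
}

# Tiny synthetic study shared by several tests (cheap: 60 kb, 3 genes,
# few planted DMRs so placement always succeeds).
small_config <- function(seed = 7,
                         dmr_spec = list(n = 5, length_range = c(300, 700),
                                         delta = -0.4,
                                         target = "gene_body"),
                         ...) {
  synthetic_config(genome_length = 60000, n_genes = 3, seed = seed,
                   bisulfite_coverage = 15, dmr_spec = dmr_spec, ...)
}
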