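test_that("generation is bit-deterministic under a fixed config and seed", {
  cfg <- small_config(seed = 7)
  a <- make_genome_and_annotation(cfg)
  b <- make_genome_and_annotation(cfg)
  expect_identical(as.character(a$genome$sequences),
                   as.character(b$genome$sequences))
  expect_identical(a$truth$cpg, b$truth$cpg)
  expect_identical(a$truth$dmrs, b$truth$dmrs)

  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_genome_fasta(a$genome, fa1); write_genome_fasta(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  r1 <- simulate_bisulfite_reads(a$genome, a$truth, "wt", cfg)
  r2 <- simulate_bisulfite_reads(b$genome, b$truth, "wt", cfg)
  expect_identical(r1, r2)
})

test_that("planted DMRs lie on gene bodies and CpG density is gene-enriched", {
  cfg <- small_config(seed = 19)
  sim <- make_genome_and_annotation(cfg)
  tr <- sim$truth

  # every planted DMR base classifies as gene body (exon or intron)
  er <- element_ranges(sim$genes)
  for (i in seq_len(nrow(tr$dmrs))) {
    lab <- classify_position(tr$dmrs$chrom[i],
                             tr$dmrs$start[i]:tr$dmrs$end[i], er)
    expect_true(all(lab %in% c("exon", "intron")))
  }
  # inside DMRs, KO truth differs from WT by the configured delta
  inside <- rep(FALSE, nrow(tr$cpg))
  for (i in seq_len(nrow(tr$dmrs))) {
    inside <- inside | (tr$cpg$pos >= tr$dmrs$start[i] &
                          tr$cpg$pos <= tr$dmrs$end[i])
  }
  expect_true(all(abs((tr$cpg$p_ko - tr$cpg$p_wt)[inside] -
                        cfg$dmr_spec$delta) < 1e-12))

  # CpG density: count CG dinucleotides genic vs intergenic
  gb <- gene_body_ranges(sim$genes)
  cpg <- sim$genome$cpg$chrS
  genic <- rep(FALSE, cfg$genome_length)
  for (i in seq_along(gb)) {
    genic[BiocGenerics::start(gb)[i]:BiocGenerics::end(gb)[i]] <- TRUE
  }
  dens_genic <- sum(genic[cpg]) / sum(genic)
  dens_inter <- sum(!genic[cpg]) / sum(!genic)
  expect_gt(dens_genic, 2 * dens_inter)
})

test_that("bisulfite base model follows methylation and conversion", {
  # forced extremes on a tiny CpG-bearing genome covered by many reads
  g <- reference_genome(c(chrS = paste(rep("AACGTT", 200), collapse = "")))
  cpg <- g$cpg$chrS
  expect_gt(length(cpg), 0)

  mk_truth <- function(m, cfg) {
    structure(list(
      cpg = data.frame(chrom = "chrS", pos = cpg, p_wt = m, p_ko = m),
      dmrs = NULL, gene_dmr_length = numeric(0), config = cfg
    ), class = "synthetic_truth")
  }
  base_at <- function(reads, p) {
    cover <- reads$pos <= p & reads$pos + nchar(reads$seq) - 1L >= p
    substr(reads$seq[cover], p - reads$pos[cover] + 1L,
           p - reads$pos[cover] + 1L)
  }

  cfg <- synthetic_config(genome_length = 1200, n_genes = 1, seed = 3,
                          bisulfite_coverage = 40, read_length = 50,
                          conversion_efficiency = 1)
  r1 <- simulate_bisulfite_reads(g, mk_truth(1, cfg), "wt", cfg)
  r0 <- simulate_bisulfite_reads(g, mk_truth(0, cfg), "wt", cfg)
  p <- cpg[10]
  expect_true(all(base_at(r1, p) == "C"))  # fully methylated: C retained
  expect_true(all(base_at(r0, p) == "T"))  # unmethylated, full conversion

  # intermediate methylation recovered within 3 binomial SE at high depth
  cfg2 <- synthetic_config(genome_length = 1200, n_genes = 1, seed = 5,
                           bisulfite_coverage = 1000, read_length = 50,
                           conversion_efficiency = 1)
  r6 <- simulate_bisulfite_reads(g, mk_truth(0.6, cfg2), "wt", cfg2)
  b <- base_at(r6, p)
  n <- length(b)
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(mean(b == "C") - 0.6), 3 * se)
})

test_that("junction read simulation hits the requested skip rate exactly at the extremes", {
  cfg <- small_config(seed = 23)
  sim <- make_genome_and_annotation(cfg)
  g <- sim$genes[[1]]

  r0 <- simulate_junction_reads(g, 4, 0, 300, cfg, genome = sim$genome)
  expect_false(any(startsWith(r0$qname, "skip_")))
  r1 <- simulate_junction_reads(g, 4, 1, 300, cfg, genome = sim$genome)
  tl <- attr(r1, "truth_labels")
  expect_true(all(tl$label[!startsWith(tl$qname, "decoy_")] == "skip"))

  # intermediate rate within 3 binomial SE
  r3 <- simulate_junction_reads(g, 4, 0.3, 2000, cfg, genome = sim$genome)
  tl3 <- attr(r3, "truth_labels")
  frac <- mean(tl3$label[tl3$label != "decoy"] == "skip")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))

  # first/last exon cannot be skipped
  expect_error(simulate_junction_reads(g, 1, 0.3, 10, cfg), "internal")

  # emitted junction blocks match annotated exon boundaries
  blocks <- skipmeth:::.blocks_from_table(r3)
  es <- IRanges::start(g$exons); ee <- IRanges::end(g$exons)
  multi <- lengths(blocks) > 1
  for (b in as.list(blocks[multi][1:20])) {
    nb <- length(b)
    expect_true(all(IRanges::end(b)[-nb] %in% ee))
    expect_true(all(IRanges::start(b)[-1] %in% es))
  }
})

test_that("expression simulation couples fold change to planted DMR length", {
  lens <- c(a = 0, b = 100, c = 500, d = 1500)

  cfg0 <- synthetic_config(fc_coupling = 0, noise_sd = 0)
  e0 <- simulate_expression(lens, cfg0)
  expect_equal(e0$value_ko, e0$value_wt)  # fold change exactly 0

  cfgp <- synthetic_config(fc_coupling = 0.001, noise_sd = 0)
  ep <- simulate_expression(lens, cfgp)
  lfc <- log2(ep$value_ko / ep$value_wt)
  expect_true(all(diff(lfc) > 0))  # strictly increasing in length
  expect_equal(lfc, unname(0.001 * lens), tolerance = 1e-10)

  # with noise, the emitted table still carries a positive correlation
  set.seed(1)
  lens400 <- stats::setNames(runif(400, 0, 1500), sprintf("g%03d", 1:400))
  cfgn <- synthetic_config(fc_coupling = 0.001, noise_sd = 0.5, seed = 9)
  en <- simulate_expression(lens400, cfgn)
  r <- cor(lens400, log2(en$value_ko / en$value_wt))
  expect_gt(r, 0)
})

test_that("simulated SAM validates against the emitted genome", {
  cfg <- small_config(seed = 31)
  sim <- make_genome_and_annotation(cfg)
  r <- simulate_bisulfite_reads(sim$genome, sim$truth, "ko", cfg)
  L <- chrom_lengths(sim$genome)[["chrS"]]
  expect_true(all(r$pos >= 1))
  expect_true(all(r$pos + nchar(r$seq) - 1L <= L))
  # read bases differ from the reference only at C (bisulfite) positions
  one <- r[17, ]
  ref <- substr(as.character(sim$genome$sequences[[1]]), one$pos,
                one$pos + nchar(one$seq) - 1L)
  diffs <- which(strsplit(ref, "")[[1]] != strsplit(one$seq, "")[[1]])
  expect_true(all(strsplit(ref, "")[[1]][diffs] == "C"))
  expect_true(all(strsplit(one$seq, "")[[1]][diffs] == "T"))
})
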