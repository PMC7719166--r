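test_that("vectorised Fisher p-values match stats::fisher.test", {
  set.seed(21)
  ta <- sample(5:60, 40, replace = TRUE)
  tb <- sample(5:60, 40, replace = TRUE)
  ma <- rbinom(40, ta, runif(40))
  mb <- rbinom(40, tb, runif(40))
  mine <- fisher_p_2x2(ma, ta, mb, tb)
  ref <- mapply(function(a, at, b, bt) {
    stats::fisher.test(matrix(c(a, at - a, b, bt - b), 2))$p.value
  }, ma, ta, mb, tb)
  expect_equal(mine, unname(ref), tolerance = 1e-9)
})

test_that("identical tracks produce zero DMRs", {
  tr <- make_track(seq(100, 1000, by = 50), 15, 20)
  d <- call_dmrs(tr, tr)
  expect_equal(nrow(d), 0)
  w <- attr(d, "windows")
  expect_true(all(w$p > 1 - 1e-9))
})

test_that("a fully differential 10-CpG block yields one DMR with the pooled Fisher p", {
  pos <- seq(1000, 1180, by = 20)           # 10 CpGs, span 181 bp
  a <- make_track(pos, 20, 20)              # 20/20 methylated
  b <- make_track(pos, 2, 20)               # 2/20 methylated
  d <- call_dmrs(a, b, window_cpgs = 5, min_delta = 0.2, alpha = 0.01,
                 min_cpgs = 4)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_cpgs, 10)
  expect_equal(d$start, 1000)
  expect_equal(d$end, 1180)
  expect_equal(d$length, 181)
  expect_equal(d$delta, -0.9)
  # region p = min window p = pooled 100/100 vs 10/100 Fisher (all windows
  # are identical); checked against the hypergeometric oracle
  oracle <- stats::fisher.test(matrix(c(100, 0, 10, 90), 2))$p.value
  expect_equal(d$p_value, oracle, tolerance = 1e-9)
})

test_that("DMR calling is antisymmetric in the track order", {
  cfg <- small_config(seed = 3)
  sim <- make_genome_and_annotation(cfg)
  ta <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "wt", cfg), sim$genome, 4)
  tb <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "ko", cfg), sim$genome, 4)
  ab <- call_dmrs(ta, tb)
  ba <- call_dmrs(tb, ta)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$start, ba$start)
  expect_equal(ab$end, ba$end)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("lowering alpha never increases the DMR count", {
  cfg <- small_config(seed = 13)
  sim <- make_genome_and_annotation(cfg)
  ta <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "wt", cfg), sim$genome, 4)
  tb <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "ko", cfg), sim$genome, 4)
  alphas <- c(0.05, 0.01, 0.001, 1e-5)
  counts <- vapply(alphas,
                   function(a) nrow(call_dmrs(ta, tb, alpha = a)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("length and direction filters apply the strict boundary semantics", {
  d <- data.frame(
    chrom = "c", start = c(1000, 2000, 3000, 4000),
    end = c(1199, 2300, 3250, 4220),
    length = c(200, 301, 251, 221), n_cpgs = 5,
    level_a = 0.8, level_b = c(0.4, 0.4, 0.9, 0.4),
    delta = c(-0.4, -0.4, +0.3, -0.4),
    p_value = 1e-6, q_value = 1e-5
  )
  d$cpg_pos <- list(1:5, 1:5, 1:5, 1:5)
  f <- filter_dmrs(d, min_length = 200, direction = "hypo_in_b")
  # 200 bp exactly is dropped (strictly "longer than"), hyper dropped
  expect_equal(f$start, c(2000, 4000))
  expect_equal(nrow(filter_dmrs(d, 200, "both")), 3)
  expect_equal(nrow(filter_dmrs(d[0, ], 200, "hypo_in_b")), 0)
})

test_that("gene-body CpG fraction counts member CpGs by element class", {
  genes <- toy_genes()
  # 3 CpGs in gA's CDS exons/introns + 1 in gA's promoter
  d <- data.frame(chrom = "chrT", start = 2900, end = 3600, length = 701,
                  n_cpgs = 4, level_a = 0.8, level_b = 0.4, delta = -0.4,
                  p_value = 1e-6, q_value = 1e-5)
  d$cpg_pos <- list(c(2950, 3150, 3250, 3450))  # promoter, exon, exon, intron
  expect_equal(gene_body_cpg_fraction(d, genes), 75)
  expect_error(gene_body_cpg_fraction(d[0, ], genes), "no DMRs")
})

test_that("planted DMRs are recovered with high recall and precision", {
  # equal backgrounds: the planted hypomethylated regions are the only truth
  cfg <- synthetic_config(genome_length = 300000, n_genes = 10, seed = 29,
                          bisulfite_coverage = 30, ko_background_mcg = 0.769,
                          dmr_spec = list(n = 8, length_range = c(300, 1000),
                                          delta = -0.4, target = "gene_body"))
  sim <- make_genome_and_annotation(cfg)
  ta <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "wt", cfg), sim$genome, 4)
  tb <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "ko", cfg), sim$genome, 4)
  d <- call_dmrs(ta, tb)
  # the designed workflow applies the >200 bp + hypomethylation filter;
  # planted DMRs (300-1000 bp, delta < 0) all survive it
  f <- filter_dmrs(d, 200, "hypo_in_b")
  m <- match_planted_dmrs(f, sim$truth$dmrs)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
  expect_true(all(f$delta < 0))
})

test_that("the per-region report matches truth at a validation-depth DMR", {
  # a planted contrast like a targeted-validation region: truth means
  # 0.71 vs 0.34 at depth 100x
  pos <- seq(5000, 5400, by = 25)
  set.seed(77)
  a <- make_track(pos, rbinom(length(pos), 100, 0.71), 100)
  b <- make_track(pos, rbinom(length(pos), 100, 0.34), 100)
  d <- call_dmrs(a, b, window_cpgs = 5, min_delta = 0.2, alpha = 0.01)
  expect_equal(nrow(d), 1)
  rep <- dmr_region_report(d[1, ], a, b)
  expect_equal(nrow(rep), length(pos))
  means <- attr(rep, "means")
  expect_lt(abs(means[["mean_a"]] - 0.71), 0.05)
  expect_lt(abs(means[["mean_b"]] - 0.34), 0.05)

  # trivial two-site case
  a2 <- make_track(c(10, 20), c(8, 6), 10)
  b2 <- make_track(c(10, 20), c(3, 1), 10)
  r2 <- dmr_region_report(list(chrom = "chrT", start = 1, end = 30), a2, b2)
  expect_equal(unname(attr(r2, "means")), c(0.7, 0.2))
})

test_that("DMR BED round trip and annotation carry the expected columns", {
  cfg <- small_config(seed = 3)
  sim <- make_genome_and_annotation(cfg)
  ta <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "wt", cfg), sim$genome, 4)
  tb <- call_methylation(
    simulate_bisulfite_reads(sim$genome, sim$truth, "ko", cfg), sim$genome, 4)
  d <- filter_dmrs(call_dmrs(ta, tb), 200, "hypo_in_b")
  f <- tempfile(fileext = ".bed")
  write_dmr_bed(d, f, comments = "hdr")
  back <- read_dmr_bed(f)
  expect_equal(back$start, d$start)
  expect_equal(back$end, d$end)
  expect_equal(back$n_cpgs, d$n_cpgs)
  expect_equal(back$delta, d$delta, tolerance = 1e-5)

  ann <- annotate_dmrs(d, sim$genes)
  # DMRs recovering planted (gene-body) regions carry gene annotations
  tr <- sim$truth$dmrs
  on_truth <- vapply(seq_len(nrow(ann)), function(i) {
    any(ann$start[i] <= tr$end & ann$end[i] >= tr$start)
  }, TRUE)
  expect_true(any(on_truth))
  expect_true(all(nchar(ann$genes[on_truth]) > 0))
  expect_equal(vapply(ann$element_breakdown, sum, 1L), ann$n_cpgs)
})
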