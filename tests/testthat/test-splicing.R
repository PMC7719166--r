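# A 5-exon gene used throughout: exons of 200 bp separated by 600 bp introns
splice_gene <- function() {
  starts <- c(1000, 1800, 2600, 3400, 4200)
  gene_model("gS", "chrT", "+", starts, starts + 199)
}

# hand-built reads: helper mirrors the simulator's SAM fields
read_row <- function(qname, pos, cigar) {
  data.frame(qname = qname, flag = 0L, chrom = "chrT", pos = pos,
             cigar = cigar, seq = "*", stringsAsFactors = FALSE)
}

test_that("read classification follows the junction and exclusion rules", {
  g <- splice_gene()  # target exon 3: 2600-2799; flanking 1800-1999, 3400-3599
  reads <- rbind(
    # skipping: junction from exon 2's 3' end to exon 4's 5' start
    read_row("sk", 1950, "50M1400N50M"),
    # inclusion: fully inside the target exon
    read_row("in1", 2650, "100M"),
    # inclusion: junction exon2 -> exon3 at annotated bounds
    read_row("in2", 1950, "50M600N50M"),
    # inclusion spanning exon2 -> exon3 -> exon4 (covers the target)
    read_row("in3", 1980, "20M600N200M600N20M"),
    # excluded: unsplit read straddling the target's 3' boundary
    read_row("ex1", 2750, "100M"),
    # excluded: intron-retaining block between exon 2 and 3
    read_row("ex2", 2100, "100M"),
    # uninformative: entirely in a flanking exon, no junction
    read_row("un1", 1850, "100M"),
    # uninformative: unannotated junction (acceptor off by 5 bp)
    read_row("un2", 1950, "50M605N50M")
  )
  cl <- classify_reads(reads, g, 3)
  got <- stats::setNames(cl$label, cl$qname)
  expect_identical(unname(got[c("sk", "in1", "in2", "in3")]),
                   c("skipping", "inclusion", "inclusion", "inclusion"))
  expect_identical(unname(got[c("ex1", "ex2")]), c("excluded", "excluded"))
  expect_identical(unname(got[c("un1", "un2")]),
                   c("uninformative", "uninformative"))

  # exhaustiveness: every inspected read gets exactly one label
  expect_equal(nrow(cl), nrow(reads))
  expect_true(all(cl$label %in%
                    c("skipping", "inclusion", "excluded", "uninformative")))

  # junction-only mode demotes contained reads from Ri
  c_any <- count_junction_reads(reads, g, 3, inclusion_mode = "any")
  c_junc <- count_junction_reads(reads, g, 3, inclusion_mode = "junction_only")
  expect_equal(c_any$Ri, 3)
  expect_equal(c_junc$Ri, 2)
  expect_equal(c_any$Rs, 1)
})

test_that("the skipping rate is exactly Rs/(Ri+Rs) with the no-read exclusion", {
  expect_equal(skipping_rate(3, 1)$rate, 0.25)
  expect_equal(skipping_rate(7, 0)$rate, 0)
  r00 <- skipping_rate(0, 0)
  expect_identical(r00$status, "excluded_no_reads")
  expect_true(is.na(r00$rate))
  expect_error(skipping_rate(-1, 2), "non-negative")

  # formula exactness over random integer counts
  set.seed(5)
  Ri <- sample(0:500, 200, replace = TRUE)
  Rs <- sample(0:500, 200, replace = TRUE)
  for (i in seq_len(200)) {
    res <- skipping_rate(Ri[i], Rs[i])
    if (Ri[i] + Rs[i] == 0) {
      expect_identical(res$status, "excluded_no_reads")
    } else {
      expect_identical(res$rate, Rs[i] / (Ri[i] + Rs[i]))
      expect_true(res$ci_low <= res$rate && res$rate <= res$ci_high)
    }
  }
})

test_that("duplicating every read leaves the rate unchanged", {
  cfg <- small_config(seed = 51)
  sim <- make_genome_and_annotation(cfg)
  g <- sim$genes[[1]]
  jr <- simulate_junction_reads(g, 4, 0.25, 400, cfg, genome = sim$genome)
  r1 <- skipping_rate(count_junction_reads(jr, g, 4))
  jr2 <- rbind(jr, transform(jr, qname = paste0(qname, "_dup")))
  r2 <- skipping_rate(count_junction_reads(jr2, g, 4))
  expect_equal(r2$rate, r1$rate)
  expect_equal(r2$Ri, 2 * r1$Ri)
})

test_that("decoy reads are excluded and never count toward Ri or Rs", {
  cfg <- small_config(seed = 57)
  sim <- make_genome_and_annotation(cfg)
  g <- sim$genes[[2]]
  jr <- simulate_junction_reads(g, 5, 0.3, 800, cfg, genome = sim$genome)
  cnt <- count_junction_reads(jr, g, 5)
  truth <- attr(jr, "truth_labels")
  lab <- merge(cnt$labels, truth, by = "qname")
  decoys <- lab[lab$label.y == "decoy", ]
  expect_gt(nrow(decoys), 0)
  expect_true(all(decoys$label.x == "excluded"))
  expect_true(all(lab$label.x[lab$label.y == "skip"] == "skipping"))
  expect_true(all(lab$label.x[lab$label.y == "incl"] == "inclusion"))
  # therefore the estimate matches the generating label fraction exactly
  expect_equal(skipping_rate(cnt)$rate,
               sum(truth$label == "skip") /
                 sum(truth$label %in% c("skip", "incl")))
})

test_that("cohort summary reproduces group means and Tukey comparisons", {
  # identical groups: all pairwise mean differences 0, adjusted p ~ 1
  same <- data.frame(
    sample = sprintf("s%d", 1:6),
    group = rep(c("x", "y"), each = 3),
    rate = rep(c(0.1, 0.2, 0.3), 2),
    status = "ok"
  )
  s1 <- cohort_skipping_summary(same)
  expect_equal(s1$tukey$diff, 0)
  expect_equal(s1$tukey$p_adj, 1, tolerance = 1e-6)

  # strongly separated groups: significant at any conventional alpha,
  # mean difference 0.5, matching a hand ANOVA on the same numbers
  sep <- data.frame(
    sample = sprintf("s%d", 1:6),
    group = rep(c("n", "t"), each = 3),
    rate = c(0.00, 0.01, 0.02, 0.49, 0.50, 0.51),
    status = "ok"
  )
  s2 <- cohort_skipping_summary(sep)
  expect_equal(s2$groups$mean, c(0.01, 0.50))
  expect_equal(s2$tukey$diff, 0.49)
  expect_lt(s2$tukey$p_adj, 1e-6)
  expect_equal(s2$groups$sem, rep(stats::sd(c(0, .01, .02)) / sqrt(3), 2))

  # excluded samples are dropped; undersized groups are dropped with warning
  withex <- rbind(sep, data.frame(sample = "s7", group = "z", rate = NA,
                                  status = "excluded_no_reads"))
  expect_silent(s3 <- cohort_skipping_summary(withex))
  expect_equal(nrow(s3$groups), 2)
  small <- rbind(sep, data.frame(sample = "s8", group = "w", rate = 0.2,
                                 status = "ok"))
  expect_warning(cohort_skipping_summary(small), "dropping group")
})

test_that("group-rate recovery on a simulated two-group cohort", {
  cfg <- small_config(seed = 61)
  sim <- make_genome_and_annotation(cfg)
  g <- sim$genes[[1]]
  rows <- list()
  for (grp in c("normal", "tumor")) {
    rate <- if (grp == "normal") 0.05 else 0.30
    for (s in 1:10) {
      jr <- simulate_junction_reads(g, 4, rate, 500, cfg,
                                    genome = sim$genome,
                                    seed = 7000 + s +
                                      1000 * (grp == "tumor"))
      res <- skipping_rate(count_junction_reads(jr, g, 4))
      rows[[length(rows) + 1]] <- data.frame(
        sample = paste0(grp, s), group = grp, rate = res$rate,
        status = res$status)
    }
  }
  summ <- cohort_skipping_summary(do.call(rbind, rows))
  means <- stats::setNames(summ$groups$mean, summ$groups$group)
  expect_lt(abs(means[["normal"]] - 0.05), 0.05)
  expect_lt(abs(means[["tumor"]] - 0.30), 0.05)
  expect_lt(summ$tukey$p_adj, 0.001)
})
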