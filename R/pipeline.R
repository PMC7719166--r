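# End-to-end orchestration of the synthetic WT-vs-KO study: simulate ->
# methylation calling -> metagene profiles -> DMR calling/filtering ->
# exon-skipping cohort -> DMR-length/expression correlation, with every
# stage artifact written to disk and a truth-vs-estimate summary.

.pkg_version <- function() {
  as.character(utils::packageVersion("skipmeth"))
}

#' Run the full synthetic two-condition demo study
#'
#' Generates a genome/annotation with planted ground truth, simulates
#' bisulfite reads for both conditions, calls both methylomes, computes
#' global mCG and 50-bin metagene profiles, calls and filters DMRs,
#' simulates and quantifies an exon-skipping cohort, simulates expression
#' coupled to planted DMR length and computes the correlation, and writes
#' every stage artifact plus a JSON summary comparing estimates to truth.
#' Identical config and seed give identical outputs. Every output file
#' carries a header with the package version, a config hash and the seed.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if missing).
#' @param min_coverage Site-emission threshold for methylation calling.
#' @param dmr_params List of [call_dmrs()] parameters.
#' @param filter_params List of [filter_dmrs()] parameters (`min_length`,
#'   `direction`).
#' @param write_sams Also write the simulated reads as SAM files (default
#'   FALSE: read tables are passed in memory; SAMs are the largest
#'   artifacts).
#' @return Invisibly, a list with the summary (also written to
#'   `summary.json`) and the in-memory stage results.
#' @export
run_demo <- function(config = synthetic_config(), outdir = tempfile("demo_"),
                     min_coverage = 4L,
                     dmr_params = list(window_cpgs = 5L, min_delta = 0.2,
                                       alpha = 0.01, min_cpgs = 4L),
                     filter_params = list(min_length = 200L,
                                          direction = "hypo_in_b"),
                     write_sams = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  cfg_yaml <- file.path(outdir, "config.yaml")
  cfg_out <- unclass(config)
  cfg_out$skipping_spec$rates <- as.list(cfg_out$skipping_spec$rates)
  yaml::write_yaml(cfg_out, cfg_yaml)
  cfg_hash <- unname(tools::md5sum(cfg_yaml))
  hdr <- sprintf("skipmeth %s seed=%d config=%s", .pkg_version(),
                 config$seed, cfg_hash)

  sim <- stage("simulate", make_genome_and_annotation(config))
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(sim$genes, file.path(outdir, "genes.gtf"))
  write_truth_json(sim$truth, file.path(outdir, "truth.json"))

  reads_wt <- stage("simulate", simulate_bisulfite_reads(
    sim$genome, sim$truth, "wt", config))
  reads_ko <- stage("simulate", simulate_bisulfite_reads(
    sim$genome, sim$truth, "ko", config))
  if (write_sams) {
    write_sam(reads_wt, file.path(outdir, "reads_wt.sam"), sim$genome,
              comments = hdr)
    write_sam(reads_ko, file.path(outdir, "reads_ko.sam"), sim$genome,
              comments = hdr)
  }

  track_wt <- stage("methcall", call_methylation(
    reads_wt, sim$genome, min_coverage, sample = "wt"))
  track_ko <- stage("methcall", call_methylation(
    reads_ko, sim$genome, min_coverage, sample = "ko"))
  write_track(track_wt, file.path(outdir, "wt.bedgraph"), comments = hdr)
  write_track(track_ko, file.path(outdir, "ko.bedgraph"), comments = hdr)
  mcg_wt <- global_mcg_percent(track_wt)
  mcg_ko <- global_mcg_percent(track_ko)

  prof_wt <- stage("metagene", profile_elements(track_wt, sim$genes))
  prof_ko <- stage("metagene", profile_elements(track_ko, sim$genes))
  prof_wt$sample <- "wt"; prof_ko$sample <- "ko"
  write_profile(rbind(prof_wt, prof_ko), file.path(outdir, "profile.tsv"),
                comments = hdr)

  dmrs <- stage("dmr", do.call(call_dmrs, c(list(track_wt, track_ko),
                                            dmr_params)))
  filtered <- stage("dmr", do.call(filter_dmrs, c(list(dmrs), filter_params)))
  filtered <- annotate_dmrs(filtered, sim$genes)
  write_dmr_bed(filtered, file.path(outdir, "dmrs.bed"), comments = hdr)
  gb_frac <- if (nrow(filtered) > 0) {
    gene_body_cpg_fraction(filtered, sim$genes)
  } else NA_real_

  # exon-skipping cohort on the first gene's configured target exon
  sk <- config$skipping_spec
  gene1 <- sim$genes[[1]]
  rows <- list()
  sid <- 0L
  for (gname in names(sk$rates)) {
    for (s in seq_len(sk$n_samples)) {
      sid <- sid + 1L
      jr <- stage("skiprate", simulate_junction_reads(
        gene1, sk$target_exon, sk$rates[[gname]], sk$reads_per_sample,
        config, genome = sim$genome,
        seed = .substream(config$seed, 100L + sid)))
      cnt <- stage("skiprate", count_junction_reads(jr, gene1,
                                                    sk$target_exon))
      res <- skipping_rate(cnt)
      rows[[sid]] <- data.frame(
        sample = sprintf("%s_%02d", gname, s), group = gname,
        gene = gene1$gene_id, exon = sk$target_exon,
        Ri = res$Ri, Rs = res$Rs, n_excluded = cnt$n_excluded,
        rate = res$rate, ci_low = res$ci_low, ci_high = res$ci_high,
        status = res$status, stringsAsFactors = FALSE
      )
    }
  }
  rates <- do.call(rbind, rows)
  con <- file(file.path(outdir, "rates.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(rates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  cohort <- stage("skiprate", cohort_skipping_summary(rates))

  expr <- stage("integrate", simulate_expression(sim$truth, config))
  write_expression(expr, file.path(outdir, "expression.tsv"), comments = hdr)
  lens <- stage("integrate", dmr_length_per_gene(filtered, sim$genes))
  rec <- gene_dmr_expression(lens, expr)
  corr <- if (sum(rec$valid & rec$total_dmr_length > 0) >= 3 &&
              stats::sd(rec$total_dmr_length[rec$total_dmr_length > 0]) > 0) {
    stage("integrate", correlate_dmr_expression(rec))
  } else NULL
  con <- file(file.path(outdir, "corr.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  truth_mcg_wt <- 100 * mean(sim$truth$cpg$p_wt)
  truth_mcg_ko <- 100 * mean(sim$truth$cpg$p_ko)
  summary <- list(
    tool = hdr,
    seed = config$seed,
    global_mcg = list(
      wt = mcg_wt, ko = mcg_ko, gap = mcg_wt - mcg_ko,
      truth_wt = truth_mcg_wt, truth_ko = truth_mcg_ko,
      truth_gap = truth_mcg_wt - truth_mcg_ko
    ),
    dmrs = list(
      n_called = nrow(dmrs), n_filtered = nrow(filtered),
      n_planted = if (is.null(sim$truth$dmrs)) 0L else nrow(sim$truth$dmrs),
      gene_body_cpg_percent = gb_frac
    ),
    skipping = list(
      true_rates = as.list(sk$rates),
      group_means = stats::setNames(as.list(cohort$groups$mean),
                                    cohort$groups$group),
      anova_p = cohort$anova_p
    ),
    correlation = if (is.null(corr)) NULL else
      list(rho = corr$estimate, p_value = corr$p_value, n = corr$n)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(summary = summary, outdir = outdir,
                 genome = sim$genome, genes = sim$genes, truth = sim$truth,
                 track_wt = track_wt, track_ko = track_ko,
                 profiles = list(wt = prof_wt, ko = prof_ko),
                 dmrs = dmrs, filtered_dmrs = filtered, rates = rates,
                 cohort = cohort, expression = expr, records = rec,
                 correlation = corr))
}

#' Match called DMRs against planted truth intervals
#'
#' A planted interval is recovered when some called DMR overlaps it
#' reciprocally by at least `min_reciprocal` (the overlap covers that
#' fraction of both intervals). Recall is the recovered fraction of planted
#' intervals; precision the matched fraction of called DMRs.
#'
#' @param called DMR data.frame (`chrom`, `start`, `end`).
#' @param planted data.frame of truth intervals (`chrom`, `start`, `end`).
#' @param min_reciprocal Reciprocal-overlap threshold (default 0.5).
#' @return List: `recall`, `precision`, `n_called`, `n_planted`.
#' @export
match_planted_dmrs <- function(called, planted, min_reciprocal = 0.5) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(called) == 0) NA_real_ else 0,
                n_called = nrow(called), n_planted = 0L))
  }
  if (nrow(called) == 0) {
    return(list(recall = 0, precision = NA_real_, n_called = 0L,
                n_planted = nrow(planted)))
  }
  cgr <- GenomicRanges::GRanges(called$chrom,
                                IRanges::IRanges(called$start, called$end))
  pgr <- GenomicRanges::GRanges(planted$chrom,
                                IRanges::IRanges(planted$start, planted$end))
  ov <- GenomicRanges::findOverlaps(cgr, pgr, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(list(recall = 0, precision = 0, n_called = nrow(called),
                n_planted = nrow(planted)))
  }
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(cgr)[qi], IRanges::ranges(pgr)[si]))
  good <- inter >= min_reciprocal * IRanges::width(cgr)[qi] &
    inter >= min_reciprocal * IRanges::width(pgr)[si]
  list(
    recall = length(unique(si[good])) / nrow(planted),
    precision = length(unique(qi[good])) / nrow(called),
    n_called = nrow(called), n_planted = nrow(planted)
  )
}
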