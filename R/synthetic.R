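# Synthetic WT-vs-KO study generator.
#
# Emulates the design of a hepatocyte methylome knockout experiment: a small
# multi-gene genome with CpG-enriched gene bodies, a wild-type methylome with
# high CG methylation, a knockout methylome with globally reduced methylation
# plus planted contiguous hypomethylated regions on gene bodies, pre-aligned
# bisulfite reads with a configurable conversion efficiency, RNA-seq junction
# reads with a configurable per-exon skipping rate, and per-gene expression
# with a configurable coupling between planted DMR length and fold change.
# Every generator is bit-deterministic under a fixed seed.

.substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 32003 + k)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic WT-vs-KO study
#'
#' Defaults define the emulated study conditions: genome-wide mean mCG near
#' 77% in the wild type and near 66% in the knockout (background 68.4% plus
#' planted hypomethylated regions of effect -0.4 on gene bodies), 30x
#' bisulfite coverage at conversion efficiency 0.995, exon-skipping groups at
#' true rates 5% and 30%, and a positive coupling of 0.001 log2-fold-change
#' units per bp of planted gene-body DMR length.
#'
#' @param genome_length Total genome size in bp (>= 10 kb per gene).
#' @param n_genes Number of genes.
#' @param seed Integer root seed; all stage streams derive from it.
#' @param wt_mcg Mean WT methylation probability per CpG.
#' @param ko_background_mcg KO methylation probability outside planted DMRs.
#' @param dmr_spec List with `n`, `length_range` (bp), `delta` (methylation
#'   difference KO - WT inside the region), `target` (only `"gene_body"`).
#' @param bisulfite_coverage Mean read depth of simulated bisulfite reads.
#' @param conversion_efficiency Probability that an unmethylated C reads as T.
#' @param read_length Read length in bp.
#' @param bisulfite_both_strands Emit reads from both strands (default plus
#'   only; the caller folds strands either way).
#' @param skipping_spec List with `rates` (named per-group true skipping
#'   rates), `n_samples` per group, `reads_per_sample`, `target_exon`
#'   (internal exon index), `decoy_fraction` (extra intron-spanning reads).
#' @param fc_coupling Slope linking planted gene-body DMR length (bp) to the
#'   expression log2 fold change.
#' @param noise_sd SD of Gaussian noise added to the log2 fold change.
#' @param expression_baseline Median baseline expression value.
#' @param n_exons Exons per gene (>= 4 so internal skipping targets exist).
#' @param exon_length_range,intron_length_range Uniform sampling ranges (bp)
#'   for exon and intron widths.
#' @param utr5_length,utr3_length UTR widths (bp) measured inward from the
#'   gene ends; 0 omits the UTR annotation entirely.
#' @param genic_cpg_boost Rate (per bp) of extra CG dinucleotides planted in
#'   gene bodies and promoters on top of the random-sequence background,
#'   emulating the CpG enrichment of islands and transcribed regions
#'   (default 1/16, i.e. roughly doubling genic CpG density).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 400000L,
                             n_genes = 20L,
                             seed = 1L,
                             wt_mcg = 0.769,
                             ko_background_mcg = 0.684,
                             dmr_spec = list(n = 20L,
                                             length_range = c(300L, 1000L),
                                             delta = -0.4,
                                             target = "gene_body"),
                             bisulfite_coverage = 30,
                             conversion_efficiency = 0.995,
                             read_length = 100L,
                             bisulfite_both_strands = FALSE,
                             skipping_spec = list(
                               rates = c(normal = 0.05, tumor = 0.30),
                               n_samples = 10L,
                               reads_per_sample = 500L,
                               target_exon = 4L,
                               decoy_fraction = 0.05),
                             fc_coupling = 0.001,
                             noise_sd = 0.5,
                             expression_baseline = 100,
                             n_exons = 8L,
                             exon_length_range = c(120L, 280L),
                             intron_length_range = c(400L, 1000L),
                             utr5_length = 80L,
                             utr3_length = 150L,
                             genic_cpg_boost = 1 / 16) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    seed = as.integer(seed), wt_mcg = wt_mcg,
    ko_background_mcg = ko_background_mcg, dmr_spec = dmr_spec,
    bisulfite_coverage = bisulfite_coverage,
    conversion_efficiency = conversion_efficiency,
    read_length = as.integer(read_length),
    bisulfite_both_strands = isTRUE(bisulfite_both_strands),
    skipping_spec = local({
      s <- skipping_spec
      s$rates <- unlist(s$rates)  # tolerate YAML-style named lists
      s
    }),
    fc_coupling = fc_coupling,
    noise_sd = noise_sd, expression_baseline = expression_baseline,
    n_exons = as.integer(n_exons),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    genic_cpg_boost = genic_cpg_boost
  )
  probs <- c(cfg$wt_mcg, cfg$ko_background_mcg, cfg$conversion_efficiency,
             cfg$skipping_spec$rates, cfg$skipping_spec$decoy_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$genome_length <= 0 || cfg$n_genes <= 0 || cfg$read_length <= 0 ||
      cfg$bisulfite_coverage <= 0) {
    stop("lengths and depths must be positive")
  }
  if (cfg$n_exons < 4) stop("genes need >= 4 exons for skipping targets")
  if (!is.null(cfg$dmr_spec) && cfg$dmr_spec$n > 0 &&
      abs(cfg$wt_mcg + cfg$dmr_spec$delta -
          min(max(cfg$wt_mcg + cfg$dmr_spec$delta, 0), 1)) > 1e-12) {
    stop("wt_mcg + dmr delta must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a toy genome, annotation and methylome ground truth
#'
#' Lays out `n_genes` multi-exon genes (alternating strands) on one
#' chromosome, samples a random sequence whose CG dinucleotides are retained
#' inside gene bodies and promoters but thinned ~7-fold in intergenic space
#' (so regional methylation signal concentrates on genes), plants
#' contiguous hypomethylated regions on gene bodies per `dmr_spec`, and
#' records per-CpG true methylation probabilities for both conditions.
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (a `reference_genome`), `genes` (named list of
#'   `gene_model`s) and `truth` (class `synthetic_truth`: per-CpG
#'   probabilities, planted DMR table, per-gene planted gene-body DMR length,
#'   and the config).
#' @export
make_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$genome_length
  ng <- config$n_genes
  slot <- L %/% ng
  if (slot < 10000L) stop("genome_length must provide >= 10 kb per gene")
  chrom <- "chrS"

  .with_seed(.substream(config$seed, 1L), {
    genes <- list()
    genic <- logical(L)
    for (i in seq_len(ng)) {
      strand <- if (i %% 2 == 1) "+" else "-"
      ne <- config$n_exons
      exon_w <- round(stats::runif(ne, config$exon_length_range[1],
                                   config$exon_length_range[2]))
      intron_w <- round(stats::runif(ne - 1, config$intron_length_range[1],
                                     config$intron_length_range[2]))
      body <- sum(exon_w) + sum(intron_w)
      slot_start <- (i - 1L) * slot + 1L
      if (body + 6000L > slot) stop("gene body does not fit in its slot")
      gstart <- slot_start + 3000L
      starts <- integer(ne); ends <- integer(ne)
      p <- gstart
      for (k in seq_len(ne)) {
        starts[k] <- p
        ends[k] <- p + exon_w[k] - 1L
        p <- ends[k] + 1L + if (k < ne) intron_w[k] else 0L
      }
      # fixed-width UTRs measured inward from the gene ends
      u5 <- config$utr5_length; u3 <- config$utr3_length
      if (strand == "+") {
        cs <- starts[1] + u5; ce <- ends[ne] - u3
      } else {
        cs <- starts[1] + u3; ce <- ends[ne] - u5
      }
      g <- gene_model(sprintf("g%03d", i), chrom, strand, starts, ends,
                      cds_start = cs, cds_end = ce, chrom_length = L)
      genes[[g$gene_id]] <- g
      genic[starts[1]:ends[ne]] <- TRUE
      if (length(g$promoter) > 0) {
        genic[IRanges::start(g$promoter):IRanges::end(g$promoter)] <- TRUE
      }
    }

    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    cg <- which(chars[-L] == "C" & chars[-1] == "G")
    drop <- cg[!genic[cg] & stats::runif(length(cg)) > 0.15]
    if (length(drop) > 0) {
      chars[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
    }
    # island-like enrichment: plant extra CGs in genic (body + promoter)
    # space on top of the random-sequence background
    if (config$genic_cpg_boost > 0) {
      gpos <- which(genic[seq_len(L - 1L)])
      extra <- gpos[stats::runif(length(gpos)) < config$genic_cpg_boost]
      # avoid back-to-back writes that would partly overwrite each other
      if (length(extra) > 1) extra <- extra[c(TRUE, diff(extra) > 1)]
      chars[extra] <- "C"
      chars[extra + 1L] <- "G"
    }
    genome <- reference_genome(stats::setNames(
      Biostrings::DNAStringSet(paste(chars, collapse = "")), chrom))

    # plant hypomethylated regions on gene bodies
    spec <- config$dmr_spec
    dmrs <- NULL
    if (!is.null(spec) && spec$n > 0) {
      if (!identical(spec$target, "gene_body")) {
        stop("only gene_body DMR targets are supported")
      }
      body_w <- vapply(genes, function(g) g$cds_end - g$cds_start + 1L, 1L)
      if (max(body_w) < min(spec$length_range)) {
        stop("dmr_spec infeasible: requested DMR longer than any gene body")
      }
      placed <- list()
      rows <- vector("list", spec$n)
      for (d in seq_len(spec$n)) {
        ok <- FALSE
        for (try in 1:200) {
          gi <- sample(ng, 1L)
          g <- genes[[gi]]
          # plant inside the CDS-to-CDS interval so every planted base is
          # exonic or intronic (gene body), never UTR
          lo <- g$cds_start; hi <- g$cds_end
          w <- hi - lo + 1L
          len <- round(stats::runif(1, spec$length_range[1],
                                    min(spec$length_range[2], w)))
          s <- lo + sample.int(w - len + 1L, 1L) - 1L
          cand <- IRanges::IRanges(s, s + len - 1L)
          prev <- placed[[g$gene_id]]
          if (!is.null(prev) &&
              length(IRanges::findOverlaps(cand, prev)) > 0) next
          if (sum(genome$cpg[[chrom]] >= s &
                  genome$cpg[[chrom]] <= s + len - 1L) < 3) next
          placed[[g$gene_id]] <- c(prev %||% IRanges::IRanges(), cand)
          rows[[d]] <- data.frame(chrom = chrom, start = s,
                                  end = s + len - 1L, length = len,
                                  gene_id = g$gene_id, delta = spec$delta)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place planted DMR ", d,
                      "; dmr_spec too dense for this genome")
      }
      dmrs <- do.call(rbind, rows)
    }

    cpg_pos <- genome$cpg[[chrom]]
    p_wt <- rep(config$wt_mcg, length(cpg_pos))
    p_ko <- rep(config$ko_background_mcg, length(cpg_pos))
    if (!is.null(dmrs)) {
      inside <- rep(FALSE, length(cpg_pos))
      for (d in seq_len(nrow(dmrs))) {
        inside <- inside | (cpg_pos >= dmrs$start[d] & cpg_pos <= dmrs$end[d])
      }
      p_ko[inside] <- min(max(config$wt_mcg + spec$delta, 0), 1)
    }

    gene_dmr_length <- stats::setNames(numeric(ng), names(genes))
    if (!is.null(dmrs)) {
      agg <- tapply(dmrs$length, dmrs$gene_id, sum)
      gene_dmr_length[names(agg)] <- agg
    }

    truth <- structure(
      list(
        cpg = data.frame(chrom = chrom, pos = cpg_pos,
                         p_wt = p_wt, p_ko = p_ko),
        dmrs = dmrs,
        gene_dmr_length = gene_dmr_length,
        config = config
      ),
      class = "synthetic_truth"
    )
    list(genome = genome, genes = genes, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate aligned bisulfite reads
#'
#' Reads are emitted pre-aligned (ungapped, uniform start positions). At each
#' CpG cytosine a covering read shows C with probability
#' `m + (1 - m) * (1 - conversion_efficiency)` (methylated, or unconverted by
#' chance) and T otherwise; cytosines outside CpG context convert with
#' probability `conversion_efficiency`. With `bisulfite_both_strands`, half
#' the reads come from the minus strand, where the informative base is the G
#' of the CpG (G retained when methylated, A when converted); SAM sequences
#' are stored in plus-strand orientation either way.
#'
#' @param genome A `reference_genome` (single chromosome, as generated).
#' @param truth A `synthetic_truth` covering every CpG of the genome.
#' @param condition `"wt"` or `"ko"`: which planted methylome to sample.
#' @param config A [synthetic_config()].
#' @param seed Optional integer; defaults to a stream derived from
#'   `config$seed` and the condition.
#' @return Read table (data.frame: `qname`, `flag`, `chrom`, `pos`, `cigar`,
#'   `seq`) suitable for [write_sam()] or directly for [call_methylation()].
#' @export
simulate_bisulfite_reads <- function(genome, truth, condition = c("wt", "ko"),
                                     config, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(genome, "reference_genome"),
            inherits(truth, "synthetic_truth"))
  if (config$bisulfite_coverage <= 0) stop("coverage must be positive")
  if (is.null(seed)) {
    seed <- .substream(config$seed, if (condition == "wt") 2L else 3L)
  }
  chrom <- names(genome$sequences)[1]
  if (length(genome$sequences) != 1) {
    stop("the bisulfite simulator expects a single-chromosome genome")
  }
  tcpg <- truth$cpg[truth$cpg$chrom == chrom, ]
  if (!all(genome$cpg[[chrom]] %in% tcpg$pos)) {
    stop("truth does not cover every CpG of the genome")
  }
  rl <- config$read_length
  L <- chrom_lengths(genome)[[chrom]]
  ce <- config$conversion_efficiency
  m <- if (condition == "wt") tcpg$p_wt else tcpg$p_ko

  s_chars <- strsplit(as.character(genome$sequences[[chrom]]), "")[[1]]
  # retention probability for every informative base on each strand
  c_all <- which(s_chars == "C")
  p_ret_c <- rep(1 - ce, length(c_all))
  is_cpg_c <- match(c_all, tcpg$pos)
  p_ret_c[!is.na(is_cpg_c)] <-
    m[is_cpg_c[!is.na(is_cpg_c)]] * ce + (1 - ce)
  # p(C shown) = m + (1-m)(1-ce) = m*ce + (1-ce)
  g_all <- which(s_chars == "G")
  p_ret_g <- rep(1 - ce, length(g_all))
  is_cpg_g <- match(g_all - 1L, tcpg$pos)
  p_ret_g[!is.na(is_cpg_g)] <-
    m[is_cpg_g[!is.na(is_cpg_g)]] * ce + (1 - ce)

  n_reads <- round(L * config$bisulfite_coverage / rl)
  .with_seed(seed, {
    starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
    flags <- if (config$bisulfite_both_strands) {
      sample(c(0L, 16L), n_reads, replace = TRUE)
    } else rep(0L, n_reads)

    seqs <- character(n_reads)
    chunk <- 50000L
    c_ir <- IRanges::IRanges(c_all, c_all)
    g_ir <- IRanges::IRanges(g_all, g_all)
    for (lo in seq(1L, n_reads, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_reads)
      st <- starts[lo:hi]
      fl <- flags[lo:hi]
      n <- length(st)
      base <- s_chars[rep(st, each = rl) + 0:(rl - 1L)]
      r_ir <- IRanges::IRanges(st, st + rl - 1L)

      convert_at <- function(site_ir, p_ret, rows, to) {
        if (!any(rows)) return()
        ov <- IRanges::findOverlaps(r_ir[rows], site_ir)
        if (length(ov) == 0) return()
        q <- which(rows)[S4Vectors::queryHits(ov)]
        sidx <- S4Vectors::subjectHits(ov)
        off <- (q - 1L) * rl + (IRanges::start(site_ir)[sidx] - st[q] + 1L)
        conv <- stats::runif(length(off)) > p_ret[sidx]
        base[off[conv]] <<- to
      }
      convert_at(c_ir, p_ret_c, fl == 0L, "T")
      convert_at(g_ir, p_ret_g, fl == 16L, "A")

      mchar <- matrix(base, nrow = rl)
      seqs[lo:hi] <- do.call(paste0,
                             lapply(seq_len(rl), function(r) mchar[r, ]))
    }

    data.frame(
      qname = sprintf("bs_%s_%07d", condition, seq_len(n_reads)),
      flag = flags, chrom = chrom, pos = starts,
      cigar = paste0(rl, "M"), seq = seqs,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate split-aligned RNA-seq reads around a target exon
#'
#' Each read is, with probability `true_skip_rate`, a junction read joining
#' the exons flanking the target (the skipping form); otherwise it supports
#' inclusion (fully contained in the target exon when the exon is long
#' enough, or spanning an annotated junction between the target and an
#' adjacent exon). A configurable fraction of decoy reads straddling an
#' exon/intron boundary is added on top; the classifier must exclude them.
#' Read names carry their generating class (`skip_`/`incl_`/`decoy_`) so
#' recovery can be checked against truth labels.
#'
#' @param gene A `gene_model` with >= 3 exons.
#' @param target_exon_index Genomic index of the target exon; must be
#'   internal (not first or last).
#' @param true_skip_rate Probability a non-decoy read is the skipping form.
#' @param n_reads Number of non-decoy reads.
#' @param config A [synthetic_config()] (read length, decoy fraction, seed).
#' @param genome Optional `reference_genome` used to fill read sequences;
#'   without it sequences are written as `*`.
#' @param seed Optional integer seed override.
#' @return Read table as for [simulate_bisulfite_reads()], with attribute
#'   `truth_labels` (data.frame `qname`, `label`).
#' @export
simulate_junction_reads <- function(gene, target_exon_index, true_skip_rate,
                                    n_reads, config = synthetic_config(),
                                    genome = NULL, seed = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  k <- target_exon_index
  ne <- length(gene$exons)
  if (k <= 1 || k >= ne) {
    stop("target exon must be internal (flanked on both sides)")
  }
  if (true_skip_rate < 0 || true_skip_rate > 1) stop("rate must be in [0,1]")
  if (is.null(seed)) seed <- .substream(config$seed, 7L + k)
  rl <- config$read_length
  es <- IRanges::start(gene$exons); ee <- IRanges::end(gene$exons)
  ew <- IRanges::width(gene$exons)
  decoy_n <- round((config$skipping_spec$decoy_fraction %||% 0.05) * n_reads)

  .with_seed(seed, {
    is_skip <- stats::runif(n_reads) < true_skip_rate
    rows <- vector("list", n_reads + decoy_n)
    mk <- function(qname, pos, blocks) {
      # blocks: integer matrix 2 x nb of (start, end) on the reference
      widths <- blocks[2, ] - blocks[1, ] + 1L
      gaps <- if (ncol(blocks) > 1) {
        blocks[1, -1] - blocks[2, -ncol(blocks)] - 1L
      } else integer(0)
      cig <- paste0(widths[1], "M")
      if (length(gaps) > 0) {
        cig <- paste0(cig, paste0(gaps, "N", widths[-1], "M", collapse = ""))
      }
      sq <- if (is.null(genome)) "*" else {
        paste(vapply(seq_len(ncol(blocks)), function(b) {
          as.character(Biostrings::subseq(genome$sequences[[gene$chrom]],
                                          blocks[1, b], blocks[2, b]))
        }, ""), collapse = "")
      }
      data.frame(qname = qname, flag = 0L, chrom = gene$chrom, pos = pos,
                 cigar = cig, seq = sq, stringsAsFactors = FALSE)
    }
    split_read <- function(donor, acceptor, qname) {
      # junction read: left block ends at the donor exon's 3' end, right
      # block starts at the acceptor exon's 5' start
      left <- sample(8:(rl - 8L), 1L)
      left <- min(left, ew[donor])
      right <- min(rl - left, ew[acceptor])
      left <- rl - right  # re-balance if the acceptor clamped
      left <- min(left, ew[donor])
      a_end <- ee[donor]; b_start <- es[acceptor]
      mk(qname, a_end - left + 1L,
         matrix(c(a_end - left + 1L, a_end,
                  b_start, b_start + right - 1L), nrow = 2))
    }
    for (i in seq_len(n_reads)) {
      if (is_skip[i]) {
        rows[[i]] <- split_read(k - 1L, k + 1L, sprintf("skip_%05d", i))
      } else {
        # inclusion: contained read when the target exon is long enough,
        # otherwise a junction read with an adjacent exon
        choices <- c(if (ew[k] >= rl) "contained",
                     "junc_up", "junc_down")
        ch <- sample(choices, 1L)
        rows[[i]] <- switch(ch,
          contained = {
            s <- es[k] + sample.int(ew[k] - rl + 1L, 1L) - 1L
            mk(sprintf("incl_%05d", i), s,
               matrix(c(s, s + rl - 1L), nrow = 2))
          },
          junc_up = split_read(k - 1L, k, sprintf("incl_%05d", i)),
          junc_down = split_read(k, k + 1L, sprintf("incl_%05d", i))
        )
      }
    }
    for (j in seq_len(decoy_n)) {
      # unsplit read straddling a target-exon boundary into the intron
      boundary <- if (stats::runif(1) < 0.5) es[k] else ee[k]
      s <- boundary - rl %/% 2L
      rows[[n_reads + j]] <- mk(sprintf("decoy_%05d", j), s,
                                matrix(c(s, s + rl - 1L), nrow = 2))
    }
    out <- do.call(rbind, rows)
    attr(out, "truth_labels") <- data.frame(
      qname = out$qname,
      label = sub("_.*$", "", out$qname),
      stringsAsFactors = FALSE
    )
    out
  })
}

#' Simulate a two-condition expression table with DMR-length coupling
#'
#' The planted log2 fold change of each gene is
#' `fc_coupling * planted_gene_body_DMR_length + N(0, noise_sd)`; baseline
#' expression is log-normal around `expression_baseline` and the condition-B
#' value is the baseline scaled by the fold change.
#'
#' @param dmr_lengths Named numeric vector of planted gene-body DMR lengths
#'   (bp) per gene, or a `synthetic_truth` (its `gene_dmr_length` is used).
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed override.
#' @return data.frame `gene_id`, `value_wt`, `value_ko` with attribute
#'   `truth` (data.frame `gene_id`, `dmr_length`, `true_log2_fc`).
#' @export
simulate_expression <- function(dmr_lengths, config = synthetic_config(),
                                seed = NULL) {
  if (inherits(dmr_lengths, "synthetic_truth")) {
    dmr_lengths <- dmr_lengths$gene_dmr_length
  }
  if (is.null(names(dmr_lengths))) {
    names(dmr_lengths) <- sprintf("g%03d", seq_along(dmr_lengths))
  }
  if (is.null(seed)) seed <- .substream(config$seed, 5L)
  n <- length(dmr_lengths)
  .with_seed(seed, {
    lfc <- config$fc_coupling * dmr_lengths +
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    base <- config$expression_baseline *
      exp(stats::rnorm(n, 0, 0.4))
    out <- data.frame(
      gene_id = names(dmr_lengths),
      value_wt = base,
      value_ko = base * 2^lfc,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- data.frame(
      gene_id = names(dmr_lengths),
      dmr_length = as.numeric(dmr_lengths),
      true_log2_fc = as.numeric(lfc),
      stringsAsFactors = FALSE
    )
    out
  })
}

#' Write ground truth to JSON
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    cpg = truth$cpg,
    dmrs = truth$dmrs,
    gene_dmr_length = as.list(truth$gene_dmr_length),
    config = unclass(truth$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
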