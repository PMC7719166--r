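#' Classify RNA-seq reads around a target exon
#'
#' Partitions every read overlapping the neighbourhood of a target exon
#' (from the start of the nearest upstream exon to the end of the nearest
#' downstream exon) into exactly one of four labels:
#'
#' * `skipping` - the read has a splice junction whose donor is the 3' end
#'   of an exon upstream of the target and whose acceptor is the 5' start of
#'   an exon downstream of it (the target is absent between matched exonic
#'   blocks);
#' * `inclusion` - all aligned blocks lie within annotated exons and either
#'   a block overlaps the target exon with every junction matching an
#'   annotated adjacent-exon boundary, or the read is fully contained in the
#'   target exon;
#' * `excluded` - any aligned block overlaps intronic (non-exonic) sequence:
#'   intron-retaining or boundary-spanning reads, which prove neither form;
#' * `uninformative` - none of the above (e.g. a read confined to a flanking
#'   exon, or an unannotated junction).
#'
#' @param aln A [GenomicAlignments::GAlignments] or a simulator read table.
#' @param gene A `gene_model`.
#' @param target_exon_index Genomic index of the target exon (internal).
#' @param neighbourhood_only Restrict to reads overlapping the target's
#'   neighbourhood before classifying (default TRUE).
#' @return data.frame `qname`, `label` for every inspected read.
#' @export
classify_reads <- function(aln, gene, target_exon_index,
                           neighbourhood_only = TRUE) {
  stopifnot(inherits(gene, "gene_model"))
  k <- target_exon_index
  ne <- length(gene$exons)
  if (k <= 1 || k >= ne) stop("target exon must be internal")
  es <- IRanges::start(gene$exons); ee <- IRanges::end(gene$exons)

  if (is.data.frame(aln)) {
    blocks <- .blocks_from_table(aln)
    qname <- aln$qname
    chroms <- aln$chrom
  } else {
    stopifnot(methods::is(aln, "GAlignments"))
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(aln), pos = BiocGenerics::start(aln),
      ops = "M", reduce.ranges = TRUE
    )
    qname <- names(aln)
    if (is.null(qname)) qname <- sprintf("read_%d", seq_along(aln))
    chroms <- as.character(GenomicAlignments::seqnames(aln))
  }
  if (any(chroms != gene$chrom)) {
    stop("reads aligned to a different chromosome than gene ", gene$gene_id)
  }

  nb_start <- es[k - 1]; nb_end <- ee[k + 1]
  span <- unlist(range(blocks))
  keep <- IRanges::start(span) <= nb_end & IRanges::end(span) >= nb_start
  if (neighbourhood_only) {
    blocks <- blocks[keep]
    qname <- qname[keep]
  }

  exons <- gene$exons
  labels <- character(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    bs <- IRanges::start(b); be <- IRanges::end(b)
    # exonic-membership of each block: fully inside one annotated exon?
    block_exon <- vapply(seq_along(b), function(j) {
      hit <- which(es <= bs[j] & ee >= be[j])
      if (length(hit) == 1) hit else NA_integer_
    }, 1L)
    if (anyNA(block_exon)) {
      # some block touches non-exonic sequence -> intron-overlapping read
      labels[i] <- "excluded"
      next
    }
    nb <- length(b)
    if (nb == 1) {
      labels[i] <- if (block_exon[1] == k) "inclusion" else "uninformative"
      next
    }
    # junctions between consecutive blocks; require exact annotated bounds
    don <- block_exon[-nb]; acc <- block_exon[-1]
    at_bounds <- be[-nb] == ee[don] & bs[-1] == es[acc]
    if (!all(at_bounds)) {
      labels[i] <- "uninformative"  # unannotated junction
      next
    }
    if (any(don < k & acc > k)) {
      labels[i] <- "skipping"
    } else if (any(block_exon == k) && all(acc == don + 1L)) {
      labels[i] <- "inclusion"
    } else {
      labels[i] <- "uninformative"
    }
  }
  data.frame(qname = qname, label = labels, stringsAsFactors = FALSE)
}

.blocks_from_table <- function(reads) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = "M", reduce.ranges = TRUE
  )
}

#' Tally inclusion/skipping evidence around a target exon
#'
#' @inheritParams classify_reads
#' @param inclusion_mode `"any"` counts reads fully contained in the target
#'   exon as inclusion evidence (the default); `"junction_only"` restricts
#'   Ri to junction-bearing inclusion reads.
#' @return List of class `junction_counts`: `gene_id`, `target_exon_index`,
#'   `Ri`, `Rs`, `n_excluded`, `n_uninformative`, `n_inspected`, and
#'   `labels` (the per-read classification table).
#' @export
count_junction_reads <- function(aln, gene, target_exon_index,
                                 inclusion_mode = c("any", "junction_only")) {
  inclusion_mode <- match.arg(inclusion_mode)
  cl <- classify_reads(aln, gene, target_exon_index)
  if (inclusion_mode == "junction_only" && nrow(cl) > 0) {
    blocks <- if (is.data.frame(aln)) .blocks_from_table(aln) else {
      GenomicAlignments::cigarRangesAlongReferenceSpace(
        GenomicAlignments::cigar(aln), pos = BiocGenerics::start(aln),
        ops = "M", reduce.ranges = TRUE)
    }
    nb <- lengths(blocks)
    nm <- if (is.data.frame(aln)) aln$qname else names(aln)
    unsplit_incl <- cl$label == "inclusion" &
      nb[match(cl$qname, nm)] == 1L
    cl$label[unsplit_incl] <- "uninformative"
  }
  counts <- structure(list(
    gene_id = gene$gene_id,
    target_exon_index = target_exon_index,
    Ri = sum(cl$label == "inclusion"),
    Rs = sum(cl$label == "skipping"),
    n_excluded = sum(cl$label == "excluded"),
    n_uninformative = sum(cl$label == "uninformative"),
    n_inspected = nrow(cl),
    labels = cl
  ), class = "junction_counts")
  counts
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf(
    "junction_counts %s exon %d: Ri=%d Rs=%d excluded=%d uninformative=%d\n",
    x$gene_id, x$target_exon_index, x$Ri, x$Rs, x$n_excluded,
    x$n_uninformative))
  invisible(x)
}

#' Exon-skipping rate from inclusion/skipping counts
#'
#' The rate is `Rs / (Ri + Rs)`. Samples without any informative read around
#' the exon (`Ri + Rs = 0`) are flagged `excluded_no_reads` with a missing
#' rate and are dropped from cohort summaries. A Wilson score interval is
#' attached for the binomial proportion (reported, never used for
#' exclusion).
#'
#' @param counts A `junction_counts`, or the `Ri` count directly.
#' @param Rs Skipping count when `counts` is given as a number.
#' @param conf_level Confidence level for the Wilson interval.
#' @return List of class `exon_skipping_result`: `rate`, `ci_low`,
#'   `ci_high`, `status` (`"ok"` or `"excluded_no_reads"`), `Ri`, `Rs`.
#' @export
skipping_rate <- function(counts, Rs = NULL, conf_level = 0.95) {
  if (inherits(counts, "junction_counts")) {
    Ri <- counts$Ri; Rs <- counts$Rs
  } else {
    Ri <- counts
    if (is.null(Rs)) stop("supply Rs when passing counts as numbers")
  }
  if (Ri < 0 || Rs < 0) stop("counts must be non-negative")
  n <- Ri + Rs
  if (n == 0) {
    return(structure(list(rate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, status = "excluded_no_reads",
                          Ri = Ri, Rs = Rs),
                     class = "exon_skipping_result"))
  }
  rate <- Rs / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (rate + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(rate * (1 - rate) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  structure(list(rate = rate, ci_low = max(0, centre - half),
                 ci_high = min(1, centre + half), status = "ok",
                 Ri = Ri, Rs = Rs),
            class = "exon_skipping_result")
}

#' @export
print.exon_skipping_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("exon skipping rate %.4f (Rs=%d, Ri=%d; 95%% CI %.3f-%.3f)\n",
                x$rate, x$Rs, x$Ri, x$ci_low, x$ci_high))
  } else {
    cat("sample excluded: no reads around the exon\n")
  }
  invisible(x)
}

#' Cohort summary of per-sample skipping rates
#'
#' Summarises per-sample rates by group (mean and s.e.m. over samples with
#' status `ok`), then compares groups by one-way ANOVA followed by Tukey's
#' HSD multiple-comparison test. Excluded samples are omitted; groups left
#' with fewer than 2 usable samples are dropped with a warning.
#'
#' @param samples data.frame with columns `sample`, `group`, `rate`,
#'   `status`.
#' @return List: `groups` (group, n, mean, sem), `anova_p`, `tukey`
#'   (comparison, diff, lwr, upr, p_adj).
#' @export
cohort_skipping_summary <- function(samples) {
  need <- c("sample", "group", "rate", "status")
  stopifnot(all(need %in% names(samples)))
  ok <- samples[samples$status == "ok" & !is.na(samples$rate), ]
  cnt <- table(ok$group)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 usable samples: ",
            paste(small, collapse = ", "))
    ok <- ok[!ok$group %in% small, ]
  }
  if (length(unique(ok$group)) < 2) {
    stop("need at least 2 groups with >= 2 usable samples each")
  }
  ok$group <- factor(ok$group)
  groups <- do.call(rbind, lapply(split(ok$rate, ok$group), function(r) {
    data.frame(n = length(r), mean = mean(r),
               sem = stats::sd(r) / sqrt(length(r)))
  }))
  groups <- data.frame(group = rownames(groups), groups,
                       row.names = NULL, stringsAsFactors = FALSE)
  fit <- stats::aov(rate ~ group, data = ok)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  th <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                      lwr = th[, "lwr"], upr = th[, "upr"],
                      p_adj = th[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(groups = groups, anova_p = anova_p, tukey = tukey)
}
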