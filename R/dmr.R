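#' Two-sided Fisher exact test for 2x2 methylation count tables
#'
#' Vectorised exact test of methylated/unmethylated counts between two
#' conditions, computed from the hypergeometric density (two-sided p is the
#' total probability of tables no more likely than the observed one, the
#' same definition as [stats::fisher.test()]).
#'
#' @param meth_a,total_a Methylated and total calls in condition A.
#' @param meth_b,total_b Methylated and total calls in condition B.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_p_2x2 <- function(meth_a, total_a, meth_b, total_b) {
  stopifnot(length(meth_a) == length(total_a),
            length(meth_b) == length(total_b),
            length(meth_a) == length(meth_b))
  n <- length(meth_a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- meth_a[i] + meth_b[i]                 # methylated margin
    nn <- (total_a[i] - meth_a[i]) + (total_b[i] - meth_b[i])
    k <- total_a[i]                            # condition-A margin
    lo <- max(0L, k - nn); hi <- min(k, m)
    d <- stats::dhyper(lo:hi, m, nn, k)
    p[i] <- min(1, sum(d[d <= d[meth_a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Call differentially methylated regions between two methylome tracks
#'
#' Slides a window of `window_cpgs` consecutive co-covered CpGs (step 1)
#' along each chromosome, tests the pooled methylated/unmethylated counts of
#' the two conditions by Fisher's exact test, and marks windows with
#' `p < alpha` and pooled level difference `|delta| >= min_delta`. Marked
#' windows of the same sign are merged into one DMR when they share a CpG or
#' are separated by less than `merge_gap` bp with no opposite-sign marked
#' window between them. The DMR interval runs from its first to its last
#' member CpG (length = last - first + 1); region p is the minimum member
#' window p and q-values are Benjamini-Hochberg adjusted over all tested
#' windows. DMRs with fewer than `min_cpgs` member CpGs are dropped.
#'
#' The single-replicate design (one methylome per condition) is handled by
#' pooling calls per condition; no dispersion model is fitted.
#'
#' @param track_a,track_b `methylome_track`s called on the same genome; only
#'   CpGs covered in both are used.
#' @param window_cpgs Window size in co-covered CpGs (default 5).
#' @param min_delta Minimum absolute pooled level difference (default 0.2).
#' @param alpha Window-level significance threshold (default 0.01).
#' @param min_cpgs Minimum member CpGs per emitted DMR (default 4).
#' @param merge_gap Maximum bp between marked windows that still merge
#'   (default 100).
#' @return data.frame of DMRs (`chrom`, `start`, `end`, `length`, `n_cpgs`,
#'   `level_a`, `level_b`, `delta`, `p_value`, `q_value`, list-column
#'   `cpg_pos`), with the full per-window statistics in attribute
#'   `windows` (`chrom`, `start`, `end`, `delta`, `p`, `q`, `marked`).
#' @export
call_dmrs <- function(track_a, track_b, window_cpgs = 5L, min_delta = 0.2,
                      alpha = 0.01, min_cpgs = 4L, merge_gap = 100L) {
  stopifnot(inherits(track_a, "methylome_track"),
            inherits(track_b, "methylome_track"))
  shared <- merge(
    as.data.frame(track_a)[c("chrom", "pos", "n_meth", "n_total")],
    as.data.frame(track_b)[c("chrom", "pos", "n_meth", "n_total")],
    by = c("chrom", "pos"), suffixes = c("_a", "_b")
  )
  if (nrow(shared) == 0) {
    stop("tracks share no co-covered CpG site; were they called on the same genome?")
  }
  shared <- shared[order(shared$chrom, shared$pos), ]
  w <- as.integer(window_cpgs)

  win_list <- list()
  for (ch in unique(shared$chrom)) {
    s <- shared[shared$chrom == ch, ]
    n <- nrow(s)
    if (n < w) next
    csum <- function(x) { c0 <- cumsum(x); c0[w:n] - c(0, c0)[seq_len(n - w + 1L)] }
    ma <- csum(s$n_meth_a); ta <- csum(s$n_total_a)
    mb <- csum(s$n_meth_b); tb <- csum(s$n_total_b)
    delta <- mb / tb - ma / ta
    p <- fisher_p_2x2(ma, ta, mb, tb)
    win_list[[ch]] <- data.frame(
      chrom = ch, first = seq_len(n - w + 1L),
      start = s$pos[seq_len(n - w + 1L)],
      end = s$pos[w:n],
      delta = delta, p = p, stringsAsFactors = FALSE
    )
  }
  windows <- do.call(rbind, win_list)
  dmr_cols <- c("chrom", "start", "end", "length", "n_cpgs", "level_a",
                "level_b", "delta", "p_value", "q_value")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_cpgs = integer(0), level_a = numeric(0),
                      level_b = numeric(0), delta = numeric(0),
                      p_value = numeric(0), q_value = numeric(0))
  empty$cpg_pos <- list()
  if (is.null(windows)) {
    attr(empty, "windows") <- NULL
    return(empty)
  }
  windows$q <- stats::p.adjust(windows$p, method = "BH")
  windows$marked <- windows$p < alpha & abs(windows$delta) >= min_delta

  dmrs <- list()
  for (ch in unique(windows$chrom)) {
    s <- shared[shared$chrom == ch, ]
    wc <- windows[windows$chrom == ch & windows$marked, ]
    if (nrow(wc) == 0) next
    wc <- wc[order(wc$first), ]
    sgn <- sign(wc$delta)
    cl_first <- wc$first[1]; cl_last <- wc$first[1] + w - 1L
    cl_sign <- sgn[1]; cl_p <- wc$p[1]; cl_q <- wc$q[1]
    flush <- function() {
      idx <- cl_first:cl_last
      sites <- s[idx, ]
      la <- mean(sites$n_meth_a / sites$n_total_a)
      lb <- mean(sites$n_meth_b / sites$n_total_b)
      data.frame(
        chrom = ch, start = sites$pos[1], end = sites$pos[nrow(sites)],
        length = sites$pos[nrow(sites)] - sites$pos[1] + 1L,
        n_cpgs = length(idx), level_a = la, level_b = lb,
        delta = lb - la, p_value = cl_p, q_value = cl_q,
        cpg_pos = I(list(sites$pos)), stringsAsFactors = FALSE
      )
    }
    if (nrow(wc) > 1) {
      for (j in 2:nrow(wc)) {
        shares <- wc$first[j] <= cl_last
        gap_ok <- !shares &&
          (s$pos[wc$first[j]] - s$pos[cl_last]) < merge_gap
        if ((shares || gap_ok) && sgn[j] == cl_sign) {
          cl_last <- max(cl_last, wc$first[j] + w - 1L)
          cl_p <- min(cl_p, wc$p[j]); cl_q <- min(cl_q, wc$q[j])
        } else {
          dmrs[[length(dmrs) + 1L]] <- flush()
          cl_first <- wc$first[j]; cl_last <- wc$first[j] + w - 1L
          cl_sign <- sgn[j]; cl_p <- wc$p[j]; cl_q <- wc$q[j]
        }
      }
    }
    dmrs[[length(dmrs) + 1L]] <- flush()
  }
  out <- if (length(dmrs) > 0) do.call(rbind, dmrs) else empty
  out <- out[out$n_cpgs >= min_cpgs, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "windows") <- windows[setdiff(names(windows), "first")]
  out
}

#' Filter DMRs by length and direction
#'
#' Retains DMRs strictly longer than `min_length` bp (the boundary value
#' itself is dropped) and, under `direction = "hypo_in_b"`, only those with
#' lower methylation in condition B (`delta < 0`); `"hyper_in_b"` keeps
#' `delta > 0` and `"both"` applies no direction filter. Input order is
#' preserved.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param min_length Strict length cutoff in bp (default 200).
#' @param direction `"hypo_in_b"`, `"hyper_in_b"` or `"both"`.
#' @return Filtered DMR data.frame.
#' @export
filter_dmrs <- function(dmrs, min_length = 200L,
                        direction = c("hypo_in_b", "hyper_in_b", "both")) {
  direction <- match.arg(direction)
  keep <- dmrs$length > min_length
  keep <- keep & switch(direction,
    hypo_in_b = dmrs$delta < 0,
    hyper_in_b = dmrs$delta > 0,
    both = TRUE
  )
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of DMR member CpGs located on gene bodies
#'
#' Classifies every member CpG of every DMR with [classify_position()] and
#' reports the percentage labelled exon or intron (the gene body).
#'
#' @param dmrs DMR data.frame carrying the `cpg_pos` list-column.
#' @param genes List of `gene_model`s (or an [element_ranges()] GRanges).
#' @return Percentage in `[0, 100]`.
#' @export
gene_body_cpg_fraction <- function(dmrs, genes) {
  if (nrow(dmrs) == 0) stop("gene-body CpG fraction undefined: no DMRs")
  chrom <- rep(dmrs$chrom, lengths(dmrs$cpg_pos))
  pos <- unlist(dmrs$cpg_pos, use.names = FALSE)
  lab <- classify_position(chrom, pos, genes)
  100 * mean(lab %in% c("exon", "intron"))
}

#' Annotate DMRs with overlapping genes and element composition
#'
#' @param dmrs DMR data.frame.
#' @param genes List of `gene_model`s.
#' @return `dmrs` with added columns `genes` (comma-separated gene ids whose
#'   span overlaps the DMR) and `element_breakdown` (list-column: named
#'   member-CpG counts per element label).
#' @export
annotate_dmrs <- function(dmrs, genes) {
  if (nrow(dmrs) == 0) {
    dmrs$genes <- character(0)
    dmrs$element_breakdown <- list()
    return(dmrs)
  }
  gb <- gene_body_ranges(genes)
  er <- element_ranges(genes)
  dgr <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start, dmrs$end))
  ov <- GenomicRanges::findOverlaps(dgr, gb, ignore.strand = TRUE)
  gl <- split(gb$gene_id[S4Vectors::subjectHits(ov)],
              factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(dmrs))))
  dmrs$genes <- vapply(gl, function(x) paste(sort(unique(x)), collapse = ","),
                       "")
  dmrs$element_breakdown <- lapply(seq_len(nrow(dmrs)), function(i) {
    lab <- classify_position(rep(dmrs$chrom[i], length(dmrs$cpg_pos[[i]])),
                             dmrs$cpg_pos[[i]], er)
    table(lab)
  })
  dmrs
}

#' Per-CpG report for one DMR in both conditions
#'
#' Emits the per-site methylation level of each condition across a DMR plus
#' the region means (site-weighted), the shape of a targeted-validation
#' figure for a single region.
#'
#' @param dmr One-row DMR data.frame (or any list with `chrom`, `start`,
#'   `end`).
#' @param track_a,track_b `methylome_track`s.
#' @return data.frame `pos`, `level_a`, `level_b` with attribute `means`
#'   (named vector `mean_a`, `mean_b`).
#' @export
dmr_region_report <- function(dmr, track_a, track_b) {
  if (is.data.frame(dmr)) {
    stopifnot(nrow(dmr) == 1)
    dmr <- as.list(dmr[1, ])
  }
  sel <- function(tr) {
    tr[tr$chrom == dmr$chrom & tr$pos >= dmr$start & tr$pos <= dmr$end,
       c("pos", "level")]
  }
  a <- sel(track_a); b <- sel(track_b)
  out <- merge(a, b, by = "pos", all = TRUE, suffixes = c("_a", "_b"))
  names(out) <- c("pos", "level_a", "level_b")
  out <- out[order(out$pos), ]
  rownames(out) <- NULL
  attr(out, "means") <- c(mean_a = mean(out$level_a, na.rm = TRUE),
                          mean_b = mean(out$level_b, na.rm = TRUE))
  out
}

#' Write DMRs as extended BED (BED6+)
#'
#' Columns: chrom, start (0-based), end, name, delta, strand (`.`), n_cpgs,
#' level_a, level_b, p, q.
#'
#' @param dmrs DMR data.frame.
#' @param path Output path.
#' @param comments Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  if (nrow(dmrs) > 0) {
    writeLines(sprintf("%s\t%d\t%d\tdmr_%d\t%.6g\t.\t%d\t%.6g\t%.6g\t%.6g\t%.6g",
                       dmrs$chrom, dmrs$start - 1L, dmrs$end,
                       seq_len(nrow(dmrs)), dmrs$delta, dmrs$n_cpgs,
                       dmrs$level_a, dmrs$level_b, dmrs$p_value,
                       dmrs$q_value), con)
  }
  invisible(path)
}

#' Read DMRs written by [write_dmr_bed()]
#' @param path Extended BED path.
#' @return DMR data.frame (1-based coordinates; no `cpg_pos` column).
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_cpgs = integer(0), level_a = numeric(0),
                      level_b = numeric(0), delta = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  f <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  data.frame(
    chrom = f$V1, start = f$V2 + 1L, end = f$V3,
    length = f$V3 - f$V2, n_cpgs = f$V7,
    level_a = f$V8, level_b = f$V9, delta = f$V5,
    p_value = f$V10, q_value = f$V11, stringsAsFactors = FALSE
  )
}
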