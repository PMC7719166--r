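#' Call per-CpG methylation levels from aligned bisulfite reads
#'
#' For every CpG site (indexed by its plus-strand C), reads aligned to the
#' plus strand are read out at the C position (C = methylated, T =
#' unmethylated, i.e. the C>T transition frequency after bisulfite
#' conversion); reads aligned to the minus strand are read out at the G one
#' base downstream (G = methylated, A = unmethylated) and folded onto the
#' same site. Any other base at the informative position is treated as a
#' sequencing anomaly and excluded from both counts. Sites with fewer than
#' `min_coverage` informative reads are not emitted.
#'
#' @param reads A SAM/BAM path, a GAlignments from [read_alignments()], or a
#'   simulator read table.
#' @param genome A `reference_genome` the reads were aligned to.
#' @param min_coverage Minimum informative reads for a site to be emitted
#'   (default 4).
#' @param sample Sample label stored on the track.
#' @return A `methylome_track`: data.frame with columns `chrom`, `pos`
#'   (1-based plus-strand C), `n_meth`, `n_total`, `level`, sorted by
#'   position within chromosome, plus attributes `sample`, `total_calls`,
#'   `total_methylated`.
#' @export
call_methylation <- function(reads, genome, min_coverage = 4L,
                             sample = "sample") {
  stopifnot(inherits(genome, "reference_genome"))
  if (is.character(reads) && length(reads) == 1) {
    reads <- read_alignments(reads)
  }
  tab <- .read_table(reads)
  known <- names(genome$sequences)
  bad <- setdiff(unique(tab$chrom), known)
  if (length(bad) > 0) {
    stop("reads reference unknown chromosome(s): ", paste(bad, collapse = ", "))
  }

  per_chrom <- lapply(known, function(ch) {
    cp <- genome$cpg[[ch]]
    if (length(cp) == 0) return(NULL)
    rt <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(rt) == 0) return(NULL)
    minus <- bitwAnd(rt$flag, 16L) != 0L
    r_ir <- IRanges::IRanges(rt$pos, rt$pos + rt$width - 1L)

    count_strand <- function(rows, at, meth_base, unmeth_base) {
      if (!any(rows)) {
        return(data.frame(pos = integer(0), meth = integer(0),
                          tot = integer(0)))
      }
      ov <- IRanges::findOverlaps(IRanges::IRanges(at, at), r_ir[rows])
      if (length(ov) == 0) {
        return(data.frame(pos = integer(0), meth = integer(0),
                          tot = integer(0)))
      }
      site <- S4Vectors::queryHits(ov)
      ridx <- which(rows)[S4Vectors::subjectHits(ov)]
      off <- at[site] - rt$pos[ridx] + 1L
      b <- substr(rt$seq[ridx], off, off)
      keep <- b %in% c(meth_base, unmeth_base)
      site <- site[keep]; b <- b[keep]
      data.frame(
        pos = cp[site],
        meth = as.integer(b == meth_base),
        tot = 1L
      )
    }

    plus <- count_strand(!minus, cp, "C", "T")
    mnus <- count_strand(minus, cp + 1L, "G", "A")
    both <- rbind(plus, mnus)
    if (nrow(both) == 0) return(NULL)
    dt <- data.table::as.data.table(both)
    agg <- dt[, list(n_meth = sum(meth), n_total = .N), by = "pos"]
    agg <- agg[agg$n_total >= min_coverage, ]
    if (nrow(agg) == 0) return(NULL)
    data.table::setorderv(agg, "pos")
    data.frame(chrom = ch, pos = agg$pos, n_meth = agg$n_meth,
               n_total = agg$n_total,
               level = agg$n_meth / agg$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out) || nrow(out) == 0) {
    warning("no CpG site reached min_coverage; empty track")
    out <- data.frame(chrom = character(0), pos = integer(0),
                      n_meth = integer(0), n_total = integer(0),
                      level = numeric(0))
  }
  methylome_track(out, sample = sample)
}

#' Construct a methylome track from per-site counts
#'
#' @param sites data.frame with columns `chrom`, `pos`, `n_meth`, `n_total`
#'   (and optionally `level`, recomputed here).
#' @param sample Sample label.
#' @return A `methylome_track`.
#' @export
methylome_track <- function(sites, sample = "sample") {
  need <- c("chrom", "pos", "n_meth", "n_total")
  stopifnot(all(need %in% names(sites)))
  if (any(sites$n_meth > sites$n_total) || any(sites$n_meth < 0)) {
    stop("require 0 <= n_meth <= n_total at every site")
  }
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) site")
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites$level <- ifelse(sites$n_total > 0, sites$n_meth / sites$n_total,
                        NA_real_)
  structure(sites,
            sample = sample,
            class = c("methylome_track", "data.frame"))
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf("methylome_track '%s': %d CpG sites on %d chromosome(s), %s\n",
              attr(x, "sample"), nrow(x), length(unique(x$chrom)),
              if (nrow(x) > 0) {
                sprintf("global mCG %.2f%%", global_mcg_percent(x))
              } else "empty"))
  invisible(x)
}

#' Genome-wide methylated-CG percentage
#'
#' Call-weighted: 100 x (sum of methylated calls) / (sum of all calls) over
#' every emitted site, the standard way global WGBS methylation is reported.
#' Invariant under chromosome ordering.
#'
#' @param track A `methylome_track`.
#' @return Percentage in `[0, 100]`.
#' @export
global_mcg_percent <- function(track) {
  stopifnot(inherits(track, "methylome_track"))
  if (nrow(track) == 0 || sum(track$n_total) == 0) {
    stop("global mCG undefined on an empty track")
  }
  100 * sum(track$n_meth) / sum(track$n_total)
}

#' Mean methylation level over a genomic interval
#'
#' Site-weighted: the unweighted mean of per-CpG levels inside the interval
#' (each covered CpG counts once, regardless of its depth), appropriate for
#' small-region summaries such as a single DMR.
#'
#' @param track A `methylome_track`.
#' @param chrom Chromosome.
#' @param start,end Interval bounds, 1-based closed.
#' @return Mean level, or `NA` when the interval contains no covered CpG.
#' @export
region_mean_level <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "methylome_track"), start <= end)
  sel <- track$chrom == chrom & track$pos >= start & track$pos <= end
  if (!any(sel)) return(NA_real_)
  mean(track$level[sel])
}

#' Write a methylome track as bedGraph plus a coverage table
#'
#' The bedGraph holds per-CpG levels (0-based half-open single-base
#' intervals, written by rtracklayer); the companion TSV holds the counts
#' needed to reconstruct the track losslessly.
#'
#' @param track A `methylome_track`.
#' @param bedgraph_path Output bedGraph path.
#' @param coverage_path Output TSV path (default: bedgraph path with
#'   `.cov.tsv` appended); set `NA` to skip.
#' @param comments Optional comment lines prepended as `#` lines.
#' @return `bedgraph_path`, invisibly.
#' @export
write_track <- function(track, bedgraph_path,
                        coverage_path = paste0(bedgraph_path, ".cov.tsv"),
                        comments = NULL) {
  stopifnot(inherits(track, "methylome_track"))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(track$pos, track$pos),
    score = track$level
  )
  rtracklayer::export(gr, bedgraph_path, format = "bedGraph")
  if (!is.null(comments) && length(comments) > 0) {
    body <- readLines(bedgraph_path)
    writeLines(c(paste0("# ", comments), body), bedgraph_path)
  }
  if (!is.na(coverage_path)) {
    con <- file(coverage_path, "w")
    if (!is.null(comments)) writeLines(paste0("# ", comments), con)
    writeLines(paste("chrom", "pos", "n_meth", "n_total", sep = "\t"), con)
    writeLines(sprintf("%s\t%d\t%d\t%d", track$chrom, track$pos,
                       track$n_meth, track$n_total), con)
    close(con)
  }
  invisible(bedgraph_path)
}

#' Read a methylome track written by [write_track()]
#'
#' @param bedgraph_path bedGraph of per-site levels.
#' @param coverage_path Companion coverage TSV; when present the counts are
#'   restored exactly, otherwise levels are kept with unit coverage.
#' @param sample Sample label for the rebuilt track.
#' @return A `methylome_track`.
#' @export
read_track <- function(bedgraph_path,
                       coverage_path = paste0(bedgraph_path, ".cov.tsv"),
                       sample = "sample") {
  if (!is.na(coverage_path) && file.exists(coverage_path)) {
    cov <- data.table::fread(coverage_path, sep = "\t", header = TRUE,
                             skip = "chrom")
    return(methylome_track(as.data.frame(cov), sample = sample))
  }
  gr <- rtracklayer::import(bedgraph_path, format = "bedGraph")
  if (length(gr) > 0 && any(BiocGenerics::width(gr) != 1)) {
    stop("expected single-base records in a per-CpG bedGraph")
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = BiocGenerics::start(gr),
    n_meth = NA_integer_, n_total = 1L,
    stringsAsFactors = FALSE
  )
  df$n_meth <- as.integer(round(gr$score))
  tr <- methylome_track(df, sample = sample)
  tr$level <- gr$score
  tr
}
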