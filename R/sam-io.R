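#' Write aligned reads to a SAM file
#'
#' Serialises a table of aligned reads (as produced by the simulators) into a
#' minimal valid SAM file: `@HD`/`@SQ` header, then one line per read with
#' MAPQ 60 and no mate information. Optional `#`-free comment lines are
#' emitted as `@CO` header records.
#'
#' @param reads A data.frame with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `cigar`, `seq`.
#' @param path Output path.
#' @param chrom_lengths Named integer vector of reference sequence lengths
#'   (required for the `@SQ` header; a `reference_genome` is also accepted).
#' @param comments Optional character vector written as `@CO` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths, comments = NULL) {
  if (inherits(chrom_lengths, "reference_genome")) {
    chrom_lengths <- chrom_lengths(chrom_lengths)
  }
  need <- c("qname", "flag", "chrom", "pos", "cigar", "seq")
  if (!all(need %in% names(reads))) {
    stop("reads must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(bad) > 0) stop("reads reference unknown chromosome(s): ",
                            paste(bad, collapse = ", "))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)),
    if (length(comments)) paste0("@CO\t", comments)
  )
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, as.integer(reads$flag), reads$chrom,
                  as.integer(reads$pos), reads$cigar, reads$seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read aligned reads from SAM or BAM
#'
#' SAM input is converted to BAM in a temporary location via
#' [Rsamtools::asBam()] and read with
#' [GenomicAlignments::readGAlignments()], keeping read names, flags and
#' sequences.
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file.
#' @return A [GenomicAlignments::GAlignments] with names set to read names
#'   and metadata columns `flag` and `seq`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("flag", "seq"))
  GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
}

#' Coerce a GAlignments (or simulator read table) to the internal read table
#'
#' The methylation caller operates on ungapped reads; alignments with
#' insertions, deletions or skips are rejected.
#'
#' @param aln A GAlignments from [read_alignments()], or a data.frame already
#'   in read-table form.
#' @return data.frame with columns `chrom`, `pos`, `flag`, `seq`, `width`.
#' @keywords internal
.read_table <- function(aln) {
  if (is.data.frame(aln)) {
    aln$width <- nchar(aln$seq)
    return(aln)
  }
  stopifnot(methods::is(aln, "GAlignments"))
  cig <- GenomicAlignments::cigar(aln)
  if (any(grepl("[NIDSHP]", cig))) {
    stop("methylation calling expects ungapped alignments (M-only CIGARs)")
  }
  data.frame(
    chrom = as.character(GenomicAlignments::seqnames(aln)),
    pos = BiocGenerics::start(aln),
    flag = S4Vectors::mcols(aln)$flag,
    seq = as.character(S4Vectors::mcols(aln)$seq),
    width = GenomicAlignments::qwidth(aln),
    stringsAsFactors = FALSE
  )
}
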