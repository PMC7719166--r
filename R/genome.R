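#' Reference genome with CpG index
#'
#' Wraps a set of chromosome sequences together with a per-chromosome index of
#' CpG dinucleotide positions. A CpG site is indexed by the 1-based position of
#' its plus-strand C; calls on the minus strand (the G one base downstream) are
#' folded onto the same site by the methylation caller.
#'
#' @param sequences A named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences (A/C/G/T/N only).
#' @return An object of class `reference_genome` with elements `sequences`
#'   (DNAStringSet) and `cpg` (named list of sorted integer positions of the C
#'   of each CG dinucleotide, 1-based).
#' @examples
#' g <- reference_genome(c(chr1 = "ACGCGT"))
#' g$cpg$chr1  # 2, 4
#' @export
reference_genome <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    stop("'sequences' must be a DNAStringSet or named character vector")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("chromosome sequences must have unique names")
  }
  obj <- structure(
    list(sequences = sequences, cpg = build_cpg_index(sequences)),
    class = "reference_genome"
  )
  obj
}

#' Locate all CpG dinucleotides in a set of sequences
#'
#' @param sequences A DNAStringSet (or a `reference_genome`, whose sequences
#'   are used).
#' @return Named list of strictly increasing integer vectors; each value is
#'   the 1-based position of the C of a CG dinucleotide. Dinucleotides
#'   containing N never match.
#' @export
build_cpg_index <- function(sequences) {
  if (inherits(sequences, "reference_genome")) sequences <- sequences$sequences
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  hits <- Biostrings::vmatchPattern("CG", sequences, fixed = TRUE)
  idx <- lapply(hits, function(h) BiocGenerics::start(h))
  names(idx) <- names(sequences)
  idx
}

#' @export
print.reference_genome <- function(x, ...) {
  n_cpg <- sum(lengths(x$cpg))
  cat(sprintf(
    "reference_genome: %d sequence(s), %s bp total, %d CpG sites\n",
    length(x$sequences),
    format(sum(Biostrings::width(x$sequences)), big.mark = ","),
    n_cpg
  ))
  invisible(x)
}

#' Chromosome lengths of a reference genome
#' @param genome A `reference_genome`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "reference_genome"))
  stats::setNames(Biostrings::width(genome$sequences), names(genome$sequences))
}

#' Read a reference genome from a FASTA file
#' @param path Path to a (multi-record) FASTA file.
#' @return A `reference_genome`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first word as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#' @param genome A `reference_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "reference_genome"))
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}
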