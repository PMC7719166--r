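#' Construct a gene model
#'
#' A gene model is a single dominant transcript: an ordered set of exons on
#' one strand, optionally with a CDS, from which the promoter (2 kb upstream
#' of the TSS), UTRs and introns are derived. All coordinates are 1-based
#' closed, the native convention of IRanges/GRanges; BED output converts at
#' the boundary.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon coordinates (1-based
#'   closed), in genomic order, non-overlapping.
#' @param cds_start,cds_end Optional genomic bounds of the coding region;
#'   exonic positions outside them become 5'/3' UTR (strand-aware).
#' @param chrom_length Optional chromosome length used to truncate the
#'   promoter at a chromosome boundary (truncated promoters are kept at
#'   reduced length, not dropped).
#' @param promoter_size Width of the upstream promoter window (default 2000
#'   bp, i.e. the 2 kb immediately upstream of the TSS).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       chrom_length = NA_integer_, promoter_size = 2000L) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_ends < exon_starts)) stop("exon end < start")
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)])) {
    stop("exons overlap or abut ambiguously for gene ", gene_id)
  }
  exons <- IRanges::IRanges(exon_starts, exon_ends)

  tss <- if (strand == "+") exon_starts[1] else exon_ends[length(exon_ends)]
  if (strand == "+") {
    promoter <- IRanges::IRanges(max(1L, tss - promoter_size), tss - 1L)
    if (tss == 1L) promoter <- IRanges::IRanges()  # nothing upstream
  } else {
    pe <- tss + promoter_size
    if (!is.na(chrom_length)) pe <- min(pe, as.integer(chrom_length))
    promoter <- if (pe >= tss + 1L) IRanges::IRanges(tss + 1L, pe) else
      IRanges::IRanges()
  }

  introns <- if (length(exons) > 1) {
    IRanges::IRanges(utils::head(exon_ends, -1) + 1L,
                     utils::tail(exon_starts, -1) - 1L)
  } else IRanges::IRanges()

  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exons = exons, introns = introns, tss = as.integer(tss),
      promoter = promoter,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      span = IRanges::IRanges(exon_starts[1], exon_ends[length(exon_ends)])
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "gene_model %s (%s:%d-%d, %s): %d exon(s), TSS %d\n",
    x$gene_id, x$chrom, IRanges::start(x$span), IRanges::end(x$span),
    x$strand, length(x$exons), x$tss
  ))
  invisible(x)
}

#' Strand-aware element decomposition of a gene model
#'
#' Splits the gene span into promoter, 5'UTR, exon (CDS part when a CDS is
#' annotated, whole exons otherwise), intron and 3'UTR pieces. Every position
#' within the span belongs to exactly one of the non-promoter elements.
#'
#' @param gene A `gene_model`.
#' @return A data.frame with columns `element`, `start`, `end`, `instance`
#'   (index of the piece within its element class, in transcription order).
#' @export
gene_elements <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- gene$exons
  pieces <- list()
  add <- function(el, ir) {
    ir <- ir[IRanges::width(ir) > 0]
    if (length(ir) > 0) {
      pieces[[length(pieces) + 1L]] <<- data.frame(
        element = el, start = IRanges::start(ir), end = IRanges::end(ir)
      )
    }
  }
  if (length(gene$promoter) > 0) add("promoter", gene$promoter)
  if (!is.na(gene$cds_start) && !is.na(gene$cds_end)) {
    left <- IRanges::restrict(ex, end = gene$cds_start - 1L)
    right <- IRanges::restrict(ex, start = gene$cds_end + 1L)
    cds <- IRanges::restrict(ex, start = gene$cds_start, end = gene$cds_end)
    if (gene$strand == "+") {
      add("5utr", left); add("3utr", right)
    } else {
      add("5utr", right); add("3utr", left)
    }
    add("exon", cds)
  } else {
    add("exon", ex)
  }
  add("intron", gene$introns)
  out <- do.call(rbind, pieces)
  # transcription-order instance index within each element class
  out <- out[order(out$element, out$start), , drop = FALSE]
  out$instance <- stats::ave(out$start, out$element, FUN = function(s) {
    r <- rank(s)
    if (gene$strand == "-") r <- length(s) + 1 - r
    as.integer(r)
  })
  rownames(out) <- NULL
  out
}

# Priority used when a position is covered by elements of several genes;
# promoters outrank transcribed elements because promoter methylation is the
# interpretive frame of most downstream analyses.
.element_priority <- c(promoter = 1L, `5utr` = 2L, `3utr` = 3L,
                       exon = 4L, intron = 5L)

#' Pooled element ranges for a gene set
#'
#' @param genes List of `gene_model`s.
#' @return A [GenomicRanges::GRanges] with metadata columns `element`,
#'   `gene_id`, `instance` and `gene_strand`.
#' @export
element_ranges <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  parts <- lapply(genes, function(g) {
    el <- gene_elements(g)
    GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(el$start, el$end),
      strand = "*",
      element_class = el$element, gene_id = g$gene_id,
      instance = el$instance, gene_strand = g$strand
    )
  })
  do.call(c, unname(parts))
}

#' Classify genomic positions into gene functional elements
#'
#' Assigns each position a single label among promoter, 5utr, 3utr, exon,
#' intron and intergenic. Where annotations of several genes overlap, the
#' label with the highest priority wins (promoter > 5utr > 3utr > exon >
#' intron); intergenic is the fallback. "Gene body" is the union of exon and
#' intron.
#'
#' @param chrom Chromosome name (scalar or vector parallel to `pos`).
#' @param pos Integer vector of 1-based positions.
#' @param genes List of `gene_model`s, or a precomputed [element_ranges()]
#'   GRanges (cheaper when classifying repeatedly).
#' @return Character vector of labels, one per position.
#' @export
classify_position <- function(chrom, pos, genes) {
  er <- if (methods::is(genes, "GRanges")) genes else element_ranges(genes)
  q <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, length(pos)),
    ranges = IRanges::IRanges(pos, pos)
  )
  hits <- GenomicRanges::findOverlaps(q, er, ignore.strand = TRUE)
  lab <- rep("intergenic", length(pos))
  if (length(hits) > 0) {
    h <- data.frame(
      q = S4Vectors::queryHits(hits),
      prio = .element_priority[er$element_class[S4Vectors::subjectHits(hits)]],
      el = er$element_class[S4Vectors::subjectHits(hits)]
    )
    h <- h[order(h$q, h$prio), , drop = FALSE]
    first <- !duplicated(h$q)
    lab[h$q[first]] <- h$el[first]
  }
  lab
}

#' Read gene models from a GTF file
#'
#' Parses GTF2.2 `exon` (and optional `CDS`) features grouped by `gene_id`,
#' converting from GTF's 1-based inclusive coordinates into the package's
#' IRanges convention (identical, so no shift is applied; BED I/O performs
#' the 0-based conversion instead). One dominant transcript per gene_id is
#' assumed; genes with zero exon features are skipped with a warning.
#'
#' @param path GTF file path.
#' @param chrom_lengths Optional named integer vector used to truncate
#'   promoters at chromosome ends.
#' @return Named list of `gene_model`s.
#' @export
read_gtf <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF has no gene_id attribute: ", path)
  }
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  ids <- unique(gr$gene_id)
  genes <- list()
  for (id in ids) {
    e <- ex[ex$gene_id == id]
    if (length(e) == 0) {
      warning("gene ", id, " has no exon features; skipped")
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    strand <- as.character(BiocGenerics::strand(e))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    ccds <- cds[cds$gene_id == id]
    cs <- if (length(ccds) > 0) min(BiocGenerics::start(ccds)) else NA_integer_
    ce <- if (length(ccds) > 0) max(BiocGenerics::end(ccds)) else NA_integer_
    cl <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else NA_integer_
    genes[[id]] <- gene_model(
      gene_id = id, chrom = chrom, strand = strand,
      exon_starts = BiocGenerics::start(e), exon_ends = BiocGenerics::end(e),
      cds_start = cs, cds_end = ce, chrom_length = cl
    )
  }
  genes
}

#' Write gene models to a GTF file
#' @param genes List of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  parts <- lapply(genes, function(g) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$chrom, ranges = g$exons, strand = g$strand
    )
    gr$type <- "exon"
    gr$source <- "skipmeth"
    gr$gene_id <- g$gene_id
    gr$transcript_id <- paste0(g$gene_id, ".1")
    if (!is.na(g$cds_start) && !is.na(g$cds_end)) {
      cds <- IRanges::restrict(g$exons, start = g$cds_start, end = g$cds_end)
      cds <- cds[IRanges::width(cds) > 0]
      cgr <- GenomicRanges::GRanges(
        seqnames = g$chrom, ranges = cds, strand = g$strand
      )
      cgr$type <- "CDS"
      cgr$phase <- 0L
      cgr$source <- "skipmeth"
      cgr$gene_id <- g$gene_id
      cgr$transcript_id <- paste0(g$gene_id, ".1")
      gr <- c(gr, cgr)
    }
    gr
  })
  all <- do.call(c, unname(parts))
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Gene-body spans (exons plus introns) as a GRanges
#' @param genes List of `gene_model`s.
#' @return GRanges with one range per gene (first exon start to last exon
#'   end) and a `gene_id` metadata column.
#' @export
gene_body_ranges <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      vapply(genes, function(g) IRanges::start(g$span), 1L),
      vapply(genes, function(g) IRanges::end(g$span), 1L)
    ),
    gene_id = vapply(genes, `[[`, "", "gene_id")
  )
}

#' Read a BED file as a GRanges
#' @param path BED file path (BED3-BED6).
#' @return GRanges (1-based internally; rtracklayer converts).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write a GRanges to BED
#' @param gr GRanges to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
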