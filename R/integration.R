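#' Total gene-body DMR length per gene
#'
#' Sums, for every gene, the base pairs of each (filtered) DMR interval
#' intersected with the gene body (first to last exon). A DMR overlapping
#' two genes contributes its respective overlap to each; genes without
#' overlap get 0.
#'
#' @param dmrs DMR data.frame with `chrom`, `start`, `end` (1-based closed).
#' @param genes List of `gene_model`s.
#' @return Named numeric vector, bp of DMR overlap per gene.
#' @export
dmr_length_per_gene <- function(dmrs, genes) {
  gb <- gene_body_ranges(genes)
  out <- stats::setNames(numeric(length(gb)), gb$gene_id)
  if (nrow(dmrs) == 0) return(out)
  dgr <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start, dmrs$end))
  ov <- GenomicRanges::findOverlaps(dgr, gb, ignore.strand = TRUE)
  if (length(ov) == 0) return(out)
  inter <- IRanges::pintersect(
    IRanges::ranges(dgr)[S4Vectors::queryHits(ov)],
    IRanges::ranges(gb)[S4Vectors::subjectHits(ov)]
  )
  bp <- tapply(IRanges::width(inter),
               gb$gene_id[S4Vectors::subjectHits(ov)], sum)
  out[names(bp)] <- bp
  out
}

#' Join DMR lengths with a two-condition expression table
#'
#' @param dmr_lengths Named vector from [dmr_length_per_gene()].
#' @param expression data.frame `gene_id`, `value_wt`, `value_ko` (values
#'   as provided, e.g. normalised counts or FPKM; no normalisation is
#'   applied here).
#' @param pseudocount Added to both values before the ratio (default 0;
#'   records with a non-positive value are then flagged and dropped from
#'   correlation).
#' @return data.frame `gene_id`, `total_dmr_length`, `value_wt`, `value_ko`,
#'   `log2_fold_change` (NA where undefined), `valid`.
#' @export
gene_dmr_expression <- function(dmr_lengths, expression, pseudocount = 0) {
  stopifnot(all(c("gene_id", "value_wt", "value_ko") %in% names(expression)))
  out <- data.frame(
    gene_id = expression$gene_id,
    total_dmr_length = as.numeric(dmr_lengths[expression$gene_id]),
    value_wt = expression$value_wt,
    value_ko = expression$value_ko,
    stringsAsFactors = FALSE
  )
  out$total_dmr_length[is.na(out$total_dmr_length)] <- 0
  a <- out$value_wt + pseudocount
  b <- out$value_ko + pseudocount
  out$valid <- a > 0 & b > 0
  out$log2_fold_change <- ifelse(out$valid, log2(b / a), NA_real_)
  out
}

#' Correlate gene-body DMR length with expression fold change
#'
#' Rank (Spearman) correlation by default, because DMR lengths are
#' heavy-tailed; Pearson available. The default analysis population is
#' genes carrying at least one DMR (`restrict_to_dmr_genes = TRUE`); an
#' all-genes mode (zero lengths included) is provided for sensitivity.
#'
#' @param records Output of [gene_dmr_expression()].
#' @param method `"spearman"` or `"pearson"`.
#' @param restrict_to_dmr_genes Keep only `total_dmr_length > 0` records.
#' @return List: `estimate` (rho or r), `p_value`, `n`, `method`.
#' @export
correlate_dmr_expression <- function(records,
                                     method = c("spearman", "pearson"),
                                     restrict_to_dmr_genes = TRUE) {
  method <- match.arg(method)
  r <- records[records$valid & !is.na(records$log2_fold_change), ]
  if (restrict_to_dmr_genes) r <- r[r$total_dmr_length > 0, ]
  if (nrow(r) < 3) stop("need >= 3 valid records for a correlation")
  if (stats::sd(r$total_dmr_length) == 0 || stats::sd(r$log2_fold_change) == 0) {
    stop("correlation undefined: constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(
    r$total_dmr_length, r$log2_fold_change,
    method = method, alternative = "two.sided", exact = FALSE
  ))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = nrow(r),
       method = method)
}

#' Tumor volume from caliper measurements
#'
#' `volume = length x width^2 / 2` (mm^3). When width exceeds length the
#' two are swapped with a warning, since width is defined as the
#' perpendicular (shorter) diameter.
#'
#' @param length_mm Longest diameter (mm).
#' @param width_mm Perpendicular diameter (mm).
#' @return Volume in mm^3 (vectorised).
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("measurements must be positive")
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapping")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Write / read a two-condition expression table
#' @param expression data.frame `gene_id`, `value_wt`, `value_ko`.
#' @param path TSV path.
#' @param comments Optional `#` comment lines.
#' @return `path` invisibly, or the table for the reader.
#' @export
write_expression <- function(expression, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(expression[c("gene_id", "value_wt", "value_ko")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "gene_id"))
}
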