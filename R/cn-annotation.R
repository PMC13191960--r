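#' Gene-level weighted copy number
#'
#' Mean of the copy-number segments overlapping the gene span, weighted by
#' the bp each segment covers of the transcript; when segments cover only
#' part of the gene the weights are renormalized over the covered bp.
#'
#' @param segments a `cn_segments` (or data.frame with chrom, start, end,
#'   copy_number).
#' @param gene one-row data.frame with chrom, start, end (0-based
#'   half-open).
#' @return weighted mean CN, or `NA` when no segment overlaps the gene.
#' @export
gene_weighted_cn <- function(segments, gene) {
  s <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  ov <- pmin(s$end, gene$end) - pmax(s$start, gene$start)
  keep <- ov > 0
  if (!any(keep)) return(NA_real_)
  sum(s$copy_number[keep] * ov[keep]) / sum(ov[keep])
}

#' Ploidy-aware copy-number status call
#'
#' Weighted CN below 0.5 is biallelic loss (takes precedence). Otherwise,
#' on single-copy sex chromosomes, gain when CN > ploidy x 0.8 and loss
#' when CN < ploidy x 0.3; on autosomes, gain when CN > ploidy x 1.95 and
#' loss when CN < ploidy x 0.5. All inequalities are strict; boundary
#' values fall to neutral.
#'
#' @param weighted_cn gene-level weighted CN.
#' @param ploidy tumor ploidy (> 0).
#' @param chrom_type "autosome" or "single_copy_sex".
#' @return one of "biallelic_loss", "loss", "gain", "neutral".
#' @export
call_cn_status <- function(weighted_cn, ploidy,
                           chrom_type = c("autosome", "single_copy_sex")) {
  chrom_type <- match.arg(chrom_type)
  stopifnot(ploidy > 0)
  if (is.na(weighted_cn)) return(NA_character_)
  if (weighted_cn < 0.5) return("biallelic_loss")
  if (chrom_type == "single_copy_sex") {
    if (weighted_cn > ploidy * 0.8) return("gain")
    if (weighted_cn < ploidy * 0.3) return("loss")
  } else {
    if (weighted_cn > ploidy * 1.95) return("gain")
    if (weighted_cn < ploidy * 0.5) return("loss")
  }
  "neutral"
}

#' Gene-level CN annotation across a gene table
#'
#' @param segments a `cn_segments` (its ploidy attribute is used).
#' @param genes data.frame with gene_id, chrom, start, end, and optional
#'   chrom_type column ("autosome"/"single_copy_sex"; defaults to
#'   single_copy_sex for chrX/chrY/X/Y, autosome otherwise — the male
#'   genome convention).
#' @return data.frame with gene_id, weighted_cn, status, ploidy_used,
#'   chrom_type.
#' @export
annotate_gene_cn <- function(segments, genes) {
  ploidy <- attr(segments, "ploidy")
  if (is.null(genes$chrom_type)) {
    genes$chrom_type <- ifelse(genes$chrom %in% c("chrX", "chrY", "X", "Y"),
                               "single_copy_sex", "autosome")
  }
  res <- lapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    wcn <- gene_weighted_cn(segments, g)
    data.frame(gene_id = g$gene_id, weighted_cn = wcn,
               status = call_cn_status(wcn, ploidy, g$chrom_type),
               ploidy_used = ploidy, chrom_type = g$chrom_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Event-weighted copy number of a cSV
#'
#' Length-weighted mean of the event's segment copy numbers.
#'
#' @param event an `amplicon_event`.
#' @return numeric.
#' @export
event_weighted_cn <- function(event) {
  len <- event$segments$end - event$segments$start
  if (sum(len) <= 0) stop("event has zero total segment length")
  sum(event$segments$copy_number * len) / sum(len)
}
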