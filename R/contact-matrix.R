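#' Binned Hi-C contact matrix
#'
#' A symmetric sparse matrix of contact values over genome-wide bins, plus a
#' per-bin mask. Bins with zero marginal count are masked (treated as
#' unmappable rather than as true zeros, mirroring standard Hi-C practice).
#'
#' @param bins a `genome_bins`.
#' @param i,j 1-based bin indices of non-zero pixels (any order within pair).
#' @param x non-negative contact values.
#' @param balanced logical; whether values are already normalized.
#' @param bias optional per-bin positive bias vector from balancing.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, i, j, x, balanced = FALSE, bias = NULL) {
  stopifnot(inherits(bins, "genome_bins"),
            length(i) == length(j), length(j) == length(x))
  if (any(x < 0)) stop("negative contact value")
  if (length(i) && (min(i, j) < 1 || max(i, j) > bins$n_bins)) {
    stop("bin id out of range")
  }
  # store upper triangle; symmetric container
  lo <- pmin(i, j); hi <- pmax(i, j)
  mat <- Matrix::sparseMatrix(i = lo, j = hi, x = x,
                              dims = c(bins$n_bins, bins$n_bins),
                              symmetric = TRUE)
  cm <- structure(list(bins = bins, mat = mat, balanced = balanced,
                       bias = bias), class = "contact_matrix")
  mask_zero_bins(cm)
}

# mask bins with zero marginal; drop stored entries touching masked bins
mask_zero_bins <- function(cm) {
  marg <- Matrix::rowSums(cm$mat)
  cm$bins$mask <- cm$bins$mask | (marg == 0)
  if (any(cm$bins$mask)) {
    keep <- !cm$bins$mask
    cm$mat <- cm$mat * outer(keep, keep) # zero out masked rows/cols
    cm$mat <- Matrix::drop0(cm$mat)
  }
  cm
}

#' @export
print.contact_matrix <- function(x, ...) {
  nz <- length(x$mat@x)
  cat("contact_matrix:", x$bins$n_bins, "bins,", nz, "stored entries,",
      if (x$balanced) "balanced" else "raw", "\n")
  invisible(x)
}

#' Symmetric accessor for contact values
#'
#' @param cm a `contact_matrix`.
#' @param i,j equal-length bin index vectors.
#' @return numeric contact values; pairs touching masked bins return `NA`.
#' @export
contact_value <- function(cm, i, j) {
  v <- cm$mat[cbind(i, j)]
  v[cm$bins$mask[i] | cm$bins$mask[j]] <- NA_real_
  v
}

# all values for the unordered pair set A x B (A, B bin index vectors),
# masked bins dropped. If A and B are the same set, returns each unordered
# pair once, excluding self-pairs when diag = FALSE.
pair_values <- function(cm, a, b, same_set = FALSE, diag = FALSE) {
  a <- a[!cm$bins$mask[a]]
  b <- b[!cm$bins$mask[b]]
  if (!length(a) || !length(b)) {
    return(data.frame(i = integer(), j = integer(), value = numeric(),
                      sep = integer()))
  }
  g <- expand.grid(i = a, j = b)
  if (same_set) {
    g <- g[if (diag) g$i <= g$j else g$i < g$j, , drop = FALSE]
  }
  v <- cm$mat[cbind(g$i, g$j)]
  same_chrom <- cm$bins$bin_chrom[g$i] == cm$bins$bin_chrom[g$j]
  sep <- ifelse(same_chrom, abs(g$i - g$j), NA_integer_)
  data.frame(i = g$i, j = g$j, value = v, sep = sep)
}

#' Read a contact matrix from bins + pixels text tables
#'
#' The bins table (TSV with header: chrom, start, end) must tile the declared
#' genome in order at the genome's bin size; the pixels table (TSV with
#' header: bin1_id, bin2_id, count) uses 0-based bin ids with
#' bin1_id <= bin2_id, the sparse upper-triangle dialect used by cooler.
#'
#' @param bins_path,pixels_path file paths.
#' @param bins a `genome_bins` declaring the expected genome.
#' @return a `contact_matrix` (raw counts).
#' @export
read_contact_matrix <- function(bins_path, pixels_path, bins) {
  bt <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bt))) stop("bins table needs columns: ",
                                      paste(need, collapse = ", "))
  if (nrow(bt) != bins$n_bins) {
    stop("bins table has ", nrow(bt), " rows; genome declares ", bins$n_bins)
  }
  exp_iv <- bin_interval(bins, seq_len(bins$n_bins))
  if (!all(bt$chrom == exp_iv$chrom & bt$start == exp_iv$start &
           bt$end == exp_iv$end)) {
    stop("bins table does not match the declared genome tiling")
  }
  px <- utils::read.table(pixels_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("bin1_id", "bin2_id", "count")
  if (!all(need %in% names(px))) stop("pixels table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(px$bin1_id > px$bin2_id)) stop("pixels must have bin1_id <= bin2_id")
  if (any(px$count < 0)) stop("negative count in pixels")
  if (nrow(px) && (min(px$bin1_id) < 0 || max(px$bin2_id) >= bins$n_bins)) {
    stop("bin id out of range")
  }
  contact_matrix(bins, px$bin1_id + 1L, px$bin2_id + 1L, px$count)
}

#' Write a contact matrix as bins + pixels text tables
#'
#' @param cm a `contact_matrix`.
#' @param bins_path,pixels_path output paths.
#' @export
write_contact_matrix <- function(cm, bins_path, pixels_path) {
  iv <- bin_interval(cm$bins, seq_len(cm$bins$n_bins))
  utils::write.table(iv, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tm <- methods::as(methods::as(cm$mat, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j
  px <- data.frame(bin1_id = tm@i[keep], bin2_id = tm@j[keep],
                   count = tm@x[keep])
  px <- px[order(px$bin1_id, px$bin2_id), ]
  utils::write.table(px, pixels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}
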