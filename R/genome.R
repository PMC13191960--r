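#' Genome binning at fixed resolution
#'
#' Tiles each chromosome with consecutive fixed-width bins (the last bin of a
#' chromosome may be short). Bins are indexed 1..n_bins genome-wide, in the
#' order chromosomes are given. Coordinates are 0-based half-open throughout
#' the package; converters at the I/O boundary handle 1-based dialects.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 10 kb, the working resolution for
#'   tumor Hi-C contact maps).
#' @return an object of class `genome_bins`.
#' @export
genome_bins <- function(chrom_lengths, bin_size = 10000L) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            bin_size > 0)
  bin_size <- as.integer(bin_size)
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  offset <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offset) <- names(chrom_lengths)
  n_bins <- sum(nb)
  bin_chrom <- rep.int(seq_along(nb), nb)
  bin_start <- unlist(lapply(seq_along(nb), function(k) {
    (seq_len(nb[k]) - 1) * bin_size
  }), use.names = FALSE)
  structure(list(
    chrom_names   = names(chrom_lengths),
    chrom_lengths = chrom_lengths,
    bin_size      = bin_size,
    n_per_chrom   = nb,
    offset        = offset,
    n_bins        = n_bins,
    bin_chrom     = bin_chrom,
    bin_start     = bin_start,
    mask          = logical(n_bins)
  ), class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("genome_bins:", length(x$chrom_names), "chromosome(s),",
      x$n_bins, "bins of", x$bin_size, "bp;",
      sum(x$mask), "masked\n")
  invisible(x)
}

chrom_id <- function(bins, chrom) {
  id <- match(chrom, bins$chrom_names)
  if (anyNA(id)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(id)]), collapse = ", "))
  }
  id
}

#' Bin index containing a genomic position
#'
#' @param bins a `genome_bins`.
#' @param chrom chromosome name (vectorized).
#' @param pos 0-based position (vectorized).
#' @return integer genome-wide bin indices (1-based).
#' @export
bin_index <- function(bins, chrom, pos) {
  id <- chrom_id(bins, chrom)
  stopifnot(all(pos >= 0), all(pos < bins$chrom_lengths[id]))
  as.integer(bins$offset[id] + pos %/% bins$bin_size + 1)
}

#' Bin indices overlapping a 0-based half-open interval
#' @param bins a `genome_bins`.
#' @param chrom chromosome name (scalar).
#' @param start,end 0-based half-open bounds.
#' @export
bins_for_interval <- function(bins, chrom, start, end) {
  id <- chrom_id(bins, chrom)
  stopifnot(start >= 0, end > start, end <= bins$chrom_lengths[id])
  first <- start %/% bins$bin_size
  last <- (end - 1) %/% bins$bin_size
  as.integer(bins$offset[id] + seq.int(first, last) + 1)
}

#' Interval covered by a bin
#' @param bins a `genome_bins`.
#' @param idx genome-wide bin index.
#' @return data.frame with chrom, start, end (0-based half-open).
#' @export
bin_interval <- function(bins, idx) {
  stopifnot(all(idx >= 1), all(idx <= bins$n_bins))
  cid <- bins$bin_chrom[idx]
  st <- bins$bin_start[idx]
  data.frame(chrom = bins$chrom_names[cid], start = st,
             end = pmin(st + bins$bin_size, bins$chrom_lengths[cid]),
             stringsAsFactors = FALSE)
}

#' Construct a genomic interval record (0-based half-open)
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, start < end.
#' @param chrom_length optional bound check.
#' @export
genomic_interval <- function(chrom, start, end, chrom_length = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(start >= 0), all(start < end))
  if (!is.null(chrom_length)) stopifnot(all(end <= chrom_length))
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

# Merge overlapping/adjacent intervals within each chromosome.
# Returns a data.frame(chrom,start,end) sorted by (chrom, start).
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Total bp covered by an interval set after self-merge.
intervals_bp <- function(iv) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0) 0 else sum(m$end - m$start)
}

# bp of intersection of two interval sets (each self-merged first).
intervals_intersect_bp <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  chroms <- intersect(a$chrom, b$chrom)
  tot <- 0
  for (ch in chroms) {
    ra <- IRanges::IRanges(start = a$start[a$chrom == ch] + 1,
                           end = a$end[a$chrom == ch])
    rb <- IRanges::IRanges(start = b$start[b$chrom == ch] + 1,
                           end = b$end[b$chrom == ch])
    ri <- IRanges::intersect(ra, rb)
    tot <- tot + sum(IRanges::width(ri))
  }
  tot
}
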