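#' Annotate events with regulatory-peak overlap
#'
#' An event is positive when any of its segments overlaps a peak by at
#' least `min_overlap_bp` (default 100 bp, read inclusively).
#'
#' @param events list of `amplicon_event`.
#' @param peaks data.frame with chrom, start, end.
#' @param min_overlap_bp minimum single-peak overlap in bp.
#' @return list with `per_event` (data.frame event_id, class, positive)
#'   and `fraction_by_class`.
#' @export
annotate_overlap <- function(events, peaks, min_overlap_bp = 100) {
  pos <- vapply(events, function(e) {
    any(vapply(seq_len(nrow(e$segments)), function(k) {
      s <- e$segments[k, ]
      p <- peaks[peaks$chrom == s$chrom, , drop = FALSE]
      if (!nrow(p)) return(FALSE)
      ov <- pmin(p$end, s$end) - pmax(p$start, s$start)
      any(ov >= min_overlap_bp)
    }, logical(1)))
  }, logical(1))
  per_event <- data.frame(
    event_id = vapply(events, `[[`, character(1), "event_id"),
    class = vapply(events, `[[`, character(1), "class"),
    positive = pos, stringsAsFactors = FALSE)
  list(per_event = per_event,
       fraction_by_class = tapply(per_event$positive, per_event$class, mean))
}

# per-chromosome mask-free gaps as data.frame(start, end), 0-based half-open
mask_free_gaps <- function(chrom, chrom_length, mask) {
  m <- merge_intervals(mask[mask$chrom == chrom, , drop = FALSE])
  if (!nrow(m)) return(data.frame(start = 0, end = chrom_length))
  starts <- c(0, m$end)
  ends <- c(m$start, chrom_length)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# place an interval of length len uniformly over feasible start positions
# in the gaps (exact gap-sampling: weight each gap by its feasible starts)
sample_placement <- function(gaps, len) {
  slots <- gaps$end - gaps$start - len + 1
  feasible <- slots > 0
  if (!any(feasible)) return(NA_real_)
  g <- which(feasible)
  pick <- g[sample.int(length(g), 1, prob = slots[g])]
  gaps$start[pick] + sample.int(slots[pick], 1) - 1
}

#' Permutation test for interval-set overlap with peaks
#'
#' Each permutation re-places every query interval uniformly at random on
#' its own chromosome within mask-free space, preserving interval length
#' and chromosome distribution; the statistic is the number of query
#' intervals overlapping at least one peak (any overlap). The empirical p
#' is (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param query data.frame with chrom, start, end.
#' @param peaks data.frame with chrom, start, end.
#' @param genome named vector of chromosome lengths.
#' @param exclusion_mask data.frame with chrom, start, end (may be empty).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return object of class `permutation_result`.
#' @export
permutation_overlap_test <- function(query, peaks, genome,
                                     exclusion_mask = NULL, n_perm = 1000,
                                     seed = 1) {
  if (is.null(exclusion_mask)) {
    exclusion_mask <- data.frame(chrom = character(), start = numeric(),
                                 end = numeric())
  }
  stopifnot(all(query$chrom %in% names(genome)))
  peaks_by_chrom <- split(peaks, peaks$chrom)
  overlaps_any <- function(chrom, start, end) {
    p <- peaks_by_chrom[[chrom]]
    if (is.null(p) || !nrow(p)) return(FALSE)
    any(pmin(p$end, end) - pmax(p$start, start) > 0)
  }
  count_stat <- function(q) {
    sum(vapply(seq_len(nrow(q)), function(k) {
      overlaps_any(q$chrom[k], q$start[k], q$end[k])
    }, logical(1)))
  }
  gaps <- lapply(unique(query$chrom), function(ch) {
    mask_free_gaps(ch, genome[[ch]], exclusion_mask)
  })
  names(gaps) <- unique(query$chrom)
  lens <- query$end - query$start
  for (k in seq_len(nrow(query))) {
    slots <- gaps[[query$chrom[k]]]
    if (all(slots$end - slots$start < lens[k])) {
      stop("interval ", query$chrom[k], ":", query$start[k], "-",
           query$end[k], " is longer than every mask-free gap on its ",
           "chromosome")
    }
  }
  observed <- count_stat(query)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    starts <- vapply(seq_len(nrow(query)), function(k) {
      sample_placement(gaps[[query$chrom[k]]], lens[k])
    }, numeric(1))
    qb <- data.frame(chrom = query$chrom, start = starts,
                     end = starts + lens)
    null_counts[b] <- count_stat(qb)
  }
  structure(list(observed_overlap_count = observed,
                 null_counts = null_counts,
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation overlap test: observed =", x$observed_overlap_count,
      "; null mean =", round(mean(x$null_counts), 2),
      "; empirical p =", signif(x$empirical_p, 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
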