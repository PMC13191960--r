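#' Chromothripsis caller configuration
#'
#' A 2.5 Mb window slides at 10 kb steps; a window is chromothriptic when it
#' holds at least 15 inversions, 15 copy-number switches and 10 deletions.
#'
#' @param window_size window width in bp.
#' @param step window step in bp.
#' @param min_inversions,min_cn_switches,min_deletions calling thresholds.
#' @param switch_epsilon minimum |delta CN| between adjacent segments for a
#'   boundary to count as a copy-number switch (0.5 copies separates
#'   distinct integer states at typical purity).
#' @export
chromothripsis_config <- function(window_size = 2500000, step = 10000,
                                  min_inversions = 15, min_cn_switches = 15,
                                  min_deletions = 10, switch_epsilon = 0.5) {
  stopifnot(window_size > 0, step > 0, step <= window_size,
            min_inversions > 0, min_cn_switches > 0, min_deletions > 0)
  structure(list(window_size = window_size, step = step,
                 min_inversions = min_inversions,
                 min_cn_switches = min_cn_switches,
                 min_deletions = min_deletions,
                 switch_epsilon = switch_epsilon),
            class = "chromothripsis_config")
}

# count of points in [ws, ws + width) for each window start, given sorted
# point positions; for SVs a "point" exists only when both ends fall inside,
# so we count by the condition min_pos >= ws & max_pos < ws + width.
count_span_in_windows <- function(lo, hi, starts, width) {
  if (!length(lo)) return(integer(length(starts)))
  vapply(starts, function(ws) {
    sum(lo >= ws & hi < ws + width)
  }, integer(1))
}

#' Per-window SV and copy-number switch counts on one chromosome
#'
#' Windows start at multiples of the step across the span of the input
#' data. An inversion/deletion counts in a window only when both breakends
#' lie inside it; a copy-number switch is an adjacent-segment boundary
#' inside the window where CN changes by more than `switch_epsilon`.
#' Insertions are tallied for completeness but play no part in the call.
#'
#' @param breakpoints a `breakpoints` data.frame.
#' @param segments a `cn_segments`.
#' @param chrom chromosome to scan.
#' @param config a `chromothripsis_config`.
#' @return data.frame of windows with counts and the `called` flag.
#' @export
count_window_features <- function(breakpoints, segments, chrom,
                                  config = chromothripsis_config()) {
  bp <- breakpoints[breakpoints$chrom1 == chrom &
                      breakpoints$chrom2 == chrom, , drop = FALSE]
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  switch_pos <- numeric(0)
  if (nrow(seg) > 1) {
    seg <- seg[order(seg$start), ]
    dcn <- abs(diff(seg$copy_number))
    adjacent <- seg$start[-1] == seg$end[-nrow(seg)]
    switch_pos <- seg$start[-1][adjacent & dcn > config$switch_epsilon]
  }
  pos_all <- c(bp$pos1, bp$pos2, switch_pos)
  if (!length(pos_all)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_inversions = integer(),
                      n_deletions = integer(), n_insertions = integer(),
                      n_cn_switches = integer(), called = logical()))
  }
  first <- (max(0, min(pos_all) - config$window_size) %/% config$step) *
    config$step
  last <- (max(pos_all) %/% config$step) * config$step
  starts <- seq(first, last, by = config$step)
  count_type <- function(type) {
    b <- bp[bp$sv_type == type, , drop = FALSE]
    count_span_in_windows(pmin(b$pos1, b$pos2), pmax(b$pos1, b$pos2),
                          starts, config$window_size)
  }
  n_inv <- count_type("INV")
  n_del <- count_type("DEL")
  n_ins <- count_type("INS")
  n_sw <- count_span_in_windows(switch_pos, switch_pos, starts,
                                config$window_size)
  data.frame(chrom = chrom, start = starts,
             end = starts + config$window_size,
             n_inversions = n_inv, n_deletions = n_del,
             n_insertions = n_ins, n_cn_switches = n_sw,
             called = n_inv >= config$min_inversions &
               n_sw >= config$min_cn_switches &
               n_del >= config$min_deletions)
}

#' Chromosome-level chromothripsis call
#'
#' A chromosome is positive when at least one window meets all three
#' thresholds; overlapping called windows are merged into regions.
#'
#' @param window_counts output of [count_window_features] (one or more
#'   chromosomes row-bound).
#' @return list with `positive` (named logical per chromosome) and
#'   `regions` (merged called windows).
#' @export
call_chromothripsis <- function(window_counts) {
  called <- window_counts[window_counts$called, , drop = FALSE]
  chroms <- unique(window_counts$chrom)
  positive <- vapply(chroms, function(ch) any(called$chrom == ch),
                     logical(1))
  names(positive) <- chroms
  regions <- if (nrow(called)) {
    merge_intervals(called[, c("chrom", "start", "end")])
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  list(positive = positive, regions = regions)
}

#' Association between cSV class and chromothripsis at the chromosome level
#'
#' Builds the 2x2 table of (sample, chromosome) pairs cross-classified by
#' whether the chromosome harbors an ecDNA/BFB event and whether it was
#' called chromothriptic, and applies Fisher's exact test.
#'
#' @param events list of `amplicon_event` across the cohort.
#' @param chromothripsis_calls data.frame with sample_id, chrom, positive.
#' @return list with the table and the Fisher test result.
#' @export
csv_chromothripsis_association <- function(events, chromothripsis_calls) {
  if (!nrow(chromothripsis_calls)) stop("empty cohort")
  key <- paste(chromothripsis_calls$sample_id, chromothripsis_calls$chrom)
  has_csv <- vapply(key, function(k) FALSE, logical(1))
  for (e in events) {
    if (!(e$class %in% c("ecDNA", "BFB"))) next
    for (ch in unique(e$segments$chrom)) {
      has_csv[key == paste(e$sample_id, ch)] <- TRUE
    }
  }
  ct <- chromothripsis_calls$positive
  tab <- matrix(c(sum(has_csv & ct), sum(has_csv & !ct),
                  sum(!has_csv & ct), sum(!has_csv & !ct)),
                nrow = 2, byrow = TRUE,
                dimnames = list(csv = c("yes", "no"),
                                chromothripsis = c("yes", "no")))
  c(list(table = tab), fisher_exact_2x2(tab))
}
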