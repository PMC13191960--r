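#' Configuration for Hi-C evidence testing
#'
#' @param alpha BH-adjusted significance threshold for the support call.
#' @param bin_size working resolution in bp.
#' @param min_pairs_per_set minimum number of contact values a comparison
#'   set must contain for a segment to be testable.
#' @param distance_matching restrict the two projection sets to bin pairs
#'   whose genomic separations fall in the overlap of the sets' separation
#'   ranges, neutralizing distance decay (cis only).
#' @param require_direction additionally require the expected direction of
#'   the median difference (event lower than flank in cis; intra-event
#'   higher than background in trans) for a supported call.
#' @export
validation_config <- function(alpha = 0.05, bin_size = 10000,
                              min_pairs_per_set = 10,
                              distance_matching = TRUE,
                              require_direction = TRUE) {
  stopifnot(alpha > 0, alpha < 1, bin_size > 0, min_pairs_per_set >= 1)
  structure(list(alpha = alpha, bin_size = bin_size,
                 min_pairs_per_set = min_pairs_per_set,
                 distance_matching = distance_matching,
                 require_direction = require_direction),
            class = "validation_config")
}

#' Structural category of a cSV for Hi-C testing
#'
#' Category 1: a single segment on one chromosome; 2: multiple segments on
#' one chromosome; 3: segments from two chromosomes; 4: segments from more
#' than two chromosomes. Categories 1-2 are tested in cis, 3-4 in trans.
#'
#' @param event an `amplicon_event`.
#' @return integer in 1..4.
#' @export
classify_event_category <- function(event) {
  nchrom <- length(unique(event$segments$chrom))
  if (nchrom == 1) {
    if (nrow(event$segments) == 1) 1L else 2L
  } else if (nchrom == 2) 3L else 4L
}

# walk outward from a bin range collecting usable flank bins
collect_flank <- function(start_bin, step, n_want, chrom_lo, chrom_hi,
                          forbidden, mask) {
  out <- integer(0)
  b <- start_bin
  while (length(out) < n_want) {
    b <- b + step
    if (b < chrom_lo || b > chrom_hi) break
    if (b %in% forbidden || mask[b]) next
    out <- c(out, b)
  }
  out
}

#' Build event and flank bin sets for Hi-C testing
#'
#' For each event segment, defines upstream and downstream flanks of equal
#' bin length to the segment, walking outward and skipping past bins that
#' overlap any amplified segment of any event in the sample, and past masked
#' bins. Flanks truncated at a chromosome end are flagged. Per-chromosome
#' unions of event and flank bins are kept for trans testing.
#'
#' @param event the `amplicon_event` under test.
#' @param all_sample_events list of every `amplicon_event` in the same
#'   sample (including `event`); their bins are excluded from flanks.
#' @param bins a `genome_bins` (mask respected).
#' @param config a `validation_config`.
#' @return object of class `validation_regions`.
#' @export
build_validation_regions <- function(event, all_sample_events, bins,
                                     config = validation_config()) {
  forbidden <- unique(unlist(lapply(all_sample_events, function(e) {
    unlist(lapply(seq_len(nrow(e$segments)), function(k) {
      s <- e$segments[k, ]
      bins_for_interval(bins, s$chrom, s$start, s$end)
    }))
  })))
  seg_regions <- lapply(seq_len(nrow(event$segments)), function(k) {
    s <- event$segments[k, ]
    eb <- bins_for_interval(bins, s$chrom, s$start, s$end)
    eb <- eb[!bins$mask[eb]]
    cid <- chrom_id(bins, s$chrom)
    lo <- bins$offset[cid] + 1L
    hi <- bins$offset[cid] + bins$n_per_chrom[cid]
    n_want <- length(eb)
    all_eb <- bins_for_interval(bins, s$chrom, s$start, s$end)
    up <- collect_flank(min(all_eb), -1L, n_want, lo, hi, forbidden,
                        bins$mask)
    dn <- collect_flank(max(all_eb), +1L, n_want, lo, hi, forbidden,
                        bins$mask)
    list(chrom = s$chrom, interval = s[, c("chrom", "start", "end")],
         event_bins = eb, upstream = up, downstream = dn,
         truncated = length(up) < n_want || length(dn) < n_want)
  })
  chroms <- unique(event$segments$chrom)
  by_chrom <- lapply(chroms, function(ch) {
    sr <- seg_regions[vapply(seg_regions, function(r) r$chrom == ch,
                             logical(1))]
    list(chrom = ch,
         event_bins = sort(unique(unlist(lapply(sr, `[[`, "event_bins")))),
         flank_bins = sort(unique(unlist(lapply(sr, function(r) {
           c(r$upstream, r$downstream)
         })))))
  })
  names(by_chrom) <- chroms
  structure(list(event_id = event$event_id, segments = seg_regions,
                 by_chrom = by_chrom), class = "validation_regions")
}

#' Extract labeled contact-value sets for one segment
#'
#' Four sets drive the cis framework: WITHIN_EVENT (pairs inside the
#' segment), WITHIN_FLANK (pairs inside each flank, pooled),
#' EVENT_PROJECTION (segment x flank pairs) and FLANK_PROJECTION
#' (upstream x downstream pairs, which straddle the event at comparable
#' separations). With `distance_matching`, both projection sets are
#' restricted to the overlap of their genomic-separation ranges.
#'
#' @param cm a balanced `contact_matrix`.
#' @param regions a `validation_regions`.
#' @param segment segment index within the event.
#' @param config a `validation_config`.
#' @return list of numeric value sets plus `testable` flag and reason.
#' @export
extract_contact_sets <- function(cm, regions, segment,
                                 config = validation_config()) {
  r <- regions$segments[[segment]]
  eb <- r$event_bins
  fl <- c(r$upstream, r$downstream)
  we <- pair_values(cm, eb, eb, same_set = TRUE)
  wf <- rbind(pair_values(cm, r$upstream, r$upstream, same_set = TRUE),
              pair_values(cm, r$downstream, r$downstream, same_set = TRUE))
  ep <- pair_values(cm, eb, fl)
  fp <- pair_values(cm, r$upstream, r$downstream)
  if (config$distance_matching && nrow(ep) && nrow(fp)) {
    lo <- max(min(ep$sep), min(fp$sep))
    hi <- min(max(ep$sep), max(fp$sep))
    ep <- ep[ep$sep >= lo & ep$sep <= hi, , drop = FALSE]
    fp <- fp[fp$sep >= lo & fp$sep <= hi, , drop = FALSE]
  }
  sets <- list(within_event = we$value, within_flank = wf$value,
               event_projection = ep$value, flank_projection = fp$value)
  small <- names(sets)[vapply(sets, length, integer(1)) <
                         config$min_pairs_per_set]
  c(sets, list(
    testable = length(small) == 0,
    reason = if (length(small)) {
      paste("set(s) below min_pairs_per_set:", paste(small, collapse = ", "))
    } else NA_character_))
}

median_direction <- function(event_vals, ref_vals) {
  d <- stats::median(event_vals) - stats::median(ref_vals)
  if (d < 0) "event_lower" else if (d > 0) "event_higher" else "none"
}

finalize_evidence <- function(event, category, seg_results, config,
                              expected_direction, comparison_label) {
  testable <- !is.na(seg_results$p_value)
  if (!any(testable)) {
    supported <- NA
    reason <- "no testable segment"
    seg_results$p_adjusted <- NA_real_
  } else {
    seg_results$p_adjusted <- NA_real_
    seg_results$p_adjusted[testable] <- bh_adjust(seg_results$p_value[testable])
    hit <- testable & seg_results$p_adjusted < config$alpha
    if (config$require_direction) {
      hit <- hit & seg_results$direction == expected_direction
    }
    supported <- any(hit)
    reason <- if (supported) {
      paste0(sum(hit), " significant ", comparison_label,
             " comparison(s) at adjusted p < ", config$alpha)
    } else {
      paste0("no significant ", comparison_label,
             " comparison after BH correction")
    }
  }
  structure(list(event_id = event$event_id, sample_id = event$sample_id,
                 class = event$class, category = category,
                 segment_results = seg_results, supported = supported,
                 support_reason = reason, alpha = config$alpha),
            class = "event_evidence")
}

#' @export
print.event_evidence <- function(x, ...) {
  cat("event_evidence", x$event_id, "(", x$class, ", category", x$category,
      "): supported =", x$supported, "-", x$support_reason, "\n")
  invisible(x)
}

#' Cis Hi-C evidence test (single-chromosome cSVs)
#'
#' Per segment, compares EVENT_PROJECTION to FLANK_PROJECTION with a
#' two-sided Wilcoxon rank-sum test (the decisive comparison; an amplicon
#' detached from its chromosome shows depleted event-to-flank contact after
#' balancing), and WITHIN_EVENT to WITHIN_FLANK (reported only). P-values
#' are BH-adjusted across the event's segments; the event is supported when
#' at least one segment is significant at adjusted p < alpha (and, by
#' default, in the expected event-lower direction).
#'
#' @param event an `amplicon_event` of category 1 or 2.
#' @param cm a balanced `contact_matrix`.
#' @param regions `validation_regions` for the event.
#' @param config a `validation_config`.
#' @return an `event_evidence`.
#' @export
test_cis <- function(event, cm, regions, config = validation_config()) {
  category <- classify_event_category(event)
  stopifnot(category %in% 1:2)
  rows <- lapply(seq_along(regions$segments), function(k) {
    s <- extract_contact_sets(cm, regions, k, config)
    iv <- regions$segments[[k]]$interval
    if (!s$testable) {
      return(data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                        n_event_pairs = length(s$event_projection),
                        n_flank_pairs = length(s$flank_projection),
                        statistic = NA_real_, p_value = NA_real_,
                        p_secondary = NA_real_, direction = NA_character_,
                        reason = s$reason, stringsAsFactors = FALSE))
    }
    w <- wilcoxon_rank_sum(s$event_projection, s$flank_projection,
                           "two_sided")
    wi <- wilcoxon_rank_sum(s$within_event, s$within_flank, "two_sided")
    data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
               n_event_pairs = length(s$event_projection),
               n_flank_pairs = length(s$flank_projection),
               statistic = w$statistic, p_value = w$p_value,
               p_secondary = wi$p_value,
               direction = median_direction(s$event_projection,
                                            s$flank_projection),
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  finalize_evidence(event, category, do.call(rbind, rows), config,
                    "event_lower", "projection")
}

#' Trans Hi-C evidence test (multi-chromosome cSVs)
#'
#' For each chromosome pair contributing to the event, compares INTRA_CSV
#' (cross-chromosome contacts between event segments; the decisive
#' comparison, expected elevated for a trans amplicon) and CSV_OVERLAPPING
#' (event bins on one chromosome x partner flank bins; reported) against
#' NON_OVERLAPPING (flank x partner flank background). BH across the
#' event's chromosome-pair comparisons; supported when at least one
#' decisive comparison is significant at adjusted p < alpha.
#'
#' @inheritParams test_cis
#' @param event an `amplicon_event` of category 3 or 4.
#' @return an `event_evidence`.
#' @export
test_trans <- function(event, cm, regions, config = validation_config()) {
  category <- classify_event_category(event)
  stopifnot(category %in% 3:4)
  chroms <- names(regions$by_chrom)
  pairs <- utils::combn(chroms, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- regions$by_chrom[[pr[1]]]; b <- regions$by_chrom[[pr[2]]]
    intra <- pair_values(cm, a$event_bins, b$event_bins)$value
    nonov <- pair_values(cm, a$flank_bins, b$flank_bins)$value
    csvov <- c(pair_values(cm, a$event_bins, b$flank_bins)$value,
               pair_values(cm, a$flank_bins, b$event_bins)$value)
    base <- data.frame(chrom = paste(pr, collapse = "|"), start = NA_real_,
                       end = NA_real_, n_event_pairs = length(intra),
                       n_flank_pairs = length(nonov), stringsAsFactors = FALSE)
    if (length(intra) < config$min_pairs_per_set ||
        length(nonov) < config$min_pairs_per_set) {
      return(cbind(base, data.frame(
        statistic = NA_real_, p_value = NA_real_, p_secondary = NA_real_,
        direction = NA_character_,
        reason = "too few trans contact values", stringsAsFactors = FALSE)))
    }
    w <- wilcoxon_rank_sum(intra, nonov, "two_sided")
    wo <- if (length(csvov) >= config$min_pairs_per_set) {
      wilcoxon_rank_sum(csvov, nonov, "two_sided")$p_value
    } else NA_real_
    cbind(base, data.frame(
      statistic = w$statistic, p_value = w$p_value, p_secondary = wo,
      direction = median_direction(intra, nonov),
      reason = NA_character_, stringsAsFactors = FALSE))
  })
  finalize_evidence(event, category, do.call(rbind, rows), config,
                    "event_higher", "intra-cSV vs non-overlapping")
}

#' Run the appropriate Hi-C evidence test on every event of a sample
#'
#' Balances the matrix if raw, builds validation regions, and dispatches
#' category 1-2 events to [test_cis] and category 3-4 events to
#' [test_trans].
#'
#' @param events list of `amplicon_event` (one sample).
#' @param cm a `contact_matrix` (raw or balanced).
#' @param config a `validation_config`.
#' @return list of `event_evidence`.
#' @export
validate_events <- function(events, cm, config = validation_config()) {
  if (!cm$balanced) cm <- iterative_correction(cm)
  lapply(events, function(e) {
    regions <- build_validation_regions(e, events, cm$bins, config)
    if (classify_event_category(e) <= 2) {
      test_cis(e, cm, regions, config)
    } else {
      test_trans(e, cm, regions, config)
    }
  })
}

#' Cohort-level summary of Hi-C support
#'
#' Computes the fraction of testable events supported (overall and by
#' class) and Kruskal-Wallis tests of tumor purity and event-weighted copy
#' number between supported and unsupported events.
#'
#' @param evidences list of `event_evidence`.
#' @param purities numeric, tumor purity per event (sample-level purity
#'   repeated across the sample's events).
#' @param event_weighted_cn numeric, length-weighted mean CN per event.
#' @return list with counts, fractions, and the two association tests
#'   (`NA` when only one support group is present).
#' @export
summarize_support <- function(evidences, purities = NULL,
                              event_weighted_cn = NULL) {
  stopifnot(length(evidences) >= 1)
  supported <- vapply(evidences, `[[`, logical(1), "supported")
  classes <- vapply(evidences, `[[`, character(1), "class")
  testable <- !is.na(supported)
  frac <- function(s) if (length(s)) mean(s) else NA_real_
  by_class <- tapply(supported[testable], classes[testable], frac)
  kw <- function(x) {
    if (is.null(x)) return(NULL)
    g <- split(x[testable], supported[testable])
    if (length(g) < 2 || any(lengths(g) == 0)) return(NA)
    kruskal_wallis(unname(g))
  }
  list(n_events = length(evidences), n_testable = sum(testable),
       n_supported = sum(supported[testable]),
       fraction_supported = frac(supported[testable]),
       fraction_by_class = by_class,
       purity_test = kw(purities),
       weighted_cn_test = kw(event_weighted_cn))
}
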