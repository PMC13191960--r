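#' Jaccard index of two genomic interval sets
#'
#' bp(A intersect B) / bp(A union B) after self-merging each set, so the
#' measure is invariant to how a region is segmented.
#'
#' @param a,b data.frames with chrom, start, end (0-based half-open).
#' @return value in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  if (!nrow(a) && !nrow(b)) stop("both interval sets are empty")
  inter <- intervals_intersect_bp(a, b)
  uni <- intervals_bp(rbind(a[, c("chrom", "start", "end")],
                            b[, c("chrom", "start", "end")]))
  if (uni == 0) 0 else inter / uni
}

#' Breakpoint Jaccard index
#'
#' Two breakpoints match when they share the chromosome pair and strand
#' pair and both breakend positions lie within `tol_bp`. Matching is
#' maximal one-to-one, greedy by total breakend distance with deterministic
#' ties (smaller coordinates first). Jaccard = matched / (|A| + |B| -
#' matched).
#'
#' @param bp_a,bp_b `breakpoints` data.frames (canonical order).
#' @param tol_bp positional tolerance in bp.
#' @return list with jaccard and n_matched.
#' @export
breakpoint_jaccard <- function(bp_a, bp_b, tol_bp = 100) {
  na <- nrow(bp_a); nb <- nrow(bp_b)
  if (na == 0 && nb == 0) return(list(jaccard = 1, n_matched = 0L))
  if (na == 0 || nb == 0) return(list(jaccard = 0, n_matched = 0L))
  cand <- expand.grid(a = seq_len(na), b = seq_len(nb))
  A <- bp_a[cand$a, ]; B <- bp_b[cand$b, ]
  ok <- A$chrom1 == B$chrom1 & A$chrom2 == B$chrom2 &
    A$strand1 == B$strand1 & A$strand2 == B$strand2 &
    abs(A$pos1 - B$pos1) <= tol_bp & abs(A$pos2 - B$pos2) <= tol_bp
  cand <- cand[ok, , drop = FALSE]
  dist <- abs(bp_a$pos1[cand$a] - bp_b$pos1[cand$b]) +
    abs(bp_a$pos2[cand$a] - bp_b$pos2[cand$b])
  o <- order(dist, bp_a$pos1[cand$a], bp_b$pos1[cand$b], cand$a, cand$b)
  cand <- cand[o, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb); matched <- 0L
  for (k in seq_len(nrow(cand))) {
    ia <- cand$a[k]; ib <- cand$b[k]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      matched <- matched + 1L
    }
  }
  list(jaccard = matched / (na + nb - matched), n_matched = matched)
}

#' Classify cross-sample cSV pairs as shared or independent
#'
#' Scores every pair of events from different samples whose segment sets
#' overlap a common locus: breakpoint Jaccard at `tol_bp` plus interval
#' Jaccard. Verdict is "shared" when breakpoint Jaccard >= theta_shared,
#' "independent" when the loci overlap but breakpoint Jaccard <=
#' theta_indep, else "indeterminate".
#'
#' @param patient_events named list: one list of `amplicon_event` per
#'   sample.
#' @param tol_bp breakpoint matching tolerance.
#' @param theta_shared,theta_indep verdict thresholds.
#' @return data.frame, one row per overlapping cross-sample event pair.
#' @export
convergence_classify <- function(patient_events, tol_bp = 100,
                                 theta_shared = 0.25, theta_indep = 0.05) {
  samples <- names(patient_events)
  out <- list()
  if (length(samples) < 2) {
    return(data.frame(sample_a = character(), event_a = character(),
                      sample_b = character(), event_b = character(),
                      interval_jaccard = numeric(),
                      breakpoint_jaccard = numeric(),
                      n_matched_breakpoints = integer(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  for (i in seq_len(length(samples) - 1)) {
    for (j in seq(i + 1, length(samples))) {
      for (ea in patient_events[[i]]) {
        for (eb in patient_events[[j]]) {
          ij <- interval_jaccard(ea$segments, eb$segments)
          if (ij == 0) next
          bj <- if (!is.null(ea$junctions) && !is.null(eb$junctions)) {
            breakpoint_jaccard(ea$junctions, eb$junctions, tol_bp)
          } else {
            list(jaccard = NA_real_, n_matched = NA_integer_)
          }
          verdict <- if (is.na(bj$jaccard)) "indeterminate"
            else if (bj$jaccard >= theta_shared) "shared"
            else if (bj$jaccard <= theta_indep) "independent"
            else "indeterminate"
          out[[length(out) + 1]] <- data.frame(
            sample_a = samples[i], event_a = ea$event_id,
            sample_b = samples[j], event_b = eb$event_id,
            interval_jaccard = ij, breakpoint_jaccard = bj$jaccard,
            n_matched_breakpoints = bj$n_matched, verdict = verdict,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
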