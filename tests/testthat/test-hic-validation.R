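test_that("iterative correction equalizes marginals, stores bias, is idempotent", {
  b <- genome_bins(c(chr1 = 2e4), 1e4)
  cm <- contact_matrix(b, c(1, 1, 2), c(1, 2, 2), c(4, 2, 1))
  bal <- iterative_correction(cm)
  rs <- Matrix::rowSums(bal$mat)
  expect_true(bal$balanced)
  expect_lt(diff(range(rs)), 1e-5 * mean(rs))
  # oracle: explicit alternating scaling to convergence
  M <- matrix(c(4, 2, 2, 1), 2)
  bias <- c(1, 1)
  for (it in 1:500) {
    s <- rowSums(M); d <- s / mean(s)
    M <- M / outer(d, d); bias <- bias * d
  }
  M <- M * mean(Matrix::rowSums(cm$mat)) / mean(rowSums(M))
  expect_equal(as.matrix(bal$mat), M, tolerance = 1e-4,
               ignore_attr = TRUE)
  # fixed point: balancing a balanced matrix changes nothing
  bal2 <- iterative_correction(bal)
  expect_lt(max(abs(bal2$mat - bal$mat)), 1e-4)
  # all-zero row is masked and excluded from the criterion
  cm3 <- contact_matrix(genome_bins(c(chr1 = 3e4), 1e4),
                        c(1, 1, 2), c(1, 2, 2), c(4, 2, 1))
  expect_true(cm3$bins$mask[3])
  bal3 <- iterative_correction(cm3)
  expect_true(bal3$balanced)
  expect_true(bal3$bins$mask[3])
})

test_that("event categories follow the segment/chromosome count definition", {
  e1 <- amplicon_event("a", "s", "ecDNA",
                       data.frame(chrom = "chrX", start = 0, end = 1e4,
                                  copy_number = 5))
  e2 <- amplicon_event("b", "s", "ecDNA",
                       data.frame(chrom = "chr8", start = c(0, 2e4, 5e4),
                                  end = c(1e4, 3e4, 6e4), copy_number = 5))
  e3 <- amplicon_event("c", "s", "ecDNA",
                       data.frame(chrom = c("chr18", "chrX"),
                                  start = c(0, 0), end = c(1e4, 1e4),
                                  copy_number = 5))
  e4 <- amplicon_event("d", "s", "ecDNA",
                       data.frame(chrom = c("chr1", "chr2", "chr3"),
                                  start = 0, end = 1e4, copy_number = 5))
  expect_equal(classify_event_category(e1), 1L)
  expect_equal(classify_event_category(e2), 2L)
  expect_equal(classify_event_category(e3), 3L)
  expect_equal(classify_event_category(e4), 4L)
})

test_that("validation regions give equal-length flanks that avoid all events", {
  bins <- genome_bins(c(chrA = 1e6), 1e4)
  ev <- amplicon_event("e", "s", "ecDNA",
                       data.frame(chrom = "chrA", start = 5e5, end = 6e5,
                                  copy_number = 10))
  r <- build_validation_regions(ev, list(ev), bins)
  seg <- r$segments[[1]]
  expect_length(seg$event_bins, 10)
  expect_length(seg$upstream, 10)
  expect_length(seg$downstream, 10)
  expect_false(seg$truncated)
  expect_length(intersect(c(seg$upstream, seg$downstream), seg$event_bins), 0)
  # segment 5 bins from the chromosome start: upstream truncated
  ev2 <- amplicon_event("e2", "s", "ecDNA",
                        data.frame(chrom = "chrA", start = 5e4, end = 1.5e5,
                                   copy_number = 10))
  r2 <- build_validation_regions(ev2, list(ev2), bins)
  expect_length(r2$segments[[1]]$upstream, 5)
  expect_true(r2$segments[[1]]$truncated)
  # neighboring event overlapping the default upstream flank: skipped past
  nb <- amplicon_event("nb", "s", "ecDNA",
                       data.frame(chrom = "chrA", start = 4.4e5, end = 4.7e5,
                                  copy_number = 8))
  r3 <- build_validation_regions(ev, list(ev, nb), bins)
  up <- r3$segments[[1]]$upstream
  expect_length(up, 10)
  nb_bins <- bins_for_interval(bins, "chrA", 4.4e5, 4.7e5)
  expect_length(intersect(up, nb_bins), 0)
  expect_length(intersect(up, r3$segments[[1]]$event_bins), 0)
})

test_that("flank bins never intersect any event bins across random layouts", {
  bins <- genome_bins(c(chrA = 2e6), 1e4)
  set.seed(31)
  for (rep in 1:10) {
    starts <- sort(sample(seq(1e5, 1.7e6, by = 1e4), 3))
    evs <- lapply(seq_along(starts), function(k) {
      amplicon_event(paste0("e", k), "s", "ecDNA",
                     data.frame(chrom = "chrA", start = starts[k],
                                end = starts[k] + sample(3:8, 1) * 1e4,
                                copy_number = 10))
    })
    all_bins <- unlist(lapply(evs, function(e) {
      bins_for_interval(bins, "chrA", e$segments$start, e$segments$end)
    }))
    for (e in evs) {
      r <- build_validation_regions(e, evs, bins)
      fl <- unlist(lapply(r$segments, function(s) c(s$upstream, s$downstream)))
      expect_length(intersect(fl, all_bins), 0)
    }
  }
})

test_that("contact sets have the expected combinatorial sizes", {
  bins <- genome_bins(c(chrA = 2e5), 1e4)
  n <- bins$n_bins
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  cm <- contact_matrix(bins, idx[, 1], idx[, 2], rep(5, nrow(idx)),
                       balanced = TRUE)
  ev <- amplicon_event("e", "s", "ecDNA",
                       data.frame(chrom = "chrA", start = 9e4, end = 1.2e5,
                                  copy_number = 4))
  r <- build_validation_regions(ev, list(ev), bins)
  cfg <- validation_config(distance_matching = FALSE, min_pairs_per_set = 1)
  s <- extract_contact_sets(cm, r, 1, cfg)
  expect_length(s$event_projection, 3 * 6)
  expect_length(s$flank_projection, 9)
  expect_length(s$within_event, 3)
  expect_length(s$within_flank, 6)
  # degenerate uniform matrix: all sets constant
  expect_true(all(unlist(s[1:4]) == 5))
})

test_that("cis test supports a simulated ecDNA with the event-lower signature", {
  ev <- fix_cis_event()
  sc <- sim_scenario(c(chrA = 2e6), list(ev), purity = 0.7, seed = 42)
  cm <- simulate_hic(sc)
  evid <- validate_events(list(ev), cm)[[1]]
  expect_true(evid$supported)
  expect_equal(evid$segment_results$direction, "event_lower")
  expect_lt(evid$segment_results$p_adjusted, 0.05)
})

test_that("support decision is recomputable from stored segment results", {
  ev <- fix_cis_event()
  sc <- sim_scenario(c(chrA = 2e6), list(ev), purity = 0.7, seed = 42)
  evid <- validate_events(list(ev), simulate_hic(sc))[[1]]
  sr <- evid$segment_results
  recomputed <- any(!is.na(sr$p_adjusted) & sr$p_adjusted < evid$alpha &
                      sr$direction == "event_lower")
  expect_identical(recomputed, evid$supported)
})

test_that("trans test supports a simulated two-chromosome ecDNA", {
  ev <- fix_trans_event()
  sc <- sim_scenario(c(chrA = 2e6, chrB = 1.5e6), list(ev), purity = 0.7,
                     seed = 7)
  evid <- validate_events(list(ev), simulate_hic(sc))[[1]]
  expect_equal(evid$category, 3L)
  expect_true(evid$supported)
  expect_equal(evid$segment_results$direction, "event_higher")
})

test_that("events with no usable flank or trans space come back untestable", {
  # event covering the whole (tiny) chromosome: zero flank bins
  bins_len <- c(chrA = 3e5)
  ev <- amplicon_event("full", "s", "ecDNA",
                       data.frame(chrom = "chrA", start = 0, end = 3e5,
                                  copy_number = 10))
  sc <- sim_scenario(bins_len, list(), purity = 0.7, seed = 2)
  cm <- iterative_correction(simulate_hic(sc))
  r <- build_validation_regions(ev, list(ev), cm$bins)
  evid <- test_cis(ev, cm, r)
  expect_true(is.na(evid$supported))
  expect_match(evid$support_reason, "no testable segment")
})

test_that("per-event false-support rate under the null stays at or below alpha", {
  set.seed(810)
  supp <- logical(0)
  for (r in 1:20) {
    scn <- sim_scenario(c(chrA = 5e6), list(), purity = 0.7, seed = 9000 + r)
    cmb <- iterative_correction(simulate_hic(scn))
    evs <- lapply(1:5, function(k) {
      amplicon_event(paste0("n", k), "s", "ecDNA",
                     data.frame(chrom = "chrA", start = (k - 1) * 9.6e5 + 3e5,
                                end = (k - 1) * 9.6e5 + 4e5, copy_number = 10))
    })
    for (e in evs) {
      rg <- build_validation_regions(e, evs, cmb$bins)
      supp <- c(supp, isTRUE(test_cis(e, cmb, rg)$supported))
    }
  }
  n <- length(supp)
  expect_gte(n, 100)
  # rate <= alpha within binomial 99% CI
  expect_lte(sum(supp), qbinom(0.995, n, 0.05))
})

test_that("support rate rises with amplification factor and purity", {
  rate <- function(amp, purity, n_rep = 15) {
    mean(vapply(seq_len(n_rep), function(r) {
      ev <- fix_cis_event(amp = amp)
      sc <- sim_scenario(c(chrA = 2e6), list(ev), purity = purity,
                         seed = 7000 + 97 * r + round(100 * amp + purity * 10))
      isTRUE(validate_events(list(ev), simulate_hic(sc))[[1]]$supported)
    }, logical(1)))
  }
  r_amp <- c(rate(2, 0.7), rate(5, 0.7), rate(10, 0.7))
  expect_true(all(diff(r_amp) >= 0))
  expect_gte(r_amp[3], 0.9)
  r_pur <- c(rate(10, 0.3), rate(10, 0.5), rate(10, 0.9))
  expect_true(all(diff(r_pur) >= 0))
})

test_that("cohort summary reports support fractions and associations", {
  mk_ev <- function(id, supported) {
    structure(list(event_id = id, sample_id = "s", class = "ecDNA",
                   category = 1L, segment_results = NULL,
                   supported = supported, support_reason = "",
                   alpha = 0.05), class = "event_evidence")
  }
  evid <- lapply(1:4, function(k) mk_ev(paste0("e", k), k <= 3))
  s <- summarize_support(evid)
  expect_equal(s$fraction_supported, 0.75)
  # degenerate: all supported -> association not computable
  evid2 <- lapply(1:4, function(k) mk_ev(paste0("e", k), TRUE))
  s2 <- summarize_support(evid2, purities = runif(4))
  expect_true(is.na(s2$purity_test) || is.null(s2$purity_test))
  # power: support probability increasing with purity is detected
  set.seed(55)
  n <- 200
  pur <- runif(n, 0.2, 0.9)
  supp <- rbinom(n, 1, plogis(6 * (pur - 0.5))) == 1
  evid3 <- lapply(seq_len(n), function(k) mk_ev(paste0("e", k), supp[k]))
  s3 <- summarize_support(evid3, purities = pur)
  expect_lt(s3$purity_test$p_value, 0.05)
})
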