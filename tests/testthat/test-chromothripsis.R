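test_that("the threshold boundary calls exactly as printed", {
  # generator guarantees the requested counts land in the region
  at <- simulate_chromothripsis("chr5", c(2e6, 4.5e6), 15, 10, 15,
                                chrom_length = 6e6, seed = 3)
  w <- count_window_features(at$breakpoints, at$segments, "chr5")
  expect_true(any(w$called))
  expect_equal(max(w$n_inversions), 15)
  expect_equal(max(w$n_deletions), 10)
  expect_equal(max(w$n_cn_switches), 15)
  # decrementing any one count drops the call
  for (dec in list(c(14, 10, 15), c(15, 9, 15), c(15, 10, 14))) {
    a <- simulate_chromothripsis("chr5", c(2e6, 4.5e6), dec[1], dec[2],
                                 dec[3], chrom_length = 6e6, seed = 3)
    w <- count_window_features(a$breakpoints, a$segments, "chr5")
    expect_false(any(w$called))
  }
})

test_that("empty chromosomes produce no called windows", {
  bp <- structure(data.frame(chrom1 = character(), pos1 = numeric(),
                             strand1 = character(), chrom2 = character(),
                             pos2 = numeric(), strand2 = character(),
                             name = character(), sv_type = character(),
                             stringsAsFactors = FALSE),
                  class = c("breakpoints", "data.frame"))
  seg <- cn_segments(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                copy_number = 2))
  w <- count_window_features(bp, seg, "chr1")
  expect_false(any(w$called))
})

test_that("SV counting requires both breakends inside the window and counts are monotone", {
  cfg <- chromothripsis_config()
  mk <- function(p1, p2, type) {
    bp <- data.frame(chrom1 = "chr1", pos1 = p1, strand1 = "+",
                     chrom2 = "chr1", pos2 = p2, strand2 = "+",
                     name = "x", sv_type = type, stringsAsFactors = FALSE)
    class(bp) <- c("breakpoints", "data.frame")
    bp
  }
  seg <- cn_segments(data.frame(chrom = "chr1", start = 0, end = 1e7,
                                copy_number = 2))
  # INV spanning beyond any single window never counts
  wide <- mk(1e5, 1e5 + cfg$window_size + 1e4, "INV")
  w <- count_window_features(wide, seg, "chr1", cfg)
  expect_equal(max(w$n_inversions), 0)
  inside <- mk(1e5, 2e5, "INV")
  w2 <- count_window_features(inside, seg, "chr1", cfg)
  expect_equal(max(w2$n_inversions), 1)
  # adding a breakpoint never decreases any window's count
  more <- rbind(inside, mk(1.5e5, 2.5e5, "INV"))
  class(more) <- c("breakpoints", "data.frame")
  w3 <- count_window_features(more, seg, "chr1", cfg)
  shared <- intersect(w2$start, w3$start)
  expect_true(all(w3$n_inversions[match(shared, w3$start)] >=
                    w2$n_inversions[match(shared, w2$start)]))
})

test_that("window counts are invariant to translation by whole steps", {
  cfg <- chromothripsis_config()
  shift <- 25 * cfg$step
  a <- simulate_chromothripsis("chr2", c(2e6, 4.5e6), 5, 4, 6,
                               chrom_length = 1e7, seed = 8)
  bp2 <- a$breakpoints
  bp2$pos1 <- bp2$pos1 + shift
  bp2$pos2 <- bp2$pos2 + shift
  seg2 <- as.data.frame(a$segments)
  seg2$start <- c(0, seg2$start[-1] + shift)
  seg2$end <- c(seg2$end[-nrow(seg2)] + shift, 1e7 + shift)
  seg2 <- cn_segments(seg2)
  w1 <- count_window_features(a$breakpoints, a$segments, "chr2", cfg)
  w2 <- count_window_features(bp2, seg2, "chr2", cfg)
  m <- match(w1$start + shift, w2$start)
  keep <- !is.na(m)
  expect_true(any(keep))
  for (col in c("n_inversions", "n_deletions", "n_cn_switches")) {
    expect_equal(w2[[col]][m[keep]], w1[[col]][keep])
  }
})

test_that("called flag is recomputable and overlapping windows merge", {
  a <- simulate_chromothripsis("chr3", c(1e6, 4e6), 20, 12, 20,
                               chrom_length = 5e6, seed = 4)
  cfg <- chromothripsis_config()
  w <- count_window_features(a$breakpoints, a$segments, "chr3", cfg)
  expect_equal(w$called,
               w$n_inversions >= cfg$min_inversions &
                 w$n_cn_switches >= cfg$min_cn_switches &
                 w$n_deletions >= cfg$min_deletions)
  call <- call_chromothripsis(w)
  expect_true(call$positive[["chr3"]])
  # consecutive called windows overlap (step << window) -> merged regions
  expect_lt(nrow(call$regions), sum(w$called))
})

test_that("chromosome-level cSV association recovers a planted dependence", {
  mk_event <- function(sample, chrom) {
    amplicon_event(paste0(sample, chrom), sample, "ecDNA",
                   data.frame(chrom = chrom, start = 0, end = 1e5,
                              copy_number = 10))
  }
  # perfectly concordant cohort: ecDNA chromosome == chromothriptic one
  calls <- expand.grid(sample_id = paste0("s", 1:10),
                       chrom = paste0("chr", 1:2),
                       stringsAsFactors = FALSE)
  calls$positive <- calls$chrom == "chr1"
  events <- lapply(paste0("s", 1:10), mk_event, chrom = "chr1")
  res <- csv_chromothripsis_association(events, calls)
  expect_equal(res$table["yes", "yes"], 10)
  expect_equal(res$table["no", "no"], 10)
  expect_lt(res$p_value, 0.001)
  # single (sample, chromosome) pair: degenerate margin -> p = 1
  res1 <- csv_chromothripsis_association(events[1], calls[1, ])
  expect_equal(res1$p_value, 1)
  expect_error(csv_chromothripsis_association(events, calls[0, ]), "empty")
})

test_that("association p-values are roughly uniform under independence", {
  set.seed(17)
  ps <- replicate(200, {
    calls <- data.frame(sample_id = rep(paste0("s", 1:20), each = 2),
                        chrom = rep(c("chr1", "chr2"), 20),
                        positive = runif(40) < 0.4)
    events <- lapply(which(runif(40) < 0.4), function(k) {
      amplicon_event(paste0("e", k), calls$sample_id[k], "ecDNA",
                     data.frame(chrom = calls$chrom[k], start = 0,
                                end = 1e5, copy_number = 8))
    })
    csv_chromothripsis_association(events, calls)$p_value
  })
  # exact-test p-values are super-uniform; check no excess of small ones
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps), 0.3)
})
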