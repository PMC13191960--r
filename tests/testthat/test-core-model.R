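test_that("genome bins tile chromosomes with a short last bin and map both ways", {
  b <- genome_bins(c(chr1 = 25000, chr2 = 10000), 10000)
  expect_equal(b$n_bins, 4)
  iv <- bin_interval(b, 1:4)
  expect_equal(iv$end - iv$start, c(10000, 10000, 5000, 10000))
  expect_equal(bin_index(b, "chr2", 0), 4)
  expect_equal(bin_index(b, "chr1", 24999), 3)
  expect_equal(bins_for_interval(b, "chr1", 5000, 15000), c(1, 2))
  expect_error(bin_index(b, "chr3", 0), "unknown chromosome")
})

test_that("purple_tsv segments convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c("#purity=0.6", "#ploidy=3.1",
               "chromosome\tstart\tend\tcopyNumber",
               "chr1\t1001\t2000\t3.2"), f)
  s <- read_copy_segments(f, "purple_tsv", sample_id = "a")
  expect_equal(s$start, 1000)
  expect_equal(s$end, 2000)
  expect_equal(s$copy_number, 3.2)
  expect_equal(attr(s, "purity"), 0.6)
  expect_equal(attr(s, "ploidy"), 3.1)
})

test_that("bed segments are taken as-is and overlaps are rejected", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t100\t2.0", f)
  s <- read_copy_segments(f, "bed")
  expect_equal(s$start, 0)
  expect_equal(s$end, 100)
  expect_error(
    cn_segments(data.frame(chrom = "chr1", start = c(0, 50),
                           end = c(100, 150), copy_number = 2)),
    "overlap")
})

test_that("segment round-trip through purple_tsv is exact", {
  s <- cn_segments(data.frame(chrom = c("chr1", "chr1", "chr2"),
                              start = c(0, 1500, 0),
                              end = c(1500, 9000, 400),
                              copy_number = c(2, 3.1415926, 0.5)),
                   sample_id = "rt", purity = 0.55, ploidy = 2.7)
  f <- withr::local_tempfile()
  write_copy_segments(s, f)
  s2 <- read_copy_segments(f, "purple_tsv", sample_id = "rt")
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_equal(attr(s2, "purity"), 0.55)
  expect_equal(attr(s2, "ploidy"), 2.7)
})

test_that("BEDPE breakpoints canonicalize and infer SV type from strands", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\t101\tchr1\t5000\t5001\tb1\t.\t+\t-",
    "chr1\t100\t101\tchr2\t200\t201\tb2\t.\t+\t+",
    "chr2\t300\t301\tchr1\t900\t901\tb3\t.\t-\t+",
    "chr1\t40\t41\tchr1\t70\t71\tb4\t.\t-\t-"), f)
  bp <- read_breakpoints(f)
  expect_equal(bp$sv_type, c("DEL", "TRA", "TRA", "INV"))
  # unordered pair stored with the smaller locus first
  expect_equal(bp$chrom1[3], "chr1")
  expect_equal(bp$pos1[3], 900)
  expect_equal(bp$strand1[3], "+")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t1\t2\tchr1\t9\t10\tb\t.\t+\t?", f2)
  expect_error(read_breakpoints(f2), "strand")
})

test_that("breakpoint round-trip preserves positions, strands and types", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t101\tchr1\t5000\t5001\tb1\t.\t+\t-",
               "chr1\t10\t11\tchr3\t99\t100\tb2\t.\t-\t-"), f)
  bp <- read_breakpoints(f)
  f2 <- withr::local_tempfile()
  write_breakpoints(bp, f2)
  bp2 <- read_breakpoints(f2)
  expect_equal(bp2, bp)
})

test_that("contact matrix is symmetric, masks empty bins, enforces dialect", {
  b <- genome_bins(c(chr1 = 30000), 10000)
  fb <- withr::local_tempfile(); fp <- withr::local_tempfile()
  writeLines(c("chrom\tstart\tend", "chr1\t0\t10000", "chr1\t10000\t20000",
               "chr1\t20000\t30000"), fb)
  writeLines(c("bin1_id\tbin2_id\tcount", "0\t0\t4", "0\t1\t2"), fp)
  cm <- read_contact_matrix(fb, fp, b)
  expect_equal(contact_value(cm, 2, 1), 2)
  expect_equal(contact_value(cm, 1, 2), 2)
  # bin 3 has no pixels anywhere -> masked
  expect_true(cm$bins$mask[3])
  expect_true(is.na(contact_value(cm, 1, 3)))
  writeLines(c("bin1_id\tbin2_id\tcount", "2\t1\t5"), fp)
  expect_error(read_contact_matrix(fb, fp, b), "bin1_id <= bin2_id")
  writeLines(c("bin1_id\tbin2_id\tcount", "0\t9\t5"), fp)
  expect_error(read_contact_matrix(fb, fp, b), "out of range")
  writeLines(c("bin1_id\tbin2_id\tcount", "0\t1\t-2"), fp)
  expect_error(read_contact_matrix(fb, fp, b), "negative")
})

test_that("contact matrix round-trips through bins+pixels files", {
  b <- genome_bins(c(chrA = 5e4, chrB = 3e4), 10000)
  cm <- contact_matrix(b, c(1, 1, 2, 6, 3), c(1, 2, 5, 7, 8),
                       c(4, 2, 7, 1, 3))
  fb <- withr::local_tempfile(); fp <- withr::local_tempfile()
  write_contact_matrix(cm, fb, fp)
  cm2 <- read_contact_matrix(fb, fp, genome_bins(c(chrA = 5e4, chrB = 3e4),
                                                 10000))
  expect_equal(as.matrix(cm2$mat), as.matrix(cm$mat))
  expect_equal(cm2$bins$mask, cm$bins$mask)
})

test_that("event reader groups segments, validates class, deduplicates", {
  f <- withr::local_tempfile()
  writeLines(c("sample_id\tevent_id\tclass\tchrom\tstart\tend\tcopy_number",
               "s1\te1\tecDNA\tchr18\t1000\t2000\t12",
               "s1\te1\tecDNA\tchrX\t5000\t9000\t12",
               "s1\te2\tBFB\tchr8\t0\t500\t30",
               "s1\te2\tBFB\tchr8\t0\t500\t30"), f)
  expect_warning(ev <- read_events(f), "duplicate")
  expect_length(ev, 2)
  expect_equal(nrow(ev[[1]]$segments), 2)
  expect_equal(sort(unique(ev[[1]]$segments$chrom)), c("chr18", "chrX"))
  expect_equal(nrow(ev[[2]]$segments), 1)
  writeLines(c("sample_id\tevent_id\tclass\tchrom\tstart\tend\tcopy_number",
               "s1\te1\tcircle\tchr1\t0\t10\t2"), f)
  expect_error(read_events(f), "ecDNA, BFB, CNC, unknown, linear")
})

test_that("event writer round-trips with the reader", {
  ev <- list(fix_cis_event(), fix_trans_event())
  f <- withr::local_tempfile()
  write_events(ev, f)
  ev2 <- read_events(f)
  expect_equal(ev2[[1]]$segments, ev[[1]]$segments)
  expect_equal(ev2[[2]]$segments, ev[[2]]$segments)
  expect_equal(vapply(ev2, `[[`, character(1), "class"),
               vapply(ev, `[[`, character(1), "class"),
               ignore_attr = TRUE)
})

test_that("mutation matrix round-trips and rejects non-binary entries", {
  m <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L), 2, 3,
              dimnames = list(c("s1", "s2"), c("v1", "v2", "v3")))
  f <- withr::local_tempfile()
  write_mutation_matrix(m, f)
  expect_equal(read_mutation_matrix(f), m)
  writeLines(c("sample_id\tv1", "s1\t2"), f)
  expect_error(read_mutation_matrix(f), "0/1")
})
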