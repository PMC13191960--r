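#' Read absolute copy-number segments
#'
#' Two dialects are supported. `purple_tsv` is a PURPLE-style TSV with header
#' columns `chromosome`, `start`, `end`, `copyNumber`, where `start` is
#' 1-based inclusive; sample purity and ploidy are read from `#purity=` /
#' `#ploidy=` comment lines at the top of the file (or supplied as
#' arguments). `bed` is 0-based half-open with columns chrom, start, end, CN
#' and no header. Internally everything is 0-based half-open.
#'
#' @param path file path.
#' @param dialect `"purple_tsv"` or `"bed"`.
#' @param sample_id sample identifier.
#' @param purity,ploidy overrides for the sidecar header values.
#' @return an object of class `cn_segments`: data.frame of segments plus
#'   `sample_id`, `purity`, `ploidy` attributes.
#' @export
read_copy_segments <- function(path, dialect = c("purple_tsv", "bed"),
                               sample_id = "sample", purity = NULL,
                               ploidy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    kv <- sub("^#", "", h)
    if (grepl("^purity=", kv) && is.null(purity)) {
      purity <- as.numeric(sub("^purity=", "", kv))
    }
    if (grepl("^ploidy=", kv) && is.null(ploidy)) {
      ploidy <- as.numeric(sub("^ploidy=", "", kv))
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (dialect == "purple_tsv") {
    d <- tryCatch(
      utils::read.table(text = body, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) stop("malformed segment table: ", conditionMessage(e)))
    need <- c("chromosome", "start", "end", "copyNumber")
    if (!all(need %in% names(d))) {
      stop("purple_tsv needs columns: ", paste(need, collapse = ", "))
    }
    seg <- data.frame(chrom = d$chromosome, start = d$start - 1,
                      end = d$end, copy_number = d$copyNumber,
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(text = body, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("bed dialect needs 4 columns: chrom start end CN")
    seg <- data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]],
                      copy_number = as.numeric(d[[4]]),
                      stringsAsFactors = FALSE)
  }
  bad <- which(!(seg$start >= 0 & seg$start < seg$end) | is.na(seg$copy_number) |
                 seg$copy_number < 0)
  if (length(bad)) {
    stop("malformed segment at data line ", bad[1],
         " (need 0 <= start < end and copy_number >= 0)")
  }
  cn_segments(seg, sample_id = sample_id,
              purity = if (is.null(purity)) 1 else purity,
              ploidy = if (is.null(ploidy)) 2 else ploidy)
}

#' Construct a per-sample copy-number segment set
#'
#' @param segments data.frame with chrom, start, end (0-based half-open),
#'   copy_number.
#' @param sample_id sample identifier.
#' @param purity tumor purity in (0, 1].
#' @param ploidy tumor ploidy (> 0).
#' @export
cn_segments <- function(segments, sample_id = "sample", purity = 1,
                        ploidy = 2) {
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in%
                  names(segments)),
            purity > 0, purity <= 1, ploidy > 0)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  # reject overlaps within a chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }
  structure(segments, class = c("cn_segments", "data.frame"),
            sample_id = sample_id, purity = purity, ploidy = ploidy)
}

#' @export
print.cn_segments <- function(x, ...) {
  cat("cn_segments for", attr(x, "sample_id"), "- purity",
      attr(x, "purity"), "ploidy", attr(x, "ploidy"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x), "segments total\n")
  invisible(x)
}

#' Write copy segments in the purple_tsv dialect (round-trips with
#' [read_copy_segments])
#' @param seg a `cn_segments`.
#' @param path output path.
#' @export
write_copy_segments <- function(seg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#purity=", attr(seg, "purity")),
               paste0("#ploidy=", attr(seg, "ploidy"))), con)
  d <- data.frame(chromosome = seg$chrom, start = seg$start + 1,
                  end = seg$end, copyNumber = seg$copy_number)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(seg)
}

# canonical ordering of a breakend pair
canonicalize_breakpoints <- function(d) {
  flip <- (d$chrom2 < d$chrom1) | (d$chrom1 == d$chrom2 & d$pos2 < d$pos1)
  if (any(flip)) {
    tmp <- d[flip, ]
    d$chrom1[flip] <- tmp$chrom2; d$pos1[flip] <- tmp$pos2
    d$strand1[flip] <- tmp$strand2
    d$chrom2[flip] <- tmp$chrom1; d$pos2[flip] <- tmp$pos1
    d$strand2[flip] <- tmp$strand1
  }
  d
}

infer_sv_type <- function(chrom1, strand1, chrom2, strand2) {
  ifelse(chrom1 != chrom2, "TRA",
    ifelse(strand1 == "+" & strand2 == "-", "DEL",
      ifelse(strand1 == "-" & strand2 == "+", "DUP", "INV")))
}

#' Read SV breakpoints from a BEDPE file
#'
#' Expects the 10-column BEDPE layout (chrom1, start1, end1, chrom2, start2,
#' end2, name, score, strand1, strand2) with an optional 11th `sv_type`
#' column. When absent, the type is inferred from orientation: on one
#' chromosome `+/-` is DEL, `-/+` is DUP, `+/+` or `-/-` is INV; different
#' chromosomes give TRA. Breakend pairs are stored in canonical order
#' (chrom1, pos1) <= (chrom2, pos2). Positions taken as the BEDPE start
#' (0-based).
#'
#' @param path BEDPE path (no header).
#' @return data.frame of class `breakpoints` with chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, sv_type, name.
#' @export
read_breakpoints <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 10) stop("BEDPE needs >= 10 columns")
  strands <- c(d[[9]], d[[10]])
  if (!all(strands %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(setdiff(strands, c("+", "-"))), collapse = ", "))
  }
  bp <- data.frame(chrom1 = d[[1]], pos1 = d[[2]], strand1 = d[[9]],
                   chrom2 = d[[4]], pos2 = d[[5]], strand2 = d[[10]],
                   name = d[[7]], stringsAsFactors = FALSE)
  bp <- canonicalize_breakpoints(bp)
  if (ncol(d) >= 11 && !all(is.na(d[[11]]))) {
    bp$sv_type <- toupper(d[[11]])
    ok <- bp$sv_type %in% c("DEL", "DUP", "INV", "TRA", "INS")
    if (!all(ok)) stop("unknown sv_type: ",
                       paste(unique(bp$sv_type[!ok]), collapse = ", "))
  } else {
    bp$sv_type <- infer_sv_type(bp$chrom1, bp$strand1, bp$chrom2, bp$strand2)
  }
  class(bp) <- c("breakpoints", "data.frame")
  bp
}

#' Write breakpoints as 11-column BEDPE (round-trips with
#' [read_breakpoints])
#' @param bp a `breakpoints` data.frame.
#' @param path output path.
#' @export
write_breakpoints <- function(bp, path) {
  d <- data.frame(bp$chrom1, bp$pos1, bp$pos1 + 1, bp$chrom2, bp$pos2,
                  bp$pos2 + 1,
                  if (is.null(bp$name)) "." else bp$name, ".",
                  bp$strand1, bp$strand2, bp$sv_type)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(bp)
}

EVENT_CLASSES <- c("ecDNA", "BFB", "CNC", "unknown", "linear")

#' Construct an amplicon event (one cSV call)
#'
#' @param event_id,sample_id identifiers.
#' @param class one of ecDNA, BFB, CNC, unknown, linear (case-insensitive).
#' @param segments data.frame with chrom, start, end, copy_number.
#' @param junctions optional `breakpoints` data.frame.
#' @param amp_factor optional simulated contact amplification factor.
#' @return an object of class `amplicon_event`.
#' @export
amplicon_event <- function(event_id, sample_id, class, segments,
                           junctions = NULL, amp_factor = NULL) {
  m <- match(tolower(class), tolower(EVENT_CLASSES))
  if (is.na(m)) {
    stop("unknown event class '", class, "'; allowed: ",
         paste(EVENT_CLASSES, collapse = ", "))
  }
  stopifnot(nrow(segments) >= 1, all(segments$copy_number >= 0),
            all(segments$start < segments$end))
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(event_id = event_id, sample_id = sample_id,
                 class = EVENT_CLASSES[m], segments = segments,
                 junctions = junctions, amp_factor = amp_factor),
            class = "amplicon_event")
}

#' @export
print.amplicon_event <- function(x, ...) {
  cat("amplicon_event", x$event_id, "(", x$class, ") in", x$sample_id, ":",
      nrow(x$segments), "segment(s) on",
      length(unique(x$segments$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read cSV events from the package's event TSV dialect
#'
#' One row per segment, header: sample_id, event_id, class, chrom, start,
#' end (0-based half-open), copy_number. Rows are grouped by
#' (sample_id, event_id); duplicate identical rows are dropped with a
#' warning.
#'
#' @param path TSV path.
#' @return list of `amplicon_event`.
#' @export
read_events <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "event_id", "class", "chrom", "start", "end",
            "copy_number")
  if (!all(need %in% names(d))) {
    stop("event table needs columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(d)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate event row(s)")
    d <- d[!dup, ]
  }
  key <- paste(d$sample_id, d$event_id, sep = "\r")
  lapply(split(d, factor(key, levels = unique(key))), function(g) {
    amplicon_event(g$event_id[1], g$sample_id[1], g$class[1],
                   g[, c("chrom", "start", "end", "copy_number")])
  })
}

#' Write events in the package event TSV dialect
#' @param events list of `amplicon_event`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  rows <- lapply(events, function(e) {
    data.frame(sample_id = e$sample_id, event_id = e$event_id,
               class = e$class, e$segments, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(events)
}

#' Read a binary mutation matrix (samples x variants TSV)
#'
#' First column `sample_id`, remaining columns one per variant, entries 0/1.
#' @param path TSV path.
#' @return integer matrix with sample rownames and variant colnames.
#' @export
read_mutation_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("mutation matrix entries must be 0/1")
  m
}

#' Write a binary mutation matrix
#' @param m integer matrix (samples x variants).
#' @param path output path.
#' @export
write_mutation_matrix <- function(m, path) {
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Read a BED interval file (0-based half-open, no header)
#' @param path BED path.
#' @return data.frame with chrom, start, end.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  genomic_interval(d[[1]], d[[2]], d[[3]])
}
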