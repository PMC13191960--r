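#' Define a Hi-C simulation scenario
#'
#' The generator emulates a tumor Hi-C contact map: power-law distance
#' decay in cis, a flat trans background, Poisson count noise, and cSV
#' contact signatures mixed by tumor purity. ecDNA events add contact only
#' between pairs of bins inside the event (the amplicon is detached from
#' its chromosome, so event-to-flank contact stays at baseline — the low
#' projection signature after balancing); BFB events instead amplify the
#' chromosomal copy number of their bins (so event-to-flank contact scales
#' too) and add a fold-back junction hotspot.
#'
#' @param genome named vector of chromosome lengths (bp).
#' @param events list of `amplicon_event`; each may carry `amp_factor`
#'   (contact uplift factor; defaults to (segment CN / ploidy)^2).
#' @param purity tumor purity rho in (0, 1].
#' @param ploidy tumor ploidy.
#' @param bin_size bin width in bp.
#' @param decay_alpha cis distance-decay exponent.
#' @param base_intensity expected cis count at distance 0 (B).
#' @param trans_rate trans background as a fraction of B (tau).
#' @param seed RNG seed.
#' @export
sim_scenario <- function(genome, events = list(), purity = 0.7, ploidy = 2,
                         bin_size = 10000, decay_alpha = 1,
                         base_intensity = 60, trans_rate = 0.02, seed = 1) {
  stopifnot(purity > 0, purity <= 1, ploidy > 0, base_intensity > 0,
            trans_rate >= 0, decay_alpha >= 0)
  if (length(events) >= 2) {
    segs <- do.call(rbind, lapply(events, function(e) {
      cbind(e$segments[, c("chrom", "start", "end")], id = e$event_id)
    }))
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)] &
                             s$id[-1] != s$id[-nrow(s)])) {
        stop("declared events overlap on ", ch)
      }
    }
  }
  structure(list(genome = genome, events = events, purity = purity,
                 ploidy = ploidy, bin_size = bin_size,
                 decay_alpha = decay_alpha, base_intensity = base_intensity,
                 trans_rate = trans_rate, seed = seed),
            class = "sim_scenario")
}

event_amp_factor <- function(e, ploidy) {
  if (!is.null(e$amp_factor)) return(e$amp_factor)
  (mean(e$segments$copy_number) / ploidy)^2
}

#' Simulate a Hi-C contact matrix with embedded cSV signatures
#'
#' Expected cis count for bins i, j on one chromosome is
#' B (|i-j| + 1)^(-alpha) m_i m_j, where m is the purity-mixed chromosomal
#' multiplier m = rho cn/ploidy + (1 - rho); trans background is B tau.
#' ecDNA events add B k_amp (k_amp = rho x amp_factor) to pairs with both
#' bins inside event segments, including cross-chromosome pairs; BFB
#' events raise the chromosomal multiplier of their bins and add a
#' fold-back hotspot at segment boundaries. Observed counts are Poisson.
#'
#' @param scenario a `sim_scenario`.
#' @return a raw `contact_matrix`; ground-truth labels are attached as
#'   attribute `truth`.
#' @export
simulate_hic <- function(scenario) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scenario$seed)
  bins <- genome_bins(scenario$genome, scenario$bin_size)
  rho <- scenario$purity; psi <- scenario$ploidy
  B <- scenario$base_intensity
  m <- rep(1, bins$n_bins) # multiplier of 1 == chromosomal CN at ploidy
  amp_extra <- NULL        # list of (bin set, k_amp) blocks for ecDNA
  hotspots <- NULL
  for (e in scenario$events) {
    k_amp <- rho * event_amp_factor(e, psi)
    eb_all <- unlist(lapply(seq_len(nrow(e$segments)), function(k) {
      s <- e$segments[k, ]
      bins_for_interval(bins, s$chrom, s$start, s$end)
    }))
    if (e$class == "BFB") {
      for (k in seq_len(nrow(e$segments))) {
        s <- e$segments[k, ]
        eb <- bins_for_interval(bins, s$chrom, s$start, s$end)
        m[eb] <- rho * s$copy_number / psi + (1 - rho)
        # fold-back junction hotspot at the segment's outer boundary
        hb <- eb[max(1, length(eb) - 1):length(eb)]
        hotspots <- c(hotspots, list(list(bins = hb, k = k_amp)))
      }
    } else {
      amp_extra <- c(amp_extra, list(list(bins = eb_all, k = k_amp)))
    }
  }
  n <- bins$n_bins
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- bins$bin_chrom[i] == bins$bin_chrom[j]
  e_ij <- numeric(length(i))
  e_ij[same] <- B * (abs(i[same] - j[same]) + 1)^(-scenario$decay_alpha)
  e_ij[!same] <- B * scenario$trans_rate
  e_ij <- e_ij * m[i] * m[j]
  for (blk in amp_extra) {
    inb <- i %in% blk$bins & j %in% blk$bins
    e_ij[inb] <- e_ij[inb] + B * blk$k
  }
  for (blk in hotspots) {
    inb <- i %in% blk$bins & j %in% blk$bins
    e_ij[inb] <- e_ij[inb] + B * blk$k
  }
  counts <- stats::rpois(length(e_ij), e_ij)
  keep <- counts > 0
  cm <- contact_matrix(bins, i[keep], j[keep], counts[keep])
  attr(cm, "truth") <- list(events = scenario$events,
                            multiplier = m, scenario = scenario)
  cm
}

#' Simulate a chromothriptic SV/copy-number cluster
#'
#' Places exactly the requested numbers of inversion and deletion breakend
#' pairs (both ends inside the region) and copy-number switch boundaries
#' (|delta CN| = 1) inside the region, all on a 1 kb minimum-spacing grid.
#'
#' @param chrom chromosome name.
#' @param region numeric length-2: 0-based half-open region bounds.
#' @param n_inv,n_del,n_switch feature counts.
#' @param chrom_length chromosome length (bp).
#' @param seed RNG seed.
#' @return list with `breakpoints` and `segments` (a `cn_segments` with
#'   oscillating CN, background CN 2).
#' @export
simulate_chromothripsis <- function(chrom, region, n_inv, n_del, n_switch,
                                    chrom_length = NULL, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(chrom_length)) chrom_length <- region[2] + 1e6
  spacing <- 1000
  n_pos <- 2 * (n_inv + n_del) + n_switch
  grid <- seq(region[1] + spacing, region[2] - spacing, by = spacing)
  if (length(grid) < n_pos) {
    stop("region too small for ", n_pos, " features at ", spacing,
         " bp spacing")
  }
  pos <- sort(sample(grid, n_pos))
  pos <- sample(pos) # decouple feature type from genomic order
  take <- function(k) {
    out <- pos[seq_len(k)]
    pos <<- pos[-seq_len(k)]
    out
  }
  mk_bp <- function(p1, p2, s1, s2, type) {
    if (!length(p1)) return(NULL)
    canonicalize_breakpoints(data.frame(
      chrom1 = chrom, pos1 = pmin(p1, p2), strand1 = s1,
      chrom2 = chrom, pos2 = pmax(p1, p2), strand2 = s2,
      name = paste0(type, seq_along(p1)), sv_type = type,
      stringsAsFactors = FALSE))
  }
  inv <- mk_bp(take(n_inv), take(n_inv), "+", "+", "INV")
  del <- mk_bp(take(n_del), take(n_del), "+", "-", "DEL")
  bp <- rbind(inv, del)
  class(bp) <- c("breakpoints", "data.frame")
  bounds <- sort(take(n_switch))
  starts <- c(0, bounds)
  ends <- c(bounds, chrom_length)
  cn <- 2 + (seq_along(starts) - 1) %% 2 # oscillate 2,3,2,3,...
  seg <- cn_segments(data.frame(chrom = chrom, start = starts, end = ends,
                                copy_number = cn, stringsAsFactors = FALSE),
                     sample_id = "chromothripsis_sim")
  list(breakpoints = bp, segments = seg)
}

#' Simulate a multi-sample cohort with convergent and shared cSVs
#'
#' Every listed sample carries one ecDNA event at the given locus.
#' Sample pairs named in `shared_pairs` reuse byte-identical junction
#' breakpoints (one origin); samples in no shared pair draw fresh
#' junctions at least 5 kb from all previously drawn ones (independent
#' origins at the same locus).
#'
#' @param n_samples number of samples.
#' @param locus list(chrom, start, end) of the recurrently amplified locus.
#' @param shared_pairs list of integer pairs sharing one event.
#' @param chrom_length chromosome length.
#' @param seed RNG seed.
#' @return named list per sample: `amplicon_event` list, `cn_segments`,
#'   purity/ploidy.
#' @export
simulate_cohort <- function(n_samples, locus, shared_pairs = list(),
                            chrom_length = NULL, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(chrom_length)) chrom_length <- locus$end + 2e6
  used <- numeric(0)
  draw_pos <- function(lo, hi) {
    repeat {
      p <- round(stats::runif(1, lo, hi))
      if (!length(used) || min(abs(used - p)) >= 5000) {
        used <<- c(used, p)
        return(p)
      }
    }
  }
  draw_junctions <- function() {
    margin <- (locus$end - locus$start) * 0.2
    p1 <- draw_pos(locus$start, locus$start + margin)
    p2 <- draw_pos(locus$end - margin, locus$end)
    bp <- data.frame(chrom1 = locus$chrom, pos1 = p1, strand1 = "-",
                     chrom2 = locus$chrom, pos2 = p2, strand2 = "+",
                     name = "junc1", sv_type = "DUP",
                     stringsAsFactors = FALSE)
    class(bp) <- c("breakpoints", "data.frame")
    bp
  }
  owner <- seq_len(n_samples) # owner[i] = sample whose junctions i reuses
  for (pr in shared_pairs) owner[pr[2]] <- owner[pr[1]]
  junctions <- vector("list", n_samples)
  out <- list()
  for (s in seq_len(n_samples)) {
    if (is.null(junctions[[owner[s]]])) junctions[[owner[s]]] <- draw_junctions()
    jc <- junctions[[owner[s]]]
    cn <- round(stats::runif(1, 8, 30))
    ev <- amplicon_event(
      event_id = paste0("ev", s), sample_id = paste0("S", s),
      class = "ecDNA",
      segments = data.frame(chrom = locus$chrom, start = jc$pos1,
                            end = jc$pos2, copy_number = cn,
                            stringsAsFactors = FALSE),
      junctions = jc)
    seg <- cn_segments(data.frame(
      chrom = locus$chrom,
      start = c(0, jc$pos1, jc$pos2),
      end = c(jc$pos1, jc$pos2, chrom_length),
      copy_number = c(2, cn, 2), stringsAsFactors = FALSE),
      sample_id = paste0("S", s),
      purity = stats::runif(1, 0.3, 0.9), ploidy = 2)
    out[[paste0("S", s)]] <- list(events = list(ev), segments = seg)
  }
  out
}

#' Simulate expression driven by copy number plus an ecDNA effect
#'
#' expr = beta0 + beta_cn x CN + beta_ecdna x ecDNA + Normal(0, sigma).
#' Copy number is drawn with a heavier tail in ecDNA-positive samples, so
#' CN and ecDNA status are confounded by design and the nested test is
#' genuinely exercised.
#'
#' @param n number of samples.
#' @param beta_cn,beta_ecdna true effects.
#' @param sigma residual standard deviation.
#' @param beta0 intercept.
#' @param prob_ecdna marginal probability a sample is ecDNA-positive.
#' @param seed RNG seed.
#' @return data.frame with expression, weighted_cn, ecdna_status.
#' @export
simulate_expression <- function(n, beta_cn = 0.5, beta_ecdna = 1,
                                sigma = 0.2, beta0 = 1, prob_ecdna = 0.4,
                                seed = 1) {
  stopifnot(n >= 4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ecdna <- stats::rbinom(n, 1, prob_ecdna)
  # ensure both groups are represented
  if (all(ecdna == 0)) ecdna[1] <- 1L
  if (all(ecdna == 1)) ecdna[1] <- 0L
  cn <- 2 + stats::rexp(n, rate = 1 / (1 + 4 * ecdna))
  expr <- beta0 + beta_cn * cn + beta_ecdna * ecdna +
    stats::rnorm(n, 0, sigma)
  data.frame(expression = expr, weighted_cn = cn, ecdna_status = ecdna)
}

#' Simulate a clonal mutation matrix along a known tree
#'
#' Assigns each branch a disjoint set of variants; each leaf inherits all
#' variants on its root path (perfect phylogeny, infinite sites). The
#' resulting Hamming distances are exactly additive on the tree with
#' branch lengths = mutations per branch.
#'
#' @param tree an [ape::phylo] (rooted) or Newick string.
#' @param mutations_per_branch variants per branch (scalar, recycled).
#' @param seed RNG seed (shuffles variant column order).
#' @return list with `matrix` (binary, samples x variants) and `tree`.
#' @export
simulate_mutations <- function(tree, mutations_per_branch = 5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3)
  n_edge <- nrow(tree$edge)
  per_edge <- rep_len(mutations_per_branch, n_edge)
  n_var <- sum(per_edge)
  n_tip <- length(tree$tip.label)
  m <- matrix(0L, n_tip, max(1, n_var),
              dimnames = list(tree$tip.label,
                              paste0("v", seq_len(max(1, n_var)))))
  if (n_var > 0) {
    # tips under each edge inherit that edge's variants
    col0 <- cumsum(c(0, per_edge))
    desc <- lapply(seq_len(n_edge), function(k) {
      node <- tree$edge[k, 2]
      if (node <= n_tip) node else {
        which(tree$tip.label %in%
                ape::extract.clade(tree, node)$tip.label)
      }
    })
    for (k in seq_len(n_edge)) {
      if (per_edge[k] == 0) next
      cols <- (col0[k] + 1):col0[k + 1]
      m[desc[[k]], cols] <- 1L
    }
    m <- m[, sample(ncol(m)), drop = FALSE]
  } else {
    m <- m[, 0, drop = FALSE]
  }
  list(matrix = m, tree = tree)
}
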