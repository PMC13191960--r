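# shared fixture builders (everything generated in code; no stored data)

# single-segment ecDNA event on chrA
fix_cis_event <- function(cn = 20, amp = 10) {
  amplicon_event("cis1", "s1", "ecDNA",
                 data.frame(chrom = "chrA", start = 1.0e6, end = 1.1e6,
                            copy_number = cn),
                 amp_factor = amp)
}

# two-chromosome ecDNA event
fix_trans_event <- function(cn = 18, amp = 10) {
  amplicon_event("trans1", "s1", "ecDNA",
                 data.frame(chrom = c("chrA", "chrB"),
                            start = c(1.0e6, 0.5e6),
                            end = c(1.1e6, 0.6e6), copy_number = cn),
                 amp_factor = amp)
}

# brute-force enumeration oracle for the Wilcoxon exact p-value
oracle_wilcoxon_exact <- function(x, y, alternative = "two_sided") {
  nx <- length(x); n <- nx + length(y)
  u_obs <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- colSums(utils::combn(n, nx)) - nx * (nx + 1) / 2
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  switch(alternative,
         two_sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le, greater = p_ge)
}

# brute-force BH oracle: adjusted_i = min over k with p_(k) >= p_i rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)
    adj[i] <- min(1, min(m * p[o][r:m] / (r:m)))
  }
  adj
}

# random additive tree distances: generate a random topology with positive
# branch lengths and return its exact path-length matrix + the tree
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, br = function(n) stats::runif(n, 0.5, 3))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
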