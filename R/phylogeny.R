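#' Pairwise mutation distances between tumor samples
#'
#' Hamming distance over the binary deleterious-mutation profiles: the
#' number of variants present in exactly one of the two samples. An
#' optional germline pseudo-sample with an all-zero profile provides an
#' outgroup root.
#'
#' @param m binary matrix, samples x variants.
#' @param include_germline_root add a "germline" all-zero row.
#' @return symmetric distance matrix with zero diagonal.
#' @export
mutation_distance_matrix <- function(m, include_germline_root = TRUE) {
  stopifnot(nrow(m) >= 2, all(m %in% c(0, 1)))
  if (include_germline_root) {
    m <- rbind(m, germline = 0L)
  }
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree
#'
#' Classic NJ: iteratively joins the pair (i, j) minimizing
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k), with the
#' standard branch-length formulas. Ties in Q are broken by the
#' lexicographically smallest label pair, so the result is deterministic.
#' Negative branch lengths are clamped to zero with a warning. On additive
#' distances the true topology and branch lengths are recovered exactly.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @param root_at optional leaf label to root the tree at (e.g.
#'   "germline"); otherwise the tree is left unrooted.
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(d, root_at = NULL) {
  d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3) stop("neighbor joining needs >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  # active nodes are referenced by tree-node id; leaves are 1..n0,
  # internal nodes are numbered n0+1 ... (ape convention: root-ish last)
  active <- seq_len(n0)          # tree node ids
  node_label <- labels           # for deterministic tie-breaks
  edges <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  next_internal <- n0 + (n0 - 2) # assign internal ids downward so ape's
  internal_ids <- integer(0)     # expectation (root = n0+1) can be remapped
  cur_id <- 0L
  new_ids <- integer(0)
  # simpler: number internals sequentially n0+1.. and fix up later
  internal_counter <- n0
  D <- d
  clamped <- FALSE
  while (length(active) > 2) {
    n <- length(active)
    rs <- rowSums(D)
    q <- (n - 2) * D - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- node_label[cand[, 1]]; lab2 <- node_label[cand[, 2]]
    a <- pmin(lab1, lab2); b <- pmax(lab1, lab2)
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    li <- max(0, li); lj <- max(0, lj)
    internal_counter <- internal_counter + 1L
    u <- internal_counter
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    edge_len <- c(edge_len, li, lj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    D <- rbind(cbind(D, du), c(du, 0))
    keep <- setdiff(seq_len(n + 1), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    active <- c(active, u)[keep]
    node_label <- c(node_label, min(node_label[i], node_label[j]))[keep]
  }
  # join the last two active nodes with a single edge
  l <- max(0, D[1, 2])
  if (D[1, 2] < 0) clamped <- TRUE
  edges <- rbind(edges, c(active[2], active[1]))
  edge_len <- c(edge_len, l)
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  n_internal <- internal_counter - n0
  # remap internal ids so the last-created (top) node is n0+1 (ape root)
  remap <- c(seq_len(n0), rev(seq_len(n_internal)) + n0)
  mapped <- matrix(remap[edges], ncol = 2)
  tr <- structure(list(edge = mapped, edge.length = edge_len,
                       tip.label = labels, Nnode = n_internal),
                  class = "phylo", order = "postorder")
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (!is.null(root_at)) {
    tr <- ape::root(tr, outgroup = root_at, resolve.root = TRUE)
  }
  tr
}

#' Neighbor-joining tumor phylogeny from a mutation matrix
#'
#' @param m binary mutation matrix (samples x variants).
#' @param include_germline_root add an all-zero germline outgroup and root
#'   the tree there.
#' @param newick_path optional path to write the Newick tree.
#' @return an [ape::phylo] tree.
#' @export
mutation_phylogeny <- function(m, include_germline_root = TRUE,
                               newick_path = NULL) {
  d <- mutation_distance_matrix(m, include_germline_root)
  if (all(d == 0)) stop("all pairwise distances are zero; no tree signal")
  tr <- neighbor_joining(
    d, root_at = if (include_germline_root) "germline" else NULL)
  if (!is.null(newick_path)) ape::write.tree(tr, newick_path)
  tr
}
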