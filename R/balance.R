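#' Iterative correction (ICE) of a contact matrix
#'
#' Matrix balancing that equalizes the marginals of unmasked bins, removing
#' multiplicative per-bin biases (GC content, mappability, fragment length).
#' Alternates dividing the matrix by its current marginal profile until the
#' unmasked row sums are flat; the accumulated per-bin bias vector is stored
#' so raw values can be recovered. Already-balanced input is a fixed point.
#'
#' @param cm a `contact_matrix` of raw counts.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the relative spread of marginals.
#' @return a balanced `contact_matrix` (mean unmasked marginal rescaled to
#'   the input's mean marginal); on non-convergence a warning is issued and
#'   `balanced` stays `FALSE`.
#' @export
iterative_correction <- function(cm, max_iter = 200, tol = 1e-6) {
  keep <- !cm$bins$mask
  mat <- as.matrix(cm$mat)
  bias <- rep(1, cm$bins$n_bins)
  target <- mean(Matrix::rowSums(cm$mat)[keep])
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(mat)
    mb <- mean(s[keep])
    db <- s / mb
    db[!keep | s == 0] <- 1
    if (max(abs(db[keep] - 1)) < tol) {
      converged <- TRUE
      break
    }
    mat <- mat / outer(db, db)
    bias <- bias * db
  }
  if (!converged) {
    warning("iterative correction did not converge in ", max_iter,
            " iterations; result flagged unbalanced")
  }
  # rescale so the mean unmasked marginal matches the raw input scale
  s <- rowSums(mat)
  scale <- target / mean(s[keep])
  mat <- mat * scale
  tm <- which(mat != 0, arr.ind = TRUE)
  up <- tm[tm[, 1] <= tm[, 2], , drop = FALSE]
  out <- contact_matrix(cm$bins, up[, 1], up[, 2], mat[up],
                        balanced = converged,
                        bias = bias / sqrt(scale))
  out$bins$mask <- cm$bins$mask
  out
}
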