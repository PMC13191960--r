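#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The workhorse test for comparing Hi-C contact-value sets. Uses the exact
#' null distribution (full enumeration of rank assignments) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction. The
#' reported statistic is the Mann-Whitney U of `x`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative "two_sided", "less" (x shifted below y) or "greater".
#' @param exact_max combined size at or below which the exact path is used.
#' @return list with statistic, p_value, alternative, method.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater"),
                              exact_max = 12) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty input sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n <= exact_max && !ties) {
    # exact: U over all C(n, nx) assignments of ranks to x
    combos <- utils::combn(n, nx)
    us <- colSums(combos) - nx * (nx + 1) / 2
    p_le <- mean(us <= u); p_ge <- mean(us >= u)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    method <- "wilcoxon exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sd <- sqrt(sigma2)
      z_less <- (u - mu + 0.5) / sd
      z_greater <- (u - mu - 0.5) / sd
      p <- switch(alternative,
                  two_sided = {
                    z <- (u - mu - sign(u - mu) * 0.5) / sd
                    min(1, 2 * stats::pnorm(-abs(z)))
                  },
                  less = stats::pnorm(z_less),
                  greater = stats::pnorm(z_greater, lower.tail = FALSE))
    }
    method <- "wilcoxon normal approximation"
  }
  list(statistic = u, p_value = p, alternative = alternative,
       method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities, at fixed margins,
#' of all tables at most as probable as the observed one (the usual
#' "probability mass" convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with statistic (odds ratio of the table), p_value, method.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- m1 + m2
  if (m1 == 0 || m2 == 0 || c1 == 0 || c1 == n) {
    p <- 1
  } else {
    support <- max(0, c1 - m2):min(c1, m1)
    dens <- stats::dhyper(support, m1, m2, c1)
    d_obs <- stats::dhyper(a, m1, m2, c1)
    p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(statistic = or, p_value = p, method = "fisher exact 2x2")
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with statistic (tie-corrected H), p_value (chi-squared,
#'   k - 1 df), df, method.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  tie_tab <- table(x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  df <- length(groups) - 1
  list(statistic = h, p_value = stats::pchisq(h, df, lower.tail = FALSE),
       df = df, method = "kruskal-wallis")
}

#' Nested F-test: does ecDNA status explain expression beyond copy number?
#'
#' Fits ordinary least squares for the reduced model
#' `y ~ 1 + cn` and the full model `y ~ 1 + cn + ecdna`, and tests the one
#' added degree of freedom: F = (SSE_r - SSE_f) / (SSE_f / (n - 3)).
#' A perfect full fit (SSE_f ~ 0 with SSE_r > 0) is reported as F = Inf,
#' p = 0; when both models fit perfectly, F = 0 and p = 1.
#'
#' @param y numeric response (e.g. log2(TPM+1)).
#' @param covariate_cn numeric copy-number covariate.
#' @param indicator_ecdna 0/1 ecDNA status.
#' @return list with F, p, coef_ecdna, se_ecdna, n.
#' @export
nested_f_test <- function(y, covariate_cn, indicator_ecdna) {
  n <- length(y)
  stopifnot(length(covariate_cn) == n, length(indicator_ecdna) == n, n >= 4)
  xf <- cbind(1, covariate_cn, indicator_ecdna)
  if (qr(xf)$rank < 3) {
    stop("full design is rank-deficient: ecDNA indicator is collinear ",
         "with the intercept/copy-number covariate")
  }
  fit_r <- stats::lm.fit(cbind(1, covariate_cn), y)
  fit_f <- stats::lm.fit(xf, y)
  sse_r <- sum(fit_r$residuals^2)
  sse_f <- sum(fit_f$residuals^2)
  tol <- 1e-12 * max(1, sum(y^2))
  if (sse_f <= tol) {
    if (sse_r <= tol) {
      fstat <- 0; p <- 1
    } else {
      fstat <- Inf; p <- 0
    }
  } else {
    fstat <- (sse_r - sse_f) / (sse_f / (n - 3))
    fstat <- max(0, fstat)
    p <- stats::pf(fstat, 1, n - 3, lower.tail = FALSE)
  }
  sigma2 <- if (n > 3) sse_f / (n - 3) else NA_real_
  xtxi <- chol2inv(chol(crossprod(xf)))
  list(F = fstat, p = p, coef_ecdna = unname(fit_f$coefficients[3]),
       se_ecdna = sqrt(sigma2 * xtxi[3, 3]), n = n)
}
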