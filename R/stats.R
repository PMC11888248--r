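#' Area under the ROC curve from scores and class labels
#'
#' Computes the probability that a randomly chosen positive outranks a randomly
#' chosen negative, counting ties as one half. Uses the mid-rank formula
#' \eqn{(R^+ - n^+(n^+ + 1)/2) / (n^+ n^-)} where \eqn{R^+} is the rank sum of
#' the positives.
#'
#' @param scores Numeric vector of scores (higher = more positive-like).
#' @param positives Logical vector, same length, `TRUE` for positive cases.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.2, 0.9), c(FALSE, FALSE, TRUE)) # 1
#' @export
auroc <- function(scores, positives) {
  stopifnot(length(scores) == length(positives), is.logical(positives))
  n_pos <- sum(positives)
  n_neg <- sum(!positives)
  if (n_pos == 0L || n_neg == 0L) {
    abort_atlasrep("auroc() needs at least one positive and one negative (got %d / %d)",
                   n_pos, n_neg)
  }
  r <- midrank(scores)
  (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# One-vs-rest AUROC of `scores` for every level of `labels` at once.
# Ranks are computed a single time; returns a named vector over levels.
auroc_grouped <- function(scores, labels) {
  labels <- as.character(labels)
  r <- midrank(scores)
  n <- length(scores)
  sums <- vapply(split(r, labels), sum, numeric(1))
  sizes <- vapply(split(r, labels), length, integer(1))
  out <- (sums - sizes * (sizes + 1) / 2) / (sizes * (n - sizes))
  out[sizes == n] <- NA_real_
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Returns `NA` when either vector is
#' constant (undefined rather than an error, so callers can flag such genes).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_atlasrep("spearman_rho(): length mismatch")
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

new_test_result <- function(statistic, p_value, method, tail, n, ...) {
  tibble::tibble(statistic = statistic, p_value = p_value, method = method,
                 tail = tail, n = list(n), ...)
}

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Mann-Whitney U test of two independent samples. Uses exhaustive enumeration
#' of all label assignments (handling ties exactly) when the combined sample
#' size is below 20, and the normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param tail `"two-sided"`, `"greater"` (x tends larger), or `"less"`.
#' @return One-row tibble with `statistic` (U for x), `p_value`, `method`,
#'   `tail`, and `n` (list of the two sample sizes).
#' @export
rank_sum_test <- function(x, y, tail = c("two-sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (!length(x) || !length(y)) abort_atlasrep("rank_sum_test(): empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- midrank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n < 20L) {
    # exact: U for every choice of nx positions among the pooled ranks
    combos <- utils::combn(n, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- switch(tail,
      "greater"   = mean(u_all >= u_obs - eps),
      "less"      = mean(u_all <= u_obs + eps),
      "two-sided" = min(1, 2 * min(mean(u_all >= u_obs - eps),
                                   mean(u_all <= u_obs + eps))))
    method <- "rank-sum (exact enumeration)"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z_g <- (u_obs - mu - 0.5) / sigma
    z_l <- (u_obs - mu + 0.5) / sigma
    p <- switch(tail,
      "greater"   = stats::pnorm(z_g, lower.tail = FALSE),
      "less"      = stats::pnorm(z_l),
      "two-sided" = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                   stats::pnorm(z_l))))
    method <- "rank-sum (normal approximation, tie-corrected)"
  }
  new_test_result(u_obs, p, method, tail, c(nx = nx, ny = ny))
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least `k` between a set of size
#' `n_a` and a set of size `n_b` drawn from a universe of size `n_total`.
#'
#' @param k Observed overlap.
#' @param n_a,n_b Set sizes.
#' @param n_total Universe size.
#' @return One-row tibble (see [rank_sum_test()]).
#' @export
hypergeom_overlap_test <- function(k, n_a, n_b, n_total) {
  if (k < 0 || n_a > n_total || n_b > n_total || k > min(n_a, n_b)) {
    abort_atlasrep("hypergeom_overlap_test(): infeasible margins k=%d nA=%d nB=%d N=%d",
                   k, n_a, n_b, n_total)
  }
  p <- stats::phyper(k - 1, n_a, n_total - n_a, n_b, lower.tail = FALSE)
  new_test_result(k, p, "hypergeometric overlap", "greater",
                  c(n_a = n_a, n_b = n_b, n_total = n_total))
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test. The two-sided p-value sums all tables with
#' point probability at most that of the observed table (standard conditional
#' definition). The reported odds ratio is the sample estimate
#' \eqn{ad/bc} (with `Inf`/0 conventions when a margin cell is zero), not the
#' conditional maximum-likelihood estimate.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param tail `"two-sided"`, `"greater"` (positive association of cell
#'   `[1, 1]`), or `"less"`.
#' @return One-row tibble with an additional `odds_ratio` column.
#' @export
fisher_exact_2x2 <- function(tab, tail = c("two-sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c; nn <- b + d; kk <- a + b
  lo <- max(0, kk - nn); hi <- min(kk, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, nn, kk)
  obs <- stats::dhyper(a, m, nn, kk)
  p <- switch(tail,
    "greater"   = sum(dens[support >= a]),
    "less"      = sum(dens[support <= a]),
    # relative tolerance as in the classical implementation
    "two-sided" = sum(dens[dens <= obs * (1 + 1e-7)]))
  p <- min(1, p)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  new_test_result(a, p, "Fisher exact (2x2)", tail, c(n = sum(tab)),
                  odds_ratio = or)
}

#' Multiple-testing correction
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"` (Benjamini-Hochberg step-up).
#' @return Adjusted p-values, same length.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Permutation test for the common overlap of several sets
#'
#' Tests whether the intersection of a collection of sets is larger or smaller
#' than expected when each set is replaced by a uniform random subset of the
#' universe of the same size. The empirical p-value uses the +1 correction
#' \eqn{p = (1 + \#\{\mathrm{as\ or\ more\ extreme}\}) / (n_{perm} + 1)}.
#'
#' @param sets List of character vectors (e.g. cluster ids), each a subset of
#'   `universe`.
#' @param universe Character vector of all eligible ids.
#' @param n_perm Number of permutation replicates (>= 100).
#' @param seed Integer seed.
#' @param tail `"less"` (observed smaller than chance), `"greater"`, or
#'   `"two-sided"`.
#' @return One-row tibble with `statistic` (observed intersection size),
#'   `expected` (mean null intersection), `p_value`, `method`, `tail`, `n`.
#' @export
permutation_overlap_test <- function(sets, universe, n_perm = 2000L, seed = 1L,
                                     tail = c("less", "greater", "two-sided")) {
  tail <- match.arg(tail)
  stopifnot(is.list(sets), n_perm >= 100L)
  sets <- lapply(sets, unique)
  if (!all(vapply(sets, function(s) all(s %in% universe), logical(1)))) {
    abort_atlasrep("permutation_overlap_test(): sets must be subsets of the universe")
  }
  obs <- length(Reduce(intersect, sets))
  sizes <- lengths(sets)
  if (length(sets) == 1L) {
    return(new_test_result(obs, 1, "permutation overlap", tail,
                           c(n_sets = 1L, n_perm = 0L), expected = obs))
  }
  null_sizes <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    length(Reduce(intersect, lapply(sizes, function(k) sample(universe, k))))
  }, numeric(1)))
  expected <- mean(null_sizes)
  p_less <- (1 + sum(null_sizes <= obs)) / (n_perm + 1)
  p_greater <- (1 + sum(null_sizes >= obs)) / (n_perm + 1)
  p <- switch(tail,
    "less" = p_less, "greater" = p_greater,
    "two-sided" = min(1, 2 * min(p_less, p_greater)))
  new_test_result(obs, p, "permutation overlap", tail,
                  c(n_sets = length(sets), n_perm = n_perm), expected = expected)
}
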