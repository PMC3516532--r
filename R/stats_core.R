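#' Empirical (permutation) p-value with the add-one convention
#'
#' Computes `p = (1 + b) / (N + 1)` where `b` is the number of null values at
#' least as extreme as the observed statistic. The add-one convention
#' guarantees the p-value is never exactly zero from a finite number of
#' permutations. For `tail = "two_sided"` the smaller of the two one-sided
#' p-values is doubled and capped at 1, so ties are counted in both tails.
#'
#' @param observed Observed statistic (length-1 numeric).
#' @param null_values Numeric vector of statistics under the null; must be
#'   non-empty.
#' @param tail One of `"ge"`, `"le"`, `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_values, tail = c("ge", "le", "two_sided")) {
  tail <- match.arg(tail)
  if (length(null_values) == 0L) stop("empty null set: need at least one null value")
  stopifnot(length(observed) == 1L, is.finite(observed))
  n <- length(null_values)
  p_ge <- (1 + sum(null_values >= observed)) / (n + 1)
  p_le <- (1 + sum(null_values <= observed)) / (n + 1)
  switch(tail,
    ge = p_ge,
    le = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Step-up procedure: with ordered p-values p_(1) <= ... <= p_(m), reject all
#' hypotheses up to the largest k with p_(k) <= (k/m) q. q-values are the
#' monotone (cumulative-minimum from the largest rank) adjusted p-values
#' `p_(k) m / k`, so `reject == (q_value <= q)`.
#'
#' @param p_values Numeric vector of p-values, all in (0, 1].
#' @param q Target FDR level in (0, 1).
#' @return List with `reject` (logical) and `q_values` (numeric), in input
#'   order.
#' @export
benjamini_hochberg <- function(p_values, q = 0.10) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  qv_sorted <- rev(cummin(rev(pmin(ranked, 1))))
  q_values <- numeric(m)
  q_values[ord] <- qv_sorted
  list(reject = q_values <= q, q_values = q_values)
}

#' Z-score normalization with the population standard deviation
#'
#' Centers to mean zero and scales by the population (divide-by-n) standard
#' deviation, as appropriate when normalizing over a complete gene universe
#' rather than a sample.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Normalized vector with mean 0 and population SD 1.
#' @export
zscore_normalize <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  mu <- mean(values)
  sd_pop <- sqrt(mean((values - mu)^2))
  if (sd_pop == 0) stop("degenerate spread: input is constant")
  (values - mu) / sd_pop
}

#' Fold enrichment of a count against a background proportion, exact binomial p
#'
#' fold = (k/n) / p0. The p-value is the exact binomial tail: upper tail
#' P(X >= k) when fold >= 1 (direction "over"), lower tail P(X <= k)
#' otherwise (direction "under").
#'
#' @param k Successes in the gene set.
#' @param n Set size (> 0).
#' @param p0 Background proportion in (0, 1).
#' @return An `enrichment_result` list: observed, null_mean, fold, p_value,
#'   direction.
#' @export
fold_enrichment_binomial <- function(k, n, p0) {
  if (n == 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  prop <- k / n
  fold <- prop / p0
  if (fold >= 1) {
    p <- sum(stats::dbinom(k:n, n, p0))
    direction <- "over"
  } else {
    p <- sum(stats::dbinom(0:k, n, p0))
    direction <- "under"
  }
  enrichment_result(observed = prop, null_mean = p0, fold = fold,
                    p_value = min(1, p), direction = direction)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the probabilities of tables no more probable
#' than the observed one (the standard two-sided definition).
#'
#' @param tab 2x2 numeric matrix of non-negative counts; every row and column
#'   margin must be positive.
#' @return List with `odds_ratio` (sample odds ratio ad/bc, possibly Inf) and
#'   `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  r <- rowSums(tab); cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) stop("undefined test: zero margin")
  a <- tab[1, 1]
  k_min <- max(0, cs[1] - r[2])
  k_max <- min(r[1], cs[1])
  ks <- k_min:k_max
  probs <- stats::dhyper(ks, r[1], r[2], cs[1])
  p_obs <- stats::dhyper(a, r[1], r[2], cs[1])
  # relative tolerance guards against FP noise when comparing equal densities
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = unname(or), p_value = unname(min(1, p)))
}

#' Construct an enrichment result record
#'
#' Shared container for observed-vs-null comparisons: the observed statistic,
#' the null mean (or background proportion), their ratio, and the p-value
#' (q-value added after FDR control).
#'
#' @param observed Observed statistic.
#' @param null_mean Null mean or background proportion.
#' @param fold observed / null_mean.
#' @param p_value p-value in (0, 1].
#' @param direction "over" or "under".
#' @param q_value Optional BH q-value.
#' @return A list of class `enrichment_result`.
#' @export
enrichment_result <- function(observed, null_mean, fold, p_value,
                              direction = c("over", "under"), q_value = NA_real_) {
  direction <- match.arg(direction)
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(observed = observed, null_mean = null_mean, fold = fold,
                 p_value = p_value, q_value = q_value, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: observed %.4g, null %.4g, fold %.3g (%s), p = %.3g",
              x$observed, x$null_mean, x$fold, x$direction, x$p_value))
  if (!is.na(x$q_value)) cat(sprintf(", q = %.3g", x$q_value))
  cat("\n")
  invisible(x)
}
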