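# Mixture-of-Bernoulli clustering of binary fusion functional profiles, with
# cross-validated selection of the number of clusters.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

component_loglik <- function(x, log_theta, log_1m_theta, log_pi) {
  # n x k matrix of log pi_k + sum_j [ x log theta + (1-x) log(1-theta) ]
  ll <- x %*% log_theta + (1 - x) %*% log_1m_theta
  sweep(ll, 2, log_pi, `+`)
}

#' Fit a mixture of independent Bernoulli components by EM
#'
#' Diagonal (independent-bit) Bernoulli mixture fitted by
#' expectation-maximization with multiple random restarts; the fit with the
#' best training log-likelihood is returned. Component probabilities are
#' clamped to `[clamp, 1 - clamp]` to keep the likelihood finite on degenerate
#' bits.
#'
#' @param x Binary matrix (n x d).
#' @param k Number of components.
#' @param restarts Random restarts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param clamp Probability clamp (default 1e-4).
#' @return List of class `bernoulli_mixture`: pi, theta (k x d), loglik,
#'   responsibilities (n x k), assignments (argmax responsibility), k.
#' @export
fit_bernoulli_mixture <- function(x, k, restarts = 10, max_iter = 500,
                                  tol = 1e-8, clamp = 1e-4) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of profiles")
  best <- NULL
  for (r in seq_len(restarts)) {
    theta <- matrix(stats::runif(k * d, 0.25, 0.75), k, d)
    pi_k <- rep(1 / k, k)
    ll_prev <- -Inf
    for (iter in seq_len(max_iter)) {
      cll <- component_loglik(x, t(log(theta)), t(log(1 - theta)), log(pi_k))
      norm <- logsumexp_rows(cll)
      ll <- sum(norm)
      resp <- exp(cll - norm)
      nk <- colSums(resp)
      pi_k <- nk / n
      theta <- (t(resp) %*% x) / nk
      theta <- pmin(pmax(theta, clamp), 1 - clamp)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) break
      ll_prev <- ll
    }
    # final E-step, then one closing M-step so the exported theta is exactly
    # the responsibility-weighted bit mean of the exported responsibilities
    cll <- component_loglik(x, t(log(theta)), t(log(1 - theta)), log(pi_k))
    norm <- logsumexp_rows(cll)
    ll <- sum(norm)
    if (is.null(best) || ll > best$loglik) {
      resp <- exp(cll - norm)
      nk <- colSums(resp)
      theta_out <- pmin(pmax((t(resp) %*% x) / nk, clamp), 1 - clamp)
      best <- list(pi = nk / n, theta = theta_out, loglik = ll,
                   responsibilities = resp,
                   assignments = max.col(resp, ties.method = "first"), k = k)
    }
  }
  class(best) <- "bernoulli_mixture"
  best
}

#' Held-out log-likelihood of binary profiles under a fitted mixture
#' @param model `bernoulli_mixture`.
#' @param x Binary matrix.
#' @return Total log-likelihood of `x`.
#' @export
loglik_bernoulli_mixture <- function(model, x) {
  x <- as.matrix(x)
  cll <- component_loglik(x, t(log(model$theta)), t(log(1 - model$theta)),
                          log(model$pi))
  sum(logsumexp_rows(cll))
}

#' Cluster fusion functional profiles with CV-selected number of clusters
#'
#' Fits Bernoulli mixtures of increasing size, scoring each k by the mean
#' held-out log-likelihood over `n_folds` cross-validation folds, and stops
#' growing k at the first value that does not improve the CV score; the last
#' improving k is selected and refitted on all profiles. Deterministic given
#' `seed`.
#'
#' @param profiles Binary matrix (n x 10 for 5'/3' x D/P/H/K/O indicators) or
#'   a profile data.frame from [fusion_profiles()] (bit columns are
#'   extracted).
#' @param seed Integer seed.
#' @param max_k Largest k considered.
#' @param n_folds CV folds (default 10; requires at least n_folds profiles).
#' @param restarts EM restarts per fit.
#' @return List: k (selected), model (`bernoulli_mixture` refit on all data),
#'   assignments, cluster_probs (k x d indicator probabilities), cv_loglik
#'   (named vector over candidate k).
#' @export
cluster_functional_profiles <- function(profiles, seed = 1, max_k = 10,
                                        n_folds = 10, restarts = 10) {
  if (max_k < 1) stop("max_k must be >= 1")
  x <- profile_bits(profiles)
  n <- nrow(x)
  if (n < n_folds) stop("need at least n_folds profiles")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  cv <- numeric(0)
  k_best <- 1L
  for (k in seq_len(min(max_k, n - ceiling(n / n_folds)))) {
    score <- 0
    for (f in seq_len(n_folds)) {
      train <- x[fold != f, , drop = FALSE]
      test <- x[fold == f, , drop = FALSE]
      if (k > nrow(train)) { score <- -Inf; break }
      m <- fit_bernoulli_mixture(train, k, restarts = restarts)
      score <- score + loglik_bernoulli_mixture(m, test)
    }
    score <- score / n
    cv[as.character(k)] <- score
    if (k == 1L || score > cv[as.character(k_best)] + 1e-9) {
      k_best <- k
    } else {
      break
    }
  }
  model <- fit_bernoulli_mixture(x, k_best, restarts = restarts)
  colnames(model$theta) <- colnames(x)
  list(k = k_best, model = model, assignments = model$assignments,
       cluster_probs = model$theta, cv_loglik = cv)
}

# extract the 10 bit columns from a fusion_profiles() data.frame, or pass a
# plain binary matrix through
profile_bits <- function(profiles) {
  if (is.matrix(profiles)) {
    storage.mode(profiles) <- "double"
    return(profiles)
  }
  cols <- c(paste0("five_", CATEGORIES), paste0("three_", CATEGORIES))
  if (!all(cols %in% names(profiles))) {
    stop("profiles must be a binary matrix or carry the 10 indicator columns")
  }
  as.matrix(profiles[, cols])
}
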