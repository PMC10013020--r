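#' Nearest-neighbor differential entropy estimators
#'
#' `knn_entropy()` is the Kozachenko-Leonenko estimator under the maximum
#' norm: for `N` samples of dimension `d` it returns
#' `-digamma(k) + digamma(N) + (d/N) * sum(log(2 * eps_i))` in nats, where
#' `eps_i` is the max-norm distance from sample `i` to its k-th nearest
#' neighbor among the other samples (the max-norm ball of radius `eps` has
#' volume `(2 eps)^d`).
#'
#' `knn_cross_entropy()` is the companion cross-entropy estimate: neighbor
#' distances are measured from each evaluation sample to its k-th nearest
#' neighbor within a separate reference sample, giving
#' `-digamma(k) + digamma(N_ref) + (d/N_eval) * sum(log(2 * eps_i))`.
#' Evaluation rows are never searched against themselves. By the
#' non-negativity of Kullback-Leibler divergence the cross-entropy dominates
#' the entropy of the evaluation distribution up to estimator error.
#'
#' @param samples,eval_samples,ref_samples numeric matrix (rows = samples) or
#'   an `embedding_set`.
#' @param k number of neighbors (the estimator's only tuning parameter).
#' @return entropy estimate in nats.
#' @examples
#' set.seed(1)
#' m <- matrix(runif(2000), ncol = 2)
#' knn_entropy(m, k = 5)   # true value: 0 nats
#' @export
knn_entropy <- function(samples, k) {
  m <- embedding_matrix(samples)
  k <- check_k(k)
  n <- nrow(m)
  if (n < k + 1)
    stop("need at least k + 1 = ", k + 1, " samples, got ", n, call. = FALSE)
  eps <- knn_max_dist(m, m, k, TRUE)
  if (any(eps <= 0))
    stop("zero k-th neighbor distance: duplicate samples; apply jitter",
         call. = FALSE)
  -digamma(k) + digamma(n) + (ncol(m) / n) * sum(log(2 * eps))
}

#' @rdname knn_entropy
#' @export
knn_cross_entropy <- function(eval_samples, ref_samples, k) {
  me <- embedding_matrix(eval_samples)
  mr <- embedding_matrix(ref_samples)
  k <- check_k(k)
  if (ncol(me) != ncol(mr))
    stop("eval and reference samples must have the same dimension",
         call. = FALSE)
  if (nrow(mr) < k)
    stop("reference set needs at least k = ", k, " samples", call. = FALSE)
  eps <- knn_max_dist(me, mr, k, FALSE)
  if (any(eps <= 0))
    stop("zero k-th neighbor distance: duplicate samples; apply jitter",
         call. = FALSE)
  -digamma(k) + digamma(nrow(mr)) + (ncol(me) / nrow(me)) * sum(log(2 * eps))
}

check_k <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k
}

# Deterministic seeded jitter applied to embedding matrices before neighbor
# searches: amplitude 1e-8 times the per-column standard deviation. Breaks
# exact ties from quantized timestamps; negligible against physiological
# variability.
jitter_matrix <- function(m, seed) {
  s <- apply(m, 2, stats::sd)
  s[!is.finite(s)] <- 0
  with_seed(seed, m + matrix(rnorm(length(m)), nrow(m)) %*% diag(1e-8 * s,
                                                                 ncol(m)))
}
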