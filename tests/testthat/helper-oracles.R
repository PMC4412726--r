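# Independent oracles: naive direct-formula implementations used to verify
# the package's numerically careful paths. These deliberately avoid the
# package's internal helpers.

# Gaussian density by determinant/inverse, straight from the definition.
naive_gauss_pdf <- function(x, mu, sigma) {
  d <- length(mu)
  sigma <- matrix(sigma, d, d)
  xc <- as.numeric(x - mu)
  as.numeric(exp(-0.5 * t(xc) %*% solve(sigma) %*% xc) /
               sqrt((2 * pi)^d * det(sigma)))
}

# Mixture log-likelihood by direct summation (no log-sum-exp).
naive_loglik <- function(X, params) {
  sum(apply(X, 1, function(x) {
    log(sum(vapply(seq_len(params$K), function(k)
      params$pi[k] * naive_gauss_pdf(x, params$mu[k, ],
                                     params$sigma[, , k]), numeric(1))))
  }))
}

# Posterior responsibilities by direct Bayes rule.
naive_estep <- function(X, params) {
  t(apply(X, 1, function(x) {
    w <- vapply(seq_len(params$K), function(k)
      params$pi[k] * naive_gauss_pdf(x, params$mu[k, ],
                                     params$sigma[, , k]), numeric(1))
    w / sum(w)
  }))
}

# AUC by exhaustive pair counting over all positive-negative pairs.
naive_auc <- function(scores, truth, positive) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Random symmetric positive-definite matrix.
random_spd <- function(d) {
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) + diag(d) * 0.5
}

# Random valid mixture parameter set.
random_params <- function(K, d) {
  pi_k <- runif(K) + 0.1
  pi_k <- pi_k / sum(pi_k)
  mu <- matrix(rnorm(K * d, sd = 2), K, d)
  sigma <- array(0, c(d, d, K))
  for (k in seq_len(K)) sigma[, , k] <- random_spd(d)
  list(K = K, pi = pi_k, mu = mu, sigma = sigma)
}

# Tiny block atlas: a shape split into nx slabs along x, labelled 1..nx.
slab_atlas <- function(shape = c(6L, 5L, 4L), nx = 3L) {
  labels <- array(0L, dim = shape)
  cuts <- round(seq(0, shape[1L], length.out = nx + 1L))
  for (i in seq_len(nx))
    labels[(cuts[i] + 1L):cuts[i + 1L], , ] <- i
  brain_atlas(labels, stats::setNames(paste0("Slab_", seq_len(nx)),
                                      seq_len(nx)))
}

# Shared small phantom cohort for pipeline tests (cached per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(phantom_spec(seed = 42L),
                                c(NC = 6L, MCI = 6L, AD = 6L))
    cache
  }
})
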