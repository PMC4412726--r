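# Gaussian mixture modelling with EM and BIC/AIC model selection.
#
# All likelihood work is done in log space: component log-densities come
# from a Cholesky factorization (never exponentiating the raw density), and
# mixture log-likelihoods use the log-sum-exp trick with the largest
# weighted component factored out, so fits stay finite on data whose raw
# densities underflow or overflow a double.

#' Log-density of a multivariate Gaussian
#'
#' Evaluated via the Cholesky factor of the covariance; works on a single
#' point or row-wise on a matrix of points.
#'
#' @param x Numeric vector of length D, or an N x D matrix.
#' @param mu Mean vector of length D.
#' @param sigma D x D symmetric positive-definite covariance matrix.
#' @return Log-density value(s).
#' @export
gaussian_logpdf <- function(x, mu, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  d <- length(mu)
  stopifnot(ncol(x) == d, nrow(sigma) == d, ncol(sigma) == d)
  R <- tryCatch(chol(sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  xc <- x - matrix(mu, nrow(x), d, byrow = TRUE)
  z <- backsolve(R, t(xc), transpose = TRUE)
  maha <- .colSums(z * z, d, nrow(x))
  logdet <- 2 * sum(log(diag(R)))
  drop(-0.5 * (d * log(2 * pi) + logdet + maha))
}

# N x K matrix of log(pi_k) + log N(x_i | mu_k, sigma_k). Components with
# pi_k = 0 get a -Inf column and so contribute nothing to any log-sum.
.log_weight_matrix <- function(X, params) {
  n <- nrow(X)
  W <- matrix(-Inf, n, params$K)
  for (k in seq_len(params$K)) {
    if (params$pi[k] > 0)
      W[, k] <- log(params$pi[k]) +
        gaussian_logpdf(X, params$mu[k, ], params$sigma[, , k])
  }
  W
}

# Row-wise log-sum-exp with the row maximum factored out.
.row_lse <- function(W) {
  m <- W[, 1L]
  if (ncol(W) > 1L) for (k in 2:ncol(W)) m <- pmax(m, W[, k])
  m + log(.rowSums(exp(W - m), nrow(W), ncol(W)))
}

#' Mixture log-likelihood
#'
#' Sum over points of the log mixture density, computed with the
#' log-sum-exp trick (the largest weighted component density is factored
#' out of the inner sum) for numerical stability.
#'
#' @param X N x D data matrix.
#' @param params A `gmm_params` list with elements `K`, `pi` (length K),
#'   `mu` (K x D), `sigma` (D x D x K).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(X, params) {
  X <- as.matrix(X)
  sum(.row_lse(.log_weight_matrix(X, params)))
}

#' E-step: posterior component responsibilities
#'
#' Posterior probability of each component for each point, computed in log
#' space and normalized per row.
#'
#' @inheritParams log_likelihood
#' @return N x K matrix with rows summing to 1.
#' @export
e_step <- function(X, params) {
  X <- as.matrix(X)
  W <- .log_weight_matrix(X, params)
  m <- W[, 1L]
  if (ncol(W) > 1L) for (k in 2:ncol(W)) m <- pmax(m, W[, k])
  P <- exp(W - m)
  P / .rowSums(P, nrow(P), ncol(P))
}

# E-step and log-likelihood from one pass over the data.
.e_step_ll <- function(X, params) {
  W <- .log_weight_matrix(X, params)
  m <- W[, 1L]
  if (ncol(W) > 1L) for (k in 2:ncol(W)) m <- pmax(m, W[, k])
  P <- exp(W - m)
  s <- .rowSums(P, nrow(P), ncol(P))
  list(resp = P / s, loglik = sum(m + log(s)))
}

#' M-step: parameter updates from responsibilities
#'
#' Mixing proportions are mean responsibilities; means are
#' responsibility-weighted averages; covariances are the
#' responsibility-weighted scatter around the updated means (weight-
#' normalized), with a small ridge `reg` added to the diagonal to keep
#' thin point configurations positive definite.
#'
#' @param X N x D data matrix.
#' @param resp N x K responsibility matrix.
#' @param reg Non-negative ridge added to each covariance diagonal.
#' @return A `gmm_params` list.
#' @export
m_step <- function(X, resp, reg = 0) {
  X <- as.matrix(X)
  resp <- as.matrix(resp)
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  nk <- .colSums(resp, n, K)
  if (any(nk < 1e-12))
    stop("degenerate component: total responsibility below 1e-12", call. = FALSE)
  pi_k <- nk / n
  mu <- crossprod(resp, X) / nk
  sigma <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    xc <- X - matrix(mu[k, ], n, d, byrow = TRUE)
    sigma[, , k] <- crossprod(xc * resp[, k], xc) / nk[k] + diag(reg, d)
  }
  structure(list(K = K, pi = pi_k, mu = mu, sigma = sigma),
            class = "gmm_params")
}

# Farthest-point seeding: the first center is a random data point, each
# subsequent one the point farthest from all chosen centers; a small jitter
# decouples centers from exact data points.
.init_responsibilities <- function(X, K) {
  n <- nrow(X); d <- ncol(X)
  first <- sample.int(n, 1L)
  idx <- integer(K)
  idx[1L] <- first
  mind <- .rowSums((X - matrix(X[first, ], n, d, byrow = TRUE))^2, n, d)
  if (K > 1L) for (k in 2:K) {
    idx[k] <- which.max(mind)
    dk <- .rowSums((X - matrix(X[idx[k], ], n, d, byrow = TRUE))^2, n, d)
    mind <- pmin(mind, dk)
  }
  centers <- X[idx, , drop = FALSE] +
    matrix(stats::rnorm(K * d, sd = 0.01 * pmax(apply(X, 2, stats::sd), 1e-8)),
           K, d, byrow = TRUE)
  d2 <- matrix(0, n, K)
  for (k in seq_len(K))
    d2[, k] <- .rowSums((X - matrix(centers[k, ], n, d, byrow = TRUE))^2, n, d)
  lab <- max.col(-d2, ties.method = "first")
  lab[idx] <- seq_len(K)  # each seed point anchors its own component
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), lab)] <- 1
  resp
}

#' Fit a Gaussian mixture model by EM
#'
#' Best-of-restarts EM with farthest-point seeding. Convergence is declared
#' when the absolute log-likelihood change drops below `tol`. The fit is
#' deterministic given `seed`; the caller's RNG state is left untouched.
#' `K = 1` is solved in closed form (sample mean and weight-normalized
#' scatter) in a single iteration.
#'
#' @param X N x D data matrix (N >= K).
#' @param K Number of mixture components (>= 1).
#' @param seed Integer seed controlling initialization.
#' @param n_restarts Number of independently seeded EM runs; the run with
#'   the highest final log-likelihood wins.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param reg Covariance ridge; default `1e-6` times the mean marginal data
#'   variance.
#' @return An object of class `gmm_fit` with elements `params`, `loglik`,
#'   `trajectory` (per-iteration log-likelihoods), `n_iter`, `converged`,
#'   `seed`, `n`, `d`, `reg`.
#' @export
fit_gmm <- function(X, K, seed = 1L, n_restarts = 3L, tol = 1e-6,
                    max_iter = 300L, reg = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (n < K) stop("need at least K data points", call. = FALSE)
  if (is.null(reg)) {
    reg <- 1e-6 * mean(apply(X, 2, stats::var))
    if (!is.finite(reg) || reg <= 0) reg <- 1e-10
  }

  finish <- function(params, traj, converged) {
    structure(list(params = params, loglik = traj[length(traj)],
                   trajectory = traj, n_iter = length(traj),
                   converged = converged, seed = seed, n = n, d = d,
                   reg = reg),
              class = "gmm_fit")
  }

  if (K == 1L) {
    mu <- matrix(colMeans(X), 1L, d)
    xc <- X - matrix(mu, n, d, byrow = TRUE)
    sigma <- array(crossprod(xc) / n + diag(reg, d), dim = c(d, d, 1L))
    params <- structure(list(K = 1L, pi = 1, mu = mu, sigma = sigma),
                        class = "gmm_params")
    return(finish(params, log_likelihood(X, params), TRUE))
  }

  # The iteration loop runs in compiled code (src/em.cpp); it applies the
  # same updates as e_step()/m_step() above. Initialization stays in R so
  # all randomness flows through R's RNG.
  run_once <- function(restart_seed) {
    resp <- with_seed(restart_seed, .init_responsibilities(X, K))
    res <- .em_run(X, resp, reg, tol, as.integer(max_iter))
    if (!identical(res$status, "ok"))
      stop("degenerate component: total responsibility below 1e-12",
           call. = FALSE)
    params <- structure(list(K = K, pi = as.numeric(res$pi),
                             mu = res$mu,
                             sigma = array(res$sigma, dim = c(d, d, K))),
                        class = "gmm_params")
    list(params = params, traj = as.numeric(res$trajectory),
         converged = res$converged)
  }

  best <- NULL
  errors <- character(0)
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(run_once(derive_seed(seed, r)),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, res)
      next
    }
    if (is.null(best) || res$traj[length(res$traj)] >
          best$traj[length(best$traj)]) best <- res
  }
  if (is.null(best))
    stop(sprintf("EM failed for K = %d in all %d restarts (%s)", K,
                 n_restarts, errors[1L]), call. = FALSE)
  finish(best$params, best$traj, best$converged)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K = %d, D = %d, N = %d\n",
              x$params$K, x$d, x$n))
  cat(sprintf("  log-likelihood %.4f after %d iteration(s)%s\n", x$loglik,
              x$n_iter, if (x$converged) " (converged)" else " (max iter)"))
  invisible(x)
}

#' @export
summary.gmm_fit <- function(object, ...) {
  p <- free_param_count(object$params$K, object$d)
  cat(sprintf("Gaussian mixture fit (K = %d, D = %d, N = %d)\n",
              object$params$K, object$d, object$n))
  cat(sprintf("  log-likelihood: %.4f  free parameters: %d\n",
              object$loglik, p))
  cat(sprintf("  BIC: %.4f  AIC: %.4f\n",
              bic(object$loglik, object$n, p), aic(object$loglik, p)))
  cat("  mixing proportions:", paste(sprintf("%.3f", object$params$pi),
                                     collapse = " "), "\n")
  invisible(object)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$loglik,
            df = free_param_count(object$params$K, object$d),
            nobs = object$n, class = "logLik")
}

#' Predict component memberships from a mixture fit
#'
#' @param object A `gmm_fit`.
#' @param newdata N x D matrix of points.
#' @param type `"class"` for hard component labels (ties to the lowest
#'   index) or `"resp"` for the posterior responsibility matrix.
#' @param ... Unused.
#' @export
predict.gmm_fit <- function(object, newdata,
                            type = c("class", "resp"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (type == "resp") e_step(X, object$params) else
    assign_labels(X, object$params)
}

#' Simulate draws from a fitted mixture
#'
#' @param object A `gmm_fit`.
#' @param nsim Number of points to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return N x D matrix of draws with a `component` attribute.
#' @export
simulate.gmm_fit <- function(object, nsim = 1, seed = 1L, ...) {
  pc <- gmm_point_cloud(object$params$K, object$params$pi, object$params$mu,
                        object$params$sigma, nsim, seed)
  structure(pc$X, component = pc$labels)
}

#' Hard component assignment
#'
#' Argmax of the posterior responsibility per point; ties go to the lowest
#' component index.
#'
#' @inheritParams log_likelihood
#' @return Integer vector of component indices in `1..K`.
#' @export
assign_labels <- function(X, params) {
  X <- as.matrix(X)
  W <- .log_weight_matrix(X, params)
  max.col(W, ties.method = "first")
}

#' Free-parameter count of a K-component D-dimensional Gaussian mixture
#'
#' `K - 1` mixing proportions, `K * D` means and `K * D * (D + 1) / 2`
#' covariance entries, i.e. `K * D * (D + 3) / 2 + K - 1`.
#'
#' @param K Number of components (>= 1).
#' @param D Data dimension (>= 1).
#' @return Integer parameter count.
#' @export
free_param_count <- function(K, D) {
  if (any(K < 1) || any(D < 1)) stop("K and D must be >= 1", call. = FALSE)
  as.integer(K * D * (D + 3) / 2 + K - 1)
}

#' Bayesian information criterion
#'
#' @param loglik Model log-likelihood.
#' @param n Number of data points.
#' @param p Number of free parameters.
#' @return `-2 * loglik + log(n) * p` (natural log); lower is better.
#' @export
bic <- function(loglik, n, p) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  -2 * loglik + log(n) * p
}

#' Akaike information criterion
#'
#' @inheritParams bic
#' @return `-2 * loglik + 2 * p`; lower is better.
#' @export
aic <- function(loglik, p) -2 * loglik + 2 * p

#' Select the number of mixture components by BIC or AIC
#'
#' Fits a mixture for every K in `k_grid` and picks the K minimizing the
#' chosen criterion; ties break toward smaller K. Ks whose fit fails
#' (persistent degeneracy across restarts) are skipped with a warning.
#'
#' @param X N x D data matrix.
#' @param k_grid Integer vector of candidate component counts.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param seed Integer seed; each K gets a deterministically derived
#'   sub-seed.
#' @param ... Passed to [fit_gmm()] (`n_restarts`, `tol`, `max_iter`, `reg`).
#' @return An object of class `gmm_selection` with per-K scores, the chosen
#'   K, and the per-K fits.
#' @export
select_k <- function(X, k_grid, criterion = c("bic", "aic"), seed = 1L, ...) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (!length(k_grid)) stop("k_grid is empty", call. = FALSE)
  if (any(k_grid > nrow(X)))
    stop("every K in k_grid must be <= N", call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  fits <- vector("list", length(k_grid))
  bic_v <- aic_v <- ll_v <- rep(NA_real_, length(k_grid))
  p_v <- free_param_count(k_grid, d)
  for (i in seq_along(k_grid)) {
    fit <- tryCatch(fit_gmm(X, k_grid[i], seed = derive_seed(seed, k_grid[i]),
                            ...),
                    error = function(e) {
                      warning(sprintf("K = %d skipped: %s", k_grid[i],
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    fits[[i]] <- fit
    if (!is.null(fit)) {
      ll_v[i] <- fit$loglik
      bic_v[i] <- bic(fit$loglik, n, p_v[i])
      aic_v[i] <- aic(fit$loglik, p_v[i])
    }
  }
  score <- if (criterion == "bic") bic_v else aic_v
  if (all(is.na(score)))
    stop("model selection failed: no K could be fitted", call. = FALSE)
  chosen <- k_grid[which.min(score)]  # first minimum = smallest K on ties
  structure(list(k_grid = k_grid, bic = bic_v, aic = aic_v, loglik = ll_v,
                 P = p_v, chosen_k = chosen, criterion = criterion,
                 fits = fits, seed = seed, n = n, d = d),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("Mixture model selection over K in {%s} by %s\n",
              paste(range(x$k_grid), collapse = "..."),
              toupper(x$criterion)))
  cat(sprintf("  chosen K = %d (N = %d, D = %d)\n", x$chosen_k, x$n, x$d))
  invisible(x)
}

#' @export
summary.gmm_selection <- function(object, ...) {
  print(object)
  tab <- data.frame(K = object$k_grid, loglik = object$loglik, P = object$P,
                    BIC = object$bic, AIC = object$aic)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' Plot BIC/AIC scores against the number of components
#'
#' @param x A `gmm_selection`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gmm_selection <- function(x, ...) {
  graphics::matplot(x$k_grid, cbind(x$bic, x$aic), type = "b", pch = c(1, 4),
                    lty = 1, col = c("black", "red3"),
                    xlab = "number of components K",
                    ylab = "information criterion", ...)
  graphics::abline(v = x$chosen_k, lty = 3)
  graphics::legend("topright", c("BIC", "AIC"), pch = c(1, 4),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Grade the strength of evidence of a BIC difference
#'
#' Conventional Bayes-factor grading of a difference between two BIC
#' scores: 0-2 weak, 2-6 positive, 6-10 strong, above 10 very strong
#' (boundaries fall in the lower band).
#'
#' @param bic_difference Non-negative BIC difference(s).
#' @return Character vector of grades.
#' @export
grade_evidence <- function(bic_difference) {
  if (any(bic_difference < 0))
    stop("BIC difference must be non-negative", call. = FALSE)
  as.character(cut(bic_difference, c(-Inf, 2, 6, 10, Inf),
                   labels = c("weak", "positive", "strong", "very strong"),
                   right = TRUE))
}
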