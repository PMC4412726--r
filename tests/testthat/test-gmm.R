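test_that("gaussian_logpdf matches the analytic value at the mean", {
  expect_equal(gaussian_logpdf(c(0, 0, 0), c(0, 0, 0), diag(3)),
               -1.5 * log(2 * pi))
  expect_equal(gaussian_logpdf(0, 0, matrix(1)), -0.5 * log(2 * pi))
  expect_error(gaussian_logpdf(c(0, 0), c(0, 0),
                               matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("gaussian_logpdf agrees with the determinant/inverse formula", {
  set.seed(11)
  for (i in 1:20) {
    d <- sample(1:4, 1)
    mu <- rnorm(d)
    sigma <- random_spd(d)
    x <- rnorm(d, sd = 3)
    expect_equal(gaussian_logpdf(x, mu, sigma),
                 log(naive_gauss_pdf(x, mu, sigma)), tolerance = 1e-10)
  }
})

test_that("log_likelihood reduces correctly for trivial mixtures", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  p1 <- list(K = 1L, pi = 1, mu = matrix(0, 1, 3),
             sigma = array(diag(3), c(3, 3, 1)))
  expect_equal(log_likelihood(X, p1),
               sum(gaussian_logpdf(X, rep(0, 3), diag(3))))
  # two identical components collapse to one
  p2 <- list(K = 2L, pi = c(0.5, 0.5), mu = matrix(0, 2, 3),
             sigma = array(diag(3), c(3, 3, 2)))
  expect_equal(log_likelihood(X, p2), log_likelihood(X, p1),
               tolerance = 1e-12)
})

test_that("zero-weight components are excluded, not NaN", {
  set.seed(13)
  X <- matrix(rnorm(30), 10, 3)
  p <- list(K = 2L, pi = c(1, 0), mu = rbind(rep(0, 3), rep(100, 3)),
            sigma = array(diag(3), c(3, 3, 2)))
  ll <- log_likelihood(X, p)
  expect_true(is.finite(ll))
  p1 <- list(K = 1L, pi = 1, mu = matrix(0, 1, 3),
             sigma = array(diag(3), c(3, 3, 1)))
  expect_equal(ll, log_likelihood(X, p1))
})

test_that("e_step rows are posteriors matching direct Bayes rule", {
  set.seed(14)
  X <- matrix(rnorm(45), 15, 3)
  params <- random_params(3, 3)
  resp <- e_step(X, params)
  expect_equal(rowSums(resp), rep(1, 15), tolerance = 1e-9)
  expect_true(all(resp >= 0 & resp <= 1))
  expect_equal(resp, naive_estep(X, params), tolerance = 1e-10,
               ignore_attr = TRUE)
  # K = 1: all ones
  p1 <- list(K = 1L, pi = 1, mu = matrix(0, 1, 3),
             sigma = array(diag(3), c(3, 3, 1)))
  expect_equal(as.numeric(e_step(X, p1)), rep(1, 15))
})

test_that("a point equidistant between mirror components splits 50/50", {
  p <- list(K = 2L, pi = c(0.5, 0.5), mu = rbind(c(-2, 0), c(2, 0)),
            sigma = array(diag(2), c(2, 2, 2)))
  resp <- e_step(matrix(c(0, 5), 1, 2), p)
  expect_equal(as.numeric(resp), c(0.5, 0.5))
})

test_that("m_step reproduces per-cluster statistics from hard assignments", {
  set.seed(15)
  X <- matrix(rnorm(90), 30, 3)
  lab <- rep(1:3, each = 10)
  resp <- matrix(0, 30, 3)
  resp[cbind(1:30, lab)] <- 1
  eps <- 1e-6
  params <- m_step(X, resp, reg = eps)
  for (k in 1:3) {
    Xk <- X[lab == k, ]
    expect_equal(params$mu[k, ], colMeans(Xk), ignore_attr = TRUE)
    xc <- sweep(Xk, 2, colMeans(Xk))
    expect_equal(params$sigma[, , k],
                 crossprod(xc) / nrow(Xk) + diag(eps, 3))
    expect_equal(params$pi[k], 1 / 3, ignore_attr = TRUE)
  }
})

test_that("m_step with uniform responsibilities collapses to the global mean", {
  set.seed(16)
  X <- matrix(rnorm(40), 20, 2)
  resp <- matrix(0.5, 20, 2)
  params <- m_step(X, resp)
  expect_equal(params$pi, c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(params$mu[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(params$mu[2, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(sum(params$pi), 1)
  expect_error(m_step(X, cbind(rep(1, 20), 0)), "degenerate")
})

test_that("compiled EM iterations match the R-level E/M updates", {
  set.seed(17)
  X <- matrix(rnorm(120), 40, 3)
  resp0 <- matrix(0, 40, 2)
  resp0[cbind(1:40, rep(1:2, 20))] <- 1
  reg <- 1e-6
  res <- petroi:::.em_run(X, resp0, reg, 1e-6, 1L)
  params_r <- m_step(X, resp0, reg)
  expect_equal(res$trajectory[1], log_likelihood(X, params_r),
               tolerance = 1e-10)
})

test_that("fit_gmm solves K = 1 in closed form", {
  set.seed(18)
  X <- matrix(rnorm(60), 20, 3)
  fit <- fit_gmm(X, 1)
  expect_s3_class(fit, "gmm_fit")
  expect_equal(fit$n_iter, 1L)
  expect_true(fit$converged)
  expect_equal(fit$params$mu[1, ], colMeans(X), ignore_attr = TRUE)
  xc <- sweep(X, 2, colMeans(X))
  expect_equal(fit$params$sigma[, , 1],
               crossprod(xc) / 20 + diag(fit$reg, 3))
  expect_equal(fit$loglik, log_likelihood(X, fit$params))
})

test_that("fit_gmm recovers two well-separated blobs", {
  pc <- gmm_point_cloud(2, c(0.5, 0.5), rbind(c(0, 0, 0), c(10, 0, 0)),
                        array(diag(3), c(3, 3, 2)), 500, seed = 19)
  fit <- fit_gmm(pc$X, 2, seed = 20)
  lab <- predict(fit, pc$X)
  agree <- max(mean(lab == pc$labels), mean(lab != pc$labels))
  expect_gte(agree, 0.99)
})

test_that("fit_gmm is deterministic given its seed", {
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3)
  f1 <- fit_gmm(X, 3, seed = 5)
  f2 <- fit_gmm(X, 3, seed = 5)
  expect_equal(f1$params, f2$params)
  expect_equal(f1$trajectory, f2$trajectory)
})

test_that("free_param_count matches independent enumeration for K, D <= 10", {
  expect_identical(free_param_count(1, 3), 9L)
  expect_identical(free_param_count(2, 3), 19L)
  expect_identical(free_param_count(1, 1), 2L)
  for (K in 1:10) for (D in 1:10) {
    enum <- (K - 1) + K * D + K * D * (D + 1) / 2
    expect_identical(free_param_count(K, D), as.integer(enum))
  }
  expect_error(free_param_count(0, 3), ">= 1")
})

test_that("bic and aic follow their defining arithmetic", {
  expect_equal(bic(0, 10, 0), 0)
  expect_equal(aic(0, 0), 0)
  expect_equal(bic(-500, 100, 10), 1000 + log(100) * 10)
  expect_equal(aic(-500, 10), 1020)
  # BIC - AIC = (log N - 2) P, positive iff N > e^2
  for (N in c(5, 7, 8, 100)) {
    d <- bic(-50, N, 6) - aic(-50, 6)
    expect_equal(d, (log(N) - 2) * 6)
    expect_identical(d > 0, N > exp(2))
  }
})

test_that("evidence grading respects the band boundaries", {
  expect_identical(grade_evidence(1), "weak")
  expect_identical(grade_evidence(4), "positive")
  expect_identical(grade_evidence(8), "strong")
  expect_identical(grade_evidence(11), "very strong")
  # boundaries fall in the lower band
  expect_identical(grade_evidence(c(0, 2, 6, 10, 10.01)),
                   c("weak", "weak", "positive", "strong", "very strong"))
  expect_error(grade_evidence(-1), "non-negative")
})

test_that("assign_labels is the argmax of the posterior", {
  set.seed(22)
  X <- matrix(rnorm(60, sd = 3), 20, 3)
  params <- random_params(3, 3)
  lab <- assign_labels(X, params)
  resp <- naive_estep(X, params)
  expect_identical(lab, apply(resp, 1, which.max))
  p1 <- list(K = 1L, pi = 1, mu = matrix(0, 1, 3),
             sigma = array(diag(3), c(3, 3, 1)))
  expect_identical(unique(assign_labels(X, p1)), 1L)
  # a point at a far component's mean belongs to it
  far <- random_params(2, 3)
  far$mu <- rbind(rep(0, 3), rep(50, 3))
  far$sigma <- array(diag(3), c(3, 3, 2))
  expect_identical(assign_labels(matrix(rep(50, 3), 1), far), 2L)
})

test_that("select_k picks the criterion argmin with ties toward smaller K", {
  set.seed(23)
  X <- matrix(rnorm(150), 50, 3)
  sel <- select_k(X, 1, seed = 2)
  expect_identical(sel$chosen_k, 1L)
  expect_s3_class(sel, "gmm_selection")
  sel2 <- select_k(X, c(1, 2, 3), seed = 2)
  expect_identical(sel2$chosen_k,
                   sel2$k_grid[which.min(sel2$bic)])
  expect_error(select_k(X, integer(0)), "empty")
  expect_error(select_k(X, 51), "<= N")
})

test_that("model object methods are coherent", {
  set.seed(24)
  X <- matrix(rnorm(200), 100, 2)
  fit <- fit_gmm(X, 2, seed = 3)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_identical(attr(ll, "df"), free_param_count(2, 2))
  expect_equal(AIC(fit), aic(fit$loglik, free_param_count(2, 2)))
  expect_equal(BIC(fit), bic(fit$loglik, 100, free_param_count(2, 2)))
  resp <- predict(fit, X, type = "resp")
  expect_equal(rowSums(resp), rep(1, 100), tolerance = 1e-9)
  sim <- simulate(fit, nsim = 50, seed = 4)
  expect_identical(dim(sim), c(50L, 2L))
  expect_output(print(fit), "Gaussian mixture fit")
})
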