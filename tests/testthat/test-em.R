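two_blobs <- function(n_per = 100, centers = c(-10, 10), sd = 0.5,
                      d = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(c0) {
    matrix(rnorm(n_per * d, mean = c0, sd = sd), ncol = d)
  }))
  list(X = X, truth = rep(seq_along(centers), each = n_per))
}

test_that("responsibilities match direct weighted-density evaluation", {
  model <- mixture_model(weights = c(0.3, 0.7),
                         means = matrix(c(0, 2), ncol = 1),
                         stds = matrix(c(1, 0.5), ncol = 1))
  x <- c(-1, 0.5, 3)
  a <- e_step(model, matrix(x, ncol = 1))
  # independent brute-force computation
  for (i in seq_along(x)) {
    un <- c(0.3 * dnorm(x[i], 0, 1), 0.7 * dnorm(x[i], 2, 0.5))
    expect_equal(a$responsibilities[i, ], un / sum(un), tolerance = 1e-12)
  }
  expect_equal(a$loglik,
               sum(log(0.3 * dnorm(x, 0, 1) + 0.7 * dnorm(x, 2, 0.5))),
               tolerance = 1e-10)
})

test_that("single component and symmetric points give degenerate posteriors", {
  m1 <- mixture_model(1, matrix(0), matrix(1))
  a1 <- e_step(m1, matrix(c(-3, 0, 5), ncol = 1))
  expect_true(all(a1$responsibilities == 1))

  m2 <- mixture_model(c(0.5, 0.5), matrix(c(-2, 2), ncol = 1),
                      matrix(c(1, 1), ncol = 1))
  a2 <- e_step(m2, matrix(0, ncol = 1))
  expect_equal(as.numeric(a2$responsibilities), c(0.5, 0.5),
               tolerance = 1e-12)

  expect_error(e_step(m1, matrix(NaN)), "non-finite")
})

test_that("m-step reproduces weighted statistics computed by hand", {
  x <- c(1, 2, 4, 8)
  R <- cbind(c(0.9, 0.8, 0.3, 0.1), c(0.1, 0.2, 0.7, 0.9))
  m <- m_step(list(responsibilities = R), matrix(x, ncol = 1))
  for (k in 1:2) {
    nk <- sum(R[, k])
    mu <- sum(R[, k] * x) / nk
    v <- sum(R[, k] * (x - mu)^2) / nk
    expect_equal(m$weights[k], nk / 4, tolerance = 1e-12)
    expect_equal(m$means[k, 1], mu, tolerance = 1e-12)
    expect_equal(m$stds[k, 1], sqrt(v), tolerance = 1e-12)
  }
})

test_that("hard and uniform responsibilities give group and global stats", {
  x <- c(0, 1, 10, 12)
  hard <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  m <- m_step(list(responsibilities = hard), matrix(x, ncol = 1))
  expect_equal(m$means[, 1], c(0.5, 11))
  expect_equal(m$stds[, 1], c(0.5, 1))  # MLE std within each group

  unif <- matrix(0.5, 4, 2)
  mu_all <- mean(x)
  sd_all <- sqrt(mean((x - mu_all)^2))
  m2 <- m_step(list(responsibilities = unif), matrix(x, ncol = 1))
  expect_equal(m2$means[, 1], rep(mu_all, 2))
  expect_equal(m2$stds[, 1], rep(sd_all, 2), tolerance = 1e-12)
  expect_equal(m2$weights, c(0.5, 0.5))
})

test_that("one full EM iteration equals hand-computed E and M updates", {
  x <- c(-1.2, 0.3, 0.9, 2.5)
  X <- matrix(x, ncol = 1)
  model <- mixture_model(c(0.4, 0.6), matrix(c(-1, 2), ncol = 1),
                         matrix(c(0.8, 1.5), ncol = 1))
  a <- e_step(model, X)
  R_hand <- t(vapply(x, function(xi) {
    un <- c(0.4 * dnorm(xi, -1, 0.8), 0.6 * dnorm(xi, 2, 1.5))
    un / sum(un)
  }, numeric(2)))
  expect_equal(a$responsibilities, R_hand, tolerance = 1e-10)

  m <- m_step(a, X)
  for (k in 1:2) {
    nk <- sum(R_hand[, k])
    mu <- sum(R_hand[, k] * x) / nk
    v <- sum(R_hand[, k] * (x - mu)^2) / nk
    expect_equal(m$weights[k], nk / 4, tolerance = 1e-10)
    expect_equal(m$means[k, 1], mu, tolerance = 1e-10)
    expect_equal(m$stds[k, 1], sqrt(v), tolerance = 1e-10)
  }
})

test_that("K = 1 converges immediately to the closed-form Gaussian fit", {
  set.seed(41)
  x <- rnorm(50, mean = 3, sd = 2)
  fit <- fit_em(matrix(x, ncol = 1), 1, em_config(seed = 1, n_init = 1))
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  expect_equal(tail(fit$model$loglik_trace, 1),
               sum(dnorm(x, mu, s, log = TRUE)), tolerance = 1e-8)
  expect_lte(length(fit$model$loglik_trace), 3L)
  expect_true(fit$model$converged)
})

test_that("well-separated blobs are recovered exactly up to permutation", {
  b <- two_blobs(seed = 42)
  fit <- fit_em(b$X, 2, em_config(seed = 7))
  lab <- fit$assignment$hard_labels
  agree <- max(mean(lab == b$truth), mean(lab == 3 - b$truth))
  expect_equal(agree, 1.0)
  # estimated means within 3 standard errors of the truth
  se <- 0.5 / sqrt(100)
  expect_equal(sort(fit$model$means[, 1]), c(-10, 10), tolerance = 3 * se)
  expect_true(all(diff(fit$model$loglik_trace) >=
                    -1e-9 * pmax(1, abs(fit$model$loglik_trace[-1]))))
})

test_that("identical rows receive identical responsibilities", {
  set.seed(43)
  X <- matrix(rnorm(40), ncol = 2)
  X <- rbind(X, X[1:5, ])
  fit <- fit_em(X, 3, em_config(seed = 5))
  R <- fit$assignment$responsibilities
  for (i in 1:5) expect_equal(R[20 + i, ], R[i, ], tolerance = 1e-12)
})

test_that("weights stay on the simplex and responsibilities normalized", {
  set.seed(44)
  for (rep in 1:5) {
    X <- matrix(rnorm(60 * 2, sd = sample(1:3, 1)), ncol = 2)
    fit <- fit_em(X, sample(2:4, 1), em_config(seed = rep, n_init = 2))
    expect_equal(sum(fit$model$weights), 1, tolerance = 1e-12)
    expect_true(all(fit$model$stds >= 1e-6))
    expect_equal(rowSums(fit$assignment$responsibilities),
                 rep(1, nrow(X)), tolerance = 1e-12)
  }
})

test_that("final likelihood agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  b <- two_blobs(n_per = 80, centers = c(-5, 5), sd = 1, d = 2, seed = 45)
  fit <- fit_em(b$X, 2, em_config(seed = 1))
  mc <- mclust::Mclust(b$X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(tail(fit$model$loglik_trace, 1), mc$loglik, tolerance = 0.5,
               ignore_attr = TRUE)
})

test_that("errors: K out of range and too few rows for cross-validation", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(fit_em(X, 11, em_config()), "exceeds")
  expect_error(fit_em(X, 0, em_config()), ">= 1")
  expect_error(select_k_cv(matrix(rnorm(5), ncol = 1),
                           em_config(cv_folds = 10)), "at least")
})

test_that("cross-validated selection returns 1 for structureless data", {
  set.seed(46)
  X <- matrix(rnorm(120), ncol = 2)  # one tight blob
  sel <- select_k_cv(X, em_config(seed = 3, n_init = 2, k_max = 4))
  expect_equal(sel$best_k, 1L)

  sel1 <- select_k_cv(X, em_config(seed = 3, n_init = 2, k_max = 1))
  expect_equal(sel1$best_k, 1L)
  expect_length(sel1$cv_curve, 1L)
})

test_that("mixture models survive a JSON round trip", {
  m <- mixture_model(c(0.25, 0.75), matrix(c(0, 3, 1, 2), 2),
                     matrix(c(1, 2, 0.5, 0.1), 2),
                     loglik_trace = c(-10, -8), converged = TRUE)
  path <- tempfile(fileext = ".json")
  write_mixture_model(m, path)
  m2 <- read_mixture_model(path)
  expect_equal(m2$means, m$means, ignore_attr = TRUE)
  expect_equal(m2$stds, m$stds, ignore_attr = TRUE)
  expect_equal(m2$weights, m$weights)
})
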