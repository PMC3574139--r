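#' EM clustering configuration
#'
#' @param max_iter maximum EM iterations per fit (default 100).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param min_std per-dimension standard-deviation floor (default 1e-6),
#'   mirroring the diagonal-Gaussian EM of the Weka tradition.
#' @param n_init random restarts; the fit with the best final log-likelihood
#'   wins (default 5).
#' @param seed integer seed; every source of randomness (initialization,
#'   restarts, fold assignment) flows from it.
#' @param cv_folds folds for cross-validated selection of the cluster count
#'   (default 10).
#' @param k_max upper bound on the cluster count searched (default 15).
#' @return a list of class `em_config`.
#' @export
em_config <- function(max_iter = 100L, tol = 1e-6, min_std = 1e-6,
                      n_init = 5L, seed = 1L, cv_folds = 10L, k_max = 15L) {
  cfg <- list(max_iter = as.integer(max_iter), tol = tol, min_std = min_std,
              n_init = as.integer(n_init), seed = as.integer(seed),
              cv_folds = as.integer(cv_folds), k_max = as.integer(k_max))
  if (cfg$max_iter < 1 || cfg$tol <= 0 || cfg$min_std <= 0 ||
      cfg$n_init < 1 || cfg$k_max < 1) {
    stop("em_config: max_iter, tol, min_std, n_init, k_max must be positive")
  }
  if (cfg$cv_folds < 2) stop("em_config: cv_folds must be >= 2")
  structure(cfg, class = "em_config")
}

#' Construct a diagonal-Gaussian mixture model object
#'
#' @param weights mixing proportions (length K, summing to 1).
#' @param means,stds K x d matrices of component means and standard
#'   deviations (diagonal covariance).
#' @param loglik_trace per-iteration total log-likelihood (optional).
#' @param converged logical flag.
#' @return object of class `mixture_model`.
#' @export
mixture_model <- function(weights, means, stds, loglik_trace = numeric(0),
                          converged = NA) {
  means <- as.matrix(means); stds <- as.matrix(stds)
  K <- length(weights)
  stopifnot(nrow(means) == K, nrow(stds) == K,
            ncol(means) == ncol(stds))
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(stds <= 0)) stop("mixture stds must be positive")
  structure(list(K = K, weights = as.numeric(weights), means = means,
                 stds = stds, loglik_trace = loglik_trace,
                 converged = converged),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K = %d, d = %d, final loglik = %s\n",
              x$K, ncol(x$means),
              if (length(x$loglik_trace)) format(tail(x$loglik_trace, 1))
              else "NA"))
  invisible(x)
}

# n x K matrix of per-component log densities + log weight, computed in
# log-space for stability. The quadratic form is expanded so the whole
# matrix comes from two BLAS products:
#   sum_j (x_ij - mu_kj)^2 / sd_kj^2
#     = sum_j x_ij^2 / sd_kj^2 - 2 sum_j x_ij mu_kj / sd_kj^2 + c_k
log_component_density <- function(model, X, X2 = X * X) {
  d <- ncol(X)
  P <- 1 / (model$stds * model$stds)            # K x d precisions
  A <- -0.5 * t(P)                              # d x K
  B <- t(model$means * P)                       # d x K
  ck <- -0.5 * rowSums(model$means^2 * P) - rowSums(log(model$stds)) -
    0.5 * d * log(2 * pi) + log(model$weights)
  L <- X2 %*% A + X %*% B
  L + rep(ck, each = nrow(X))
}

logsumexp_rows <- function(L) {
  m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  m + log(rowSums(exp(L - m)))
}

#' Expectation step
#'
#' Computes the posterior responsibility of each mixture component for each
#' row: r_ik proportional to weight_k times the product over dimensions of
#' Normal(x_ij; mean_kj, std_kj), rows normalized to 1. All density algebra
#' is done in log space.
#'
#' @param model a [mixture_model].
#' @param X numeric matrix (rows = observations).
#' @return object of class `cluster_assignment`: list with
#'   `responsibilities` (n x K), `hard_labels` (argmax per row) and `loglik`
#'   (total log-likelihood of `X` under `model`).
#' @export
e_step <- function(model, X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("e_step: input contains non-finite values")
  if (ncol(X) != ncol(model$means)) stop("e_step: dimension mismatch")
  estep_core(model, X, X * X)
}

estep_core <- function(model, X, X2) {
  L <- log_component_density(model, X, X2)
  lse <- logsumexp_rows(L)
  R <- exp(L - lse)
  structure(list(responsibilities = R,
                 hard_labels = max.col(R, ties.method = "first"),
                 loglik = sum(lse)),
            class = "cluster_assignment")
}

#' Maximization step
#'
#' Re-estimates mixture parameters from responsibilities: each weight is the
#' mean responsibility of its component, each mean the
#' responsibility-weighted average, each standard deviation the square root
#' of the responsibility-weighted variance floored at `min_std`. A component
#' whose total responsibility underflows to zero is reinitialized from a
#' random data row (logged via `message()` when
#' `options(medtopic.verbose = TRUE)`).
#'
#' @param assignment a [e_step()] result (or any list with a
#'   `responsibilities` matrix).
#' @param X numeric matrix the responsibilities refer to.
#' @param min_std standard-deviation floor.
#' @return a [mixture_model] (with empty `loglik_trace`).
#' @export
m_step <- function(assignment, X, min_std = 1e-6) {
  X <- as.matrix(X)
  R <- assignment$responsibilities
  stopifnot(nrow(R) == nrow(X))
  n <- nrow(X); K <- ncol(R)
  Nk <- colSums(R)
  dead <- which(Nk < n * 1e-12)
  if (length(dead) > 0) {
    if (isTRUE(getOption("medtopic.verbose", FALSE))) {
      message(sprintf("m_step: reinitializing %d empty component(s)",
                      length(dead)))
    }
    for (k in dead) {
      i <- sample.int(n, 1L)
      R[, k] <- 0
      R[i, k] <- 1
      R <- R / rowSums(R)
    }
    Nk <- colSums(R)
  }
  weights <- Nk / n
  means <- t(R) %*% X / Nk
  ex2 <- t(R) %*% (X * X) / Nk
  vars <- pmax(ex2 - means^2, min_std^2)
  mixture_model(weights, means, sqrt(vars))
}

# k-means++-style seeding: first mean uniform, later means drawn with
# probability proportional to squared distance from the nearest chosen mean
kmeanspp_means <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1], ], `-`)^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        idx[k] <- sample.int(n, 1L)
      } else {
        idx[k] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[k], ], `-`)^2))
    }
  }
  X[idx, , drop = FALSE]
}

em_single_fit <- function(X, K, config) {
  n <- nrow(X)
  means <- kmeanspp_means(X, K)
  gstd <- pmax(apply(X, 2L, sd), config$min_std)
  if (n == 1) gstd <- rep(config$min_std, ncol(X))
  model <- mixture_model(rep(1 / K, K), means,
                         matrix(gstd, K, ncol(X), byrow = TRUE))
  X2 <- X * X
  trace <- numeric(0)
  converged <- FALSE
  assign <- NULL
  for (it in seq_len(config$max_iter)) {
    assign <- estep_core(model, X, X2)
    trace <- c(trace, assign$loglik)
    if (it > 1 && (assign$loglik - trace[it - 1]) < config$tol) {
      converged <- TRUE
      break
    }
    model <- m_step(assign, X, config$min_std)
  }
  model$loglik_trace <- trace
  model$converged <- converged
  list(model = model, assignment = assign)
}

#' Fit a diagonal-Gaussian mixture by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] from a seeded k-means++-style
#' initialization (means drawn from data rows, global per-dimension standard
#' deviations, uniform weights) until the log-likelihood improvement falls
#' below `tol` or `max_iter` is reached; the best of `n_init` restarts by
#' final log-likelihood is returned. The log-likelihood trace is
#' non-decreasing up to numerical slack — the signature of a correct EM.
#'
#' @param X numeric matrix (rows = observations, e.g. PCA scores).
#' @param K number of mixture components; must not exceed `nrow(X)`.
#' @param config an [em_config()].
#' @return list with elements `model` (a [mixture_model]) and `assignment`
#'   (a `cluster_assignment` for `X` under the final model).
#' @export
fit_em <- function(X, K, config = em_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(X)) {
    stop(sprintf("K = %d exceeds the number of rows (%d)", K, nrow(X)))
  }
  if (!all(is.finite(X))) stop("fit_em: input contains non-finite values")
  set.seed(config$seed)
  best <- NULL
  for (init in seq_len(config$n_init)) {
    fit <- em_single_fit(X, K, config)
    if (is.null(best) ||
        tail(fit$model$loglik_trace, 1) > tail(best$model$loglik_trace, 1)) {
      best <- fit
    }
  }
  # refresh the assignment under the winning model
  best$assignment <- e_step(best$model, X)
  best
}

#' Select the number of clusters by cross-validated likelihood
#'
#' Starting at K = 1, rows are split into `cv_folds` folds by a seeded
#' permutation; for each K the mixture is fitted on each training split and
#' the mean held-out per-row log-likelihood is recorded. K is incremented
#' while that score strictly improves; the K preceding the first
#' non-improvement is returned (ties favor the smaller, more parsimonious
#' K), with a hard stop at `k_max`.
#'
#' @param X numeric matrix.
#' @param config an [em_config()].
#' @return list with `best_k` and `cv_curve` (named numeric vector of mean
#'   held-out per-row log-likelihood, one entry per K tried).
#' @export
select_k_cv <- function(X, config = em_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < config$cv_folds) {
    stop(sprintf("need at least cv_folds = %d rows, got %d",
                 config$cv_folds, n))
  }
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$cv_folds), n))
  curve <- numeric(0)
  best_k <- 1L
  for (K in seq_len(config$k_max)) {
    holdout <- numeric(0)
    feasible <- TRUE
    for (f in seq_len(config$cv_folds)) {
      train <- X[fold != f, , drop = FALSE]
      test <- X[fold == f, , drop = FALSE]
      if (nrow(train) < K) { feasible <- FALSE; break }
      cfg_f <- config
      cfg_f$seed <- (config$seed + 7919L * K + f) %% .Machine$integer.max
      fit <- fit_em(train, K, cfg_f)
      lse <- logsumexp_rows(log_component_density(fit$model, test))
      holdout <- c(holdout, lse)
    }
    if (!feasible) break
    score <- mean(holdout)
    curve <- c(curve, setNames(score, as.character(K)))
    if (K > 1 && score <= curve[K - 1]) break
    best_k <- K
  }
  list(best_k = best_k, cv_curve = curve)
}

#' Serialize / restore a mixture model as JSON
#' @param model a `mixture_model`.
#' @param path JSON file path.
#' @export
write_mixture_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, d = ncol(model$means), weights = model$weights,
         means = as.numeric(t(model$means)),   # row-major flat
         stds = as.numeric(t(model$stds)),
         loglik_trace = model$loglik_trace, converged = model$converged),
    path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_mixture_model
#' @export
read_mixture_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mixture_model(as.numeric(obj$weights),
                matrix(as.numeric(obj$means), nrow = obj$K, ncol = obj$d,
                       byrow = TRUE),
                matrix(as.numeric(obj$stds), nrow = obj$K, ncol = obj$d,
                       byrow = TRUE),
                loglik_trace = as.numeric(obj$loglik_trace),
                converged = isTRUE(obj$converged))
}
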