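#' Fit a principal-component reduction
#'
#' Centers the columns (no unit-variance scaling: the counts share units)
#' and computes components by singular-value decomposition of the centered
#' matrix. The retained set is the smallest leading set of components whose
#' cumulative explained-variance ratio reaches `coverage_target`. For
#' determinism each component's largest-magnitude loading is made positive.
#'
#' @param matrix a `feature_matrix` or a plain numeric matrix.
#' @param coverage_target fraction of total variance to cover, in (0, 1];
#'   default 0.95.
#' @param max_components optional hard cap on the number of retained
#'   components (applied after the coverage rule).
#' @return object of class `pca_model`: list with `mean`, `components`
#'   (retained components as rows, orthonormal), `explained_variance_ratio`,
#'   `coverage_target`.
#' @export
fit_pca <- function(matrix, coverage_target = 0.95, max_components = NULL) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("PCA requires at least 2 rows")
  if (!(coverage_target > 0 && coverage_target <= 1)) {
    stop("coverage_target must be in (0, 1]")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (ncol(Xc) > nrow(Xc)) {
    # wide matrices: eigendecompose the n x n Gram matrix and recover the
    # right singular vectors; numerically equivalent to the direct SVD
    G <- tcrossprod(Xc)
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values, 0) * 1e-12
    d_sv <- sqrt(pmax(eg$values, 0))
    V <- crossprod(Xc, eg$vectors[, pos, drop = FALSE])
    V <- sweep(V, 2L, d_sv[pos], `/`)
    sv <- list(d = d_sv, v = V)
  } else {
    sv <- svd(Xc, nu = 0)
  }
  eig <- sv$d^2 / (nrow(X) - 1)
  total <- sum(eig)
  if (total <= .Machine$double.eps * ncol(X)) {
    stop("matrix has zero total variance; PCA is undefined")
  }
  ratio <- eig / total
  # numerical rank: drop components that explain (numerically) nothing
  rank <- sum(eig > max(eig) * 1e-12)
  cum <- cumsum(ratio)
  m <- which(cum >= coverage_target - 1e-12)[1]
  if (is.na(m)) m <- rank
  m <- max(1L, min(m, rank))
  if (!is.null(max_components)) m <- min(m, as.integer(max_components))
  comps <- t(sv$v[, seq_len(m), drop = FALSE])
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(m)) {
    j <- which.max(abs(comps[k, ]))
    if (comps[k, j] < 0) comps[k, ] <- -comps[k, ]
  }
  structure(list(mean = mu, components = comps,
                 explained_variance_ratio = ratio[seq_len(m)],
                 coverage_target = coverage_target),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s) covering %.1f%% of variance\n",
              nrow(x$components), 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project data onto retained principal components
#'
#' @param model a [fit_pca()] result.
#' @param matrix a `feature_matrix` or numeric matrix with the same columns
#'   as the training data.
#' @return numeric matrix, rows = input rows, columns = retained components.
#' @export
pca_transform <- function(model, matrix) {
  stopifnot(inherits(model, "pca_model"))
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(model$mean)) {
    stop(sprintf("dimension mismatch: model has %d columns, input has %d",
                 length(model$mean), ncol(X)))
  }
  sweep(X, 2L, model$mean) %*% t(model$components)
}

#' Reconstruct data from its principal-component projection
#'
#' @param model a [fit_pca()] result.
#' @param scores projection matrix from [pca_transform()].
#' @return matrix in the original feature space.
#' @export
pca_reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  sweep(scores %*% model$components, 2L, model$mean, `+`)
}

#' Serialize / restore a PCA model as JSON
#' @param model a `pca_model`.
#' @param path JSON file path.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(n_components = nrow(model$components),
         n_features = ncol(model$components),
         mean = model$mean,
         components = as.numeric(t(model$components)),  # row-major flat
         explained_variance_ratio = model$explained_variance_ratio,
         coverage_target = model$coverage_target),
    path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  comps <- matrix(as.numeric(obj$components), nrow = obj$n_components,
                  ncol = obj$n_features, byrow = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 components = comps,
                 explained_variance_ratio = as.numeric(obj$explained_variance_ratio),
                 coverage_target = obj$coverage_target),
            class = "pca_model")
}
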