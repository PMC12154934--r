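#' @title Real-versus-random separability
#' @description
#' Sanity check that attribution matrices carry structure: an RBF-kernel
#' support-vector classifier trained on 80% of a pooled set of real
#' attribution matrices and moment-matched Gaussian random matrices should
#' separate the two classes on the held-out 20%. Matrices of varying size
#' are brought to a common representation by bilinear resampling to a fixed
#' grid and flattening.
#' @name separability
NULL

#' Bilinear resampling of a matrix to a fixed grid
#'
#' @param M Numeric matrix.
#' @param out_rows,out_cols Output grid size (default 32 x 32).
#' @return An `out_rows x out_cols` matrix.
#' @export
bilinear_resize <- function(M, out_rows = 32, out_cols = 32) {
  n <- nrow(M); m <- ncol(M)
  if (n < 2 || m < 2) abort("`M` must be at least 2 x 2")
  ri <- seq(1, n, length.out = out_rows)
  ci <- seq(1, m, length.out = out_cols)
  r0 <- pmin(floor(ri), n - 1); fr <- ri - r0
  c0 <- pmin(floor(ci), m - 1); fc <- ci - c0
  A <- M[r0, c0] * outer(1 - fr, 1 - fc) +
    M[r0 + 1, c0] * outer(fr, 1 - fc) +
    M[r0, c0 + 1] * outer(1 - fr, fc) +
    M[r0 + 1, c0 + 1] * outer(fr, fc)
  A
}

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin RBF-kernel SVM
#'
#' Standard C-SVC dual, solved as a quadratic program
#' (via [quadprog::solve.QP()]): maximize `sum(alpha) - 1/2 alpha' Q alpha`
#' with `Q = (y y') * K`, subject to `0 <= alpha <= C` and
#' `sum(alpha * y) = 0`; the bias is recovered from the margin support
#' vectors.
#'
#' @param X Feature matrix (rows = observations).
#' @param y Labels in `{-1, +1}`.
#' @param C Box constraint (default 1).
#' @param gamma RBF width; `"scale"` (default) uses `1 / (d * var(X))` as
#'   in common SVM implementations.
#' @return A list of class `rbf_svm` with the support-vector expansion.
#' @export
rbf_svm_fit <- function(X, y, C = 1, gamma = "scale") {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * max(v, .Machine$double.eps))
  }
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Dmat <- (y %*% t(y)) * K + diag(1e-8, n)
  dvec <- rep(1, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  margin <- sv & alpha < C - 1e-6
  f_no_b <- as.vector(K %*% (alpha * y))
  b <- if (any(margin)) {
    mean(y[margin] - f_no_b[margin])
  } else {
    mean(y[sv] - f_no_b[sv])
  }
  structure(list(X_sv = X[sv, , drop = FALSE], coef = (alpha * y)[sv],
                 b = b, gamma = gamma, C = C),
            class = "rbf_svm")
}

#' Predict class labels from a fitted RBF SVM
#'
#' @param object An `rbf_svm` fit.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Vector of labels in `{-1, +1}`.
#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  K <- rbf_kernel(newdata, object$X_sv, object$gamma)
  f <- as.vector(K %*% object$coef) + object$b
  ifelse(f >= 0, 1, -1)
}

#' Held-out accuracy of the real-versus-random separability check
#'
#' For every supplied attribution matrix one moment-matched Gaussian random
#' matrix (same dimensions, same mean and standard deviation) is generated;
#' all matrices are featurized by bilinear resampling to a fixed grid and
#' flattening, features are standardized on the training split, and an
#' RBF-kernel SVM is trained on a seeded 80% split and evaluated on the
#' rest.
#'
#' @param real_matrices List of at least 20 numeric matrices.
#' @param seed Integer seed controlling the matched random matrices and the
#'   split.
#' @param train_fraction Training fraction (default 0.8).
#' @param grid_size Resampling grid (default 32).
#' @param C,gamma SVM hyperparameters (see [rbf_svm_fit()]).
#' @return A one-row tibble: `accuracy` (held-out), `n_real`, `n_random`,
#'   `n_train`, `n_test`.
#' @export
random_separability_check <- function(real_matrices, seed = 1,
                                      train_fraction = 0.8, grid_size = 32,
                                      C = 1, gamma = "scale") {
  if (!is.list(real_matrices) || length(real_matrices) < 20) {
    abort("need at least 20 real matrices")
  }
  n_real <- length(real_matrices)
  random_matrices <- lapply(seq_len(n_real), function(i) {
    M <- real_matrices[[i]]
    s <- sd(as.vector(M))
    generate_random_matrix(nrow(M), ncol(M), mean(M), max(s, 1e-12),
                           seed = seed + i)
  })
  all_mats <- c(real_matrices, random_matrices)
  feats <- t(vapply(all_mats, function(M) {
    as.vector(bilinear_resize(M, grid_size, grid_size))
  }, numeric(grid_size^2)))
  labels <- c(rep(1, n_real), rep(-1, n_real))
  n_all <- nrow(feats)
  idx_train <- withr::with_seed(as.integer(seed), {
    sample.int(n_all, size = round(train_fraction * n_all))
  })
  mu <- colMeans(feats[idx_train, , drop = FALSE])
  sg <- apply(feats[idx_train, , drop = FALSE], 2, sd)
  sg[sg < 1e-12] <- 1
  scale_feats <- function(F0) sweep(sweep(F0, 2, mu), 2, sg, "/")
  Xtr <- scale_feats(feats[idx_train, , drop = FALSE])
  Xte <- scale_feats(feats[-idx_train, , drop = FALSE])
  if (all(!is.finite(Xtr)) || sd(as.vector(Xtr)) == 0) {
    abort("degenerate features")
  }
  fit <- rbf_svm_fit(Xtr, labels[idx_train], C = C, gamma = gamma)
  pred <- predict(fit, Xte)
  tibble(
    accuracy = mean(pred == labels[-idx_train]),
    n_real = n_real, n_random = n_real,
    n_train = length(idx_train), n_test = n_all - length(idx_train)
  )
}
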