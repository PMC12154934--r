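#' @title Explanation infidelity
#' @description
#' Infidelity scores an explanation by how well it linearly predicts the
#' model's response to perturbations: for a scalar predictor `f`, input `x`
#' and attribution map `phi`,
#' `INFD = E[ (I . phi - (f(x) - f(x - I)))^2 ]` with `I` a Gaussian
#' perturbation (mean 0, sd 0.01 by default, applied in raw activation
#' units). The embedding-mode aggregate `INFD_E` is the plain mean of the
#' per-output-element infidelity matrix `I_E`; the prediction-mode
#' aggregate `INFD_P` combines `I_E` with the per-residue vector `I_P`
#' through a window-weighted sum whose printed denominator,
#' `(n - 2w)(2w+1) + w(3w+1)`, differs from the algebraic value of the sum
#' it annotates (`sum_{i=w+1}^{2w} i = w(3w+1)/2`); both variants are
#' available and the as-printed one is the default.
#' @name infidelity
NULL

#' Perturbation specification
#'
#' @param sd Gaussian perturbation standard deviation (default 0.01, the
#'   published choice, in raw activation units).
#' @param n_samples Monte-Carlo draws (the published count is unstated;
#'   default 100).
#' @param seed Integer seed; draws are a pure function of the seed and the
#'   input dimension, so per-scalar recomputation is bit-reproducible.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(sd = 0.01, n_samples = 100, seed = 1) {
  if (sd <= 0) abort("perturbation `sd` must be > 0")
  if (n_samples < 1) abort("`n_samples` must be >= 1")
  structure(list(sd = sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

draw_perturbations <- function(spec, d) {
  # row-per-draw fill: the first m draws are identical for any n_samples
  # >= m (common random numbers), so enlarging the sample refines rather
  # than replaces the estimate
  withr::with_seed(spec$seed, {
    t(matrix(rnorm(spec$n_samples * d, 0, spec$sd), d, spec$n_samples))
  })
}

# residuals and mean-square, shared by the scalar and batched paths so both
# are bit-identical given the same function-value differences
infidelity_from_diffs <- function(draws, phi, f_diffs) {
  phi_vec <- as.vector(phi)
  resid <- vapply(seq_len(nrow(draws)), function(s) {
    sum(draws[s, ] * phi_vec) - f_diffs[s]
  }, numeric(1))
  mean(resid^2)
}

#' Monte-Carlo explanation infidelity of one attribution map
#'
#' @param f Scalar function of an input shaped like `x` (e.g. a handle's
#'   `scalar_forward` closed over a selector).
#' @param x Test input (any array shape).
#' @param phi Attribution map, same shape as `x`.
#' @param perturbation A [perturbation_spec()].
#' @return Non-negative scalar infidelity estimate.
#' @examples
#' h <- linear_handle(matrix(1:4, 2, 2))
#' x <- matrix(rnorm(4), 2, 2)
#' infidelity_score(h$forward, x, matrix(1:4, 2, 2),
#'                  perturbation_spec(n_samples = 10)) # exactly 0
#' @export
infidelity_score <- function(f, x, phi, perturbation = perturbation_spec()) {
  if (length(phi) != length(x)) abort("`phi` must be shaped like `x`")
  draws <- draw_perturbations(perturbation, length(x))
  f_x <- f(x)
  f_diffs <- vapply(seq_len(nrow(draws)), function(s) {
    xp <- x
    xp[] <- as.vector(x) - draws[s, ]
    fv <- f(xp)
    if (!is.finite(fv)) abort("non-finite model evaluation under perturbation")
    f_x - fv
  }, numeric(1))
  infidelity_from_diffs(draws, phi, f_diffs)
}

#' Embedding-mode infidelity matrix and aggregate
#'
#' Applies [infidelity_score()] to every output element `(i, k)` of an
#' embedder, perturbing the embedding-layer output activations, and
#' aggregates to `INFD_E = mean(I_E)`. The perturbation draws are shared
#' across output elements (they depend only on the seed and input
#' dimension), which is exactly what per-scalar recomputation with the same
#' spec produces.
#'
#' @param handle An embedder `model_handle`.
#' @param x Input activations (`n x e`).
#' @param per_scalar_attributions Either the full attribution tensor `E`
#'   (`n x e x n x e`) or a nested list `maps[[i]][[k]]` of `n x e` maps.
#' @param perturbation A [perturbation_spec()].
#' @return A list of class `infidelity_record` with `I_E` (`n x e`),
#'   `INFD_E`, and the spec.
#' @export
embedding_infidelity <- function(handle, x, per_scalar_attributions,
                                 perturbation = perturbation_spec()) {
  n <- nrow(x); e <- ncol(x)
  get_map <- function(i, k) {
    if (is.array(per_scalar_attributions) &&
        length(dim(per_scalar_attributions)) == 4) {
      per_scalar_attributions[i, k, , ]
    } else {
      row <- if (i <= length(per_scalar_attributions)) {
        per_scalar_attributions[[i]]
      } else NULL
      m <- if (!is.null(row) && k <= length(row)) row[[k]] else NULL
      if (is.null(m)) abort(sprintf("missing map for output (%d, %d)", i, k))
      m
    }
  }
  draws <- draw_perturbations(perturbation, n * e)
  O_x <- handle$forward(x)
  O_pert <- lapply(seq_len(nrow(draws)), function(s) {
    xp <- x
    xp[] <- as.vector(x) - draws[s, ]
    handle$forward(xp)
  })
  I_E <- matrix(0, n, e)
  for (i in seq_len(n)) {
    for (k in seq_len(e)) {
      f_diffs <- vapply(seq_len(nrow(draws)), function(s) {
        O_x[i, k] - O_pert[[s]][i, k]
      }, numeric(1))
      I_E[i, k] <- infidelity_from_diffs(draws, get_map(i, k), f_diffs)
    }
  }
  structure(list(I_E = I_E, INFD_E = mean(I_E), perturbation = perturbation),
            class = "infidelity_record")
}

#' Prediction-mode infidelity vector and aggregate
#'
#' Scores the per-residue predictor attributions: `I_P[i]` is the
#' infidelity of the map explaining residue `i`'s propensity, perturbing
#' its zero-padded `(2w+1) x e` embedding window. The aggregate combines
#' `I_E` and `I_P` through the published window-weighted sum `S`: interior
#' residues (covered by `2w+1` windows) enter with weight `2w+1`, terminal
#' residues `i` and `n - i + 1` (`i <= w`) with weight `w + i`.
#'
#' @param predictor A `window_predictor`, or a handle factory
#'   `function(window_letters)` as in [compute_prediction_attribution()].
#' @param embeddings `n x e` embedding matrix.
#' @param P Attribution tensor `n x (2w+1) x e`.
#' @param I_E Embedding infidelity matrix (`n x e`), see
#'   [embedding_infidelity()].
#' @param w Half-window.
#' @param perturbation A [perturbation_spec()].
#' @param letters Optional residue letters (for planted gains).
#' @param denominator `"as_printed"` (default): `(n-2w)(2w+1) + w(3w+1)`;
#'   `"consistent"`: `(n-2w)(2w+1) + w(3w+1)/2`, the algebraic value of the
#'   annotated sum.
#' @return A list of class `infidelity_record` with `I_P`, `S`, `INFD_P`,
#'   the denominator used, and the spec.
#' @export
prediction_infidelity <- function(predictor, embeddings, P, I_E, w,
                                  perturbation = perturbation_spec(),
                                  letters = NULL,
                                  denominator = c("as_printed",
                                                  "consistent")) {
  denominator <- match.arg(denominator)
  n <- nrow(embeddings)
  if (n <= 2 * w) abort("`n` must exceed 2w")
  if (!is.array(P) || !identical(dim(P)[1:2], as.integer(c(n, 2 * w + 1)))) {
    abort("`P` must be n x (2w+1) x e")
  }
  if (!is.matrix(I_E) || nrow(I_E) != n) abort("`I_E` must be n x e")
  letters <- letters %||% rep(NA_character_, n)
  if (inherits(predictor, "window_predictor")) {
    factory <- function(wl) as_handle(predictor, "true_gradient",
                                      letters = wl)
  } else {
    factory <- predictor
  }
  I_P <- vapply(seq_len(n), function(i) {
    V <- embedding_window(embeddings, i, w)
    h <- factory(window_letters(letters, i, w))
    infidelity_score(function(v) h$scalar_forward(v, NULL), V, P[i, , ],
                     perturbation)
  }, numeric(1))
  agg <- infdp_aggregate(I_E, I_P, w, denominator)
  structure(c(list(I_P = I_P), agg, list(perturbation = perturbation)),
            class = "infidelity_record")
}

# the published window-weighted aggregation of I_E and I_P into INFD_P
infdp_aggregate <- function(I_E, I_P, w, denominator = "as_printed") {
  n <- nrow(I_E)
  interior <- (w + 1):(n - w)
  S <- (sum(I_E[interior, , drop = FALSE]) + sum(I_P[interior])) *
    (2 * w + 1)
  for (i in seq_len(w)) {
    S <- S + (sum(I_E[i, ]) + sum(I_E[n - i + 1, ]) +
                I_P[i] + I_P[n - i + 1]) * (w + i)
  }
  denom <- (n - 2 * w) * (2 * w + 1) +
    switch(denominator, as_printed = w * (3 * w + 1),
           consistent = w * (3 * w + 1) / 2)
  list(S = S, INFD_P = S / denom, denominator = denominator,
       denominator_value = denom)
}

#' Serialize an infidelity record to JSON
#'
#' @param record An `infidelity_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_infidelity_record <- function(record, path) {
  stopifnot(inherits(record, "infidelity_record"))
  payload <- unclass(record)
  payload$perturbation <- unclass(payload$perturbation)
  if (!is.null(payload$I_E)) {
    payload$I_E <- list(.dim = dim(payload$I_E),
                        .data = as.vector(payload$I_E))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
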