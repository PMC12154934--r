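#' @title Residue-impact algebra
#' @description
#' The tensor algebra that turns element-level attribution tensors into
#' residue-on-residue impact matrices. For embeddings, the influence tensor
#' `E[i, k, j, l]` collapses to `XE[i, j] = sum_k sum_l E[i, k, j, l]`. For
#' predictions, the per-window tensor `P` composes with the
#' residue-on-element tensor `T[i, k, j] = sum_l E[i, k, j, l]` through
#' `XP[i, j] = sum_k sum_l P[i, k, l] * T[i + k - (w + 1), l, j]` -- the
#' formulas are 1-based and the `i + k - (w + 1)` window offset is honoured
#' exactly, with out-of-range window positions contributing according to the
#' boundary policy (default: zero, matching zero-padded windows). Sums are
#' plain signed sums: no absolute value and no normalization is applied.
#' @name aggregation
NULL

#' Construct a residue-impact matrix
#'
#' @param X Square numeric matrix (`X[i, j]` = effect of source residue `j`
#'   on target residue `i`).
#' @param mode `"embedding"` (an XE matrix) or `"prediction"` (an XP matrix).
#' @param method,model Optional provenance strings.
#' @return `X` with class `residue_impact` and mode/provenance attributes.
#' @export
impact_matrix <- function(X, mode = c("embedding", "prediction"),
                          method = NULL, model = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(X) || nrow(X) != ncol(X)) {
    abort("a residue-impact matrix must be square")
  }
  if (any(!is.finite(X))) abort("residue-impact matrix has non-finite entries")
  structure(X, mode = mode, method = method, model = model,
            class = c("residue_impact", "matrix", "array"))
}

#' Collapse the embedding attribution tensor to the residue-impact matrix XE
#'
#' `XE[i, j] = sum_k sum_l E[i, k, j, l]`: total influence of residue `j`'s
#' embedding-layer activations on residue `i`'s embedding vector.
#'
#' @param E Array with `dim = c(n, e, n, e)`.
#' @return An `n x n` [impact_matrix()] with mode `"embedding"`.
#' @export
collapse_to_XE <- function(E) {
  check_E(E)
  n <- dim(E)[1]; e <- dim(E)[2]
  XE <- matrix(0, n, n)
  # accumulate k-slices in ascending k so the streamed driver is bit-equal
  for (k in seq_len(e)) {
    S <- E[, k, , , drop = FALSE]
    dim(S) <- c(n, n, dim(E)[4])
    XE <- XE + rowSums(S, dims = 2)
  }
  impact_matrix(XE, "embedding", method = attr(E, "method"))
}

#' Reduce the embedding attribution tensor to T
#'
#' `T[i, k, j] = sum_l E[i, k, j, l]`: influence of residue `j` on embedding
#' element `(i, k)`. Summing `T` over its second axis reproduces `XE`.
#'
#' @param E Array with `dim = c(n, e, n, e)`.
#' @return An array with `dim = c(n, e, n)`.
#' @export
collapse_to_T <- function(E) {
  check_E(E)
  rowSums(E, dims = 3)
}

check_E <- function(E) {
  if (!is.array(E) || length(dim(E)) != 4 ||
      dim(E)[1] != dim(E)[3] || dim(E)[2] != dim(E)[4]) {
    abort("`E` must be an n x e x n x e array")
  }
  if (any(!is.finite(E))) abort("`E` has non-finite entries")
  invisible(E)
}

#' Compose P and T into the prediction residue-impact matrix XP
#'
#' `XP[i, j] = sum_{k=1}^{2w+1} sum_l P[i, k, l] * T[i + k - (w + 1), l, j]`
#' (all indices 1-based). Window slots whose centre offset falls outside
#' `[1, n]` contribute zero under the default boundary policy, consistent
#' with zero-padded prediction windows; `boundary_policy = "error"` turns
#' them into an error instead.
#'
#' @param P Array `n x (2w+1) x e` from [compute_prediction_attribution()].
#' @param T_tensor Array `n x e x n` from [collapse_to_T()] or streaming.
#' @param w Half-window; must satisfy `dim(P)[2] == 2 * w + 1`.
#' @param boundary_policy `"zero"` (default) or `"error"`.
#' @return An `n x n` [impact_matrix()] with mode `"prediction"`.
#' @export
compose_XP <- function(P, T_tensor, w, boundary_policy = c("zero", "error")) {
  boundary_policy <- match.arg(boundary_policy)
  if (!is.array(P) || length(dim(P)) != 3) abort("`P` must be a 3-D array")
  if (!is.array(T_tensor) || length(dim(T_tensor)) != 3) {
    abort("`T_tensor` must be a 3-D array")
  }
  n <- dim(P)[1]; win <- dim(P)[2]; e <- dim(P)[3]
  if (win != 2 * w + 1) {
    abort(sprintf("`w` = %d inconsistent with window dimension %d", w, win))
  }
  if (dim(T_tensor)[1] != n || dim(T_tensor)[2] != e ||
      dim(T_tensor)[3] != n) {
    abort("`T_tensor` must be n x e x n, consistent with `P`")
  }
  XP <- matrix(0, n, n)
  # accumulate in (k, l)-ascending order so the explicit-loop oracle is
  # reproduced bit-exactly
  for (i in seq_len(n)) {
    for (k in seq_len(win)) {
      src <- i + k - (w + 1)
      if (src < 1 || src > n) {
        if (boundary_policy == "error") {
          abort(sprintf("window position %d of residue %d out of range",
                        k, i))
        }
        next
      }
      for (l in seq_len(e)) {
        XP[i, ] <- XP[i, ] + P[i, k, l] * T_tensor[src, l, ]
      }
    }
  }
  impact_matrix(XP, "prediction", method = attr(P, "method"))
}

#' Write a residue-impact matrix as TSV
#'
#' @param X A [impact_matrix()].
#' @param path Output path.
#' @param letters Optional residue letters used as row/column headers.
#' @return `path`, invisibly.
#' @export
write_impact_matrix <- function(X, path, letters = NULL) {
  M <- unclass(X)
  attributes(M) <- list(dim = dim(X))
  if (!is.null(letters)) dimnames(M) <- list(letters, letters)
  write.table(M, path, sep = "\t", quote = FALSE,
              row.names = !is.null(letters),
              col.names = if (is.null(letters)) FALSE else NA)
  invisible(path)
}
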