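#' @title Attribution tensors for sequence models
#' @description
#' Drivers that run one attribution operator once per scalar model output.
#' For an embedder with output `n x e` this yields the 4-D influence tensor
#' `E[i, k, j, l]` (effect of input element `(j, l)` on output element
#' `(i, k)`); at realistic embedding dimensions that tensor is why the
#' published full-scale runs needed terabytes, so the embedding driver can
#' also stream the per-scalar maps straight into the residue-level
#' accumulators (`XE` and `T`) without materializing `E`. For a window
#' predictor the result is the `n x (2w+1) x e` tensor `P[i, j, k]`: the
#' effect of element `k` of window-slot `j` on the propensity of residue
#' `i`.
#' @name attribution_tensors
NULL

#' Compute the embedding attribution tensor E (or stream its collapses)
#'
#' Runs the configured method once per output element `(i, k)` of the
#' embedder. With `materialize = TRUE` returns the full `n x e x n x e`
#' tensor; with `materialize = FALSE` returns the streamed accumulators
#' `XE` (n x n residue-impact matrix) and `T` (n x e x n) computed map by
#' map, bit-identical to collapsing the materialized tensor.
#'
#' @param handle An embedder `model_handle` whose rule matches
#'   `config$method`.
#' @param x Input activations (`n x e`), e.g. [embedder_input()].
#' @param config An [attribution_config()].
#' @param materialize Materialize `E` (TRUE) or stream (FALSE).
#' @return Either an array `E` with `dim = c(n, e, n, e)`, or
#'   `list(XE = , T = )`.
#' @export
compute_embedding_attribution <- function(handle, x, config,
                                          materialize = TRUE) {
  stopifnot(inherits(config, "attribution_config"))
  n <- nrow(x); e <- ncol(x)
  if (n < 1) abort("sequence length must be >= 1")
  if (materialize) {
    E <- array(0, dim = c(n, e, n, e))
    for (i in seq_len(n)) {
      for (k in seq_len(e)) {
        map <- with_cell_context(i, k, config$method,
                                 run_attribution(handle, x, config, c(i, k)))
        E[i, k, , ] <- map
      }
    }
    structure(E, method = config$method)
  } else {
    XE <- matrix(0, n, n)
    TT <- array(0, dim = c(n, e, n))
    for (i in seq_len(n)) {
      for (k in seq_len(e)) {
        map <- with_cell_context(i, k, config$method,
                                 run_attribution(handle, x, config, c(i, k)))
        v <- rowSums(map)       # sum over the input embedding axis l
        TT[i, k, ] <- v
        XE[i, ] <- XE[i, ] + v  # then accumulate over the output axis k
      }
    }
    list(XE = impact_matrix(XE, "embedding", method = config$method),
         T = TT)
  }
}

# annotate a per-scalar failure with the offending output element
with_cell_context <- function(i, k, method, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("%s failed at output element (i = %d, k = %d): %s",
                  method, i, k, conditionMessage(e)))
  })
}

#' Zero-padded embedding window around a residue
#'
#' @param embeddings `n x e` matrix.
#' @param i Centre residue (1-based).
#' @param w Half-window.
#' @return A `(2w+1) x e` matrix; rows outside `[1, n]` are zero.
#' @export
embedding_window <- function(embeddings, i, w) {
  n <- nrow(embeddings)
  V <- matrix(0, 2 * w + 1, ncol(embeddings))
  for (k in seq_len(2 * w + 1)) {
    j <- i + k - (w + 1)
    if (j >= 1 && j <= n) V[k, ] <- embeddings[j, ]
  }
  V
}

window_letters <- function(letters, i, w) {
  n <- length(letters)
  out <- rep(NA_character_, 2 * w + 1)
  for (k in seq_len(2 * w + 1)) {
    j <- i + k - (w + 1)
    if (j >= 1 && j <= n) out[k] <- letters[j]
  }
  out
}

#' Compute the prediction attribution tensor P
#'
#' Slides the window predictor along the sequence and attributes its scalar
#' propensity for each centre residue to the `(2w+1) x e` embedding window
#' (zero-padded at the termini).
#'
#' @param predictor A `window_predictor`, or a function
#'   `function(window_letters)` returning a scalar-output `model_handle`
#'   (adapter route).
#' @param embeddings `n x e` embedding matrix the predictor reads.
#' @param config An [attribution_config()]; the handle rule is chosen to
#'   match the method.
#' @param letters Optional residue letters (needed for planted property
#'   gains); defaults to no letters.
#' @param w Half-window; taken from the predictor when it is a model.
#' @return An array `P` with `dim = c(n, 2w+1, e)`.
#' @export
compute_prediction_attribution <- function(predictor, embeddings, config,
                                           letters = NULL, w = NULL) {
  stopifnot(inherits(config, "attribution_config"))
  n <- nrow(embeddings)
  if (n < 1) abort("`embeddings` must have at least one row")
  if (inherits(predictor, "window_predictor")) {
    w <- predictor$w
    if (predictor$e != ncol(embeddings)) {
      abort("predictor embedding dimension does not match `embeddings`")
    }
    factory <- function(wl) as_handle(predictor, rule_for_method(config$method),
                                      letters = wl)
  } else if (is.function(predictor)) {
    if (is.null(w)) abort("`w` must be given when `predictor` is a factory")
    factory <- predictor
  } else {
    abort("`predictor` must be a window_predictor or a handle factory")
  }
  if (2 * w + 1 > n) {
    abort(sprintf("window size %d exceeds sequence length %d", 2 * w + 1, n))
  }
  letters <- letters %||% rep(NA_character_, n)
  e <- ncol(embeddings)
  P <- array(0, dim = c(n, 2 * w + 1, e))
  for (i in seq_len(n)) {
    V <- embedding_window(embeddings, i, w)
    h <- factory(window_letters(letters, i, w))
    map <- with_cell_context(i, 1, config$method,
                             run_attribution(h, V, config, NULL))
    P[i, , ] <- map
  }
  structure(P, method = config$method, w = w)
}
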