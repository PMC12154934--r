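#' @title Desk-scale differentiable stand-in models
#' @description
#' The published analysis attributes the outputs of GPU-scale protein language
#' models (embedding dimension 768-1024) and of a windowed interaction-site
#' predictor. The attribution algebra is size-independent, so this module
#' provides small rectifier networks with the same interface: an embedder
#' mapping a length-n sequence to an n-by-e real matrix, and a window
#' predictor mapping a (2w+1)-by-e embedding window to a propensity in (0,1).
#' Attribution is always taken with respect to the embedding-layer output
#' activations (a look-up table is not differentiable; its output is).
#'
#' Two controllable mechanisms mimic structure the analysis is designed to
#' detect: a locality decay `lambda` (input position j influences output
#' position i with weight `exp(-lambda * |i - j|)`), and an optional planted
#' property sensitivity that multiplies the contribution of residue j by
#' `exp(beta * z_prop(letter_j))`, where `z_prop` is the standardized
#' numerical property from [load_property_table()].
#' @name toy_models
NULL

relu <- function(z) pmax(z, 0)

# backward behaviour at a rectifier, by rule
rule_backward <- function(upstream, z, rule) {
  switch(rule,
    true_gradient = upstream * (z > 0),
    deconvolution = upstream * (upstream > 0),
    guided = upstream * (upstream > 0) * (z > 0),
    abort(sprintf("unknown backprop rule '%s'", rule))
  )
}

# elementwise rescale multiplier (h - h0) / (z - z0) with gradient fallback
# at near-equal pre-activations
rescale_multiplier <- function(h, h0, z, z0, grad_at_z) {
  dz <- z - z0
  m <- ifelse(abs(dz) < 1e-9, grad_at_z, (h - h0) / dz)
  m
}

validate_sensitivity <- function(property_sensitivity) {
  if (is.null(property_sensitivity)) return(NULL)
  if (!is.list(property_sensitivity) ||
      !all(c("property", "beta") %in% names(property_sensitivity))) {
    abort("`property_sensitivity` must be list(property = , beta = )")
  }
  if (!property_sensitivity$property %in% numerical_properties()) {
    abort(sprintf(
      "unknown property '%s'; planted sensitivity supports: %s",
      property_sensitivity$property,
      paste(numerical_properties(), collapse = ", ")
    ))
  }
  property_sensitivity
}

# per-letter gain vector exp(beta * z), names = AA_ALPHABET
letter_gains <- function(property_sensitivity) {
  g <- rep(1, 20)
  names(g) <- AA_ALPHABET
  if (!is.null(property_sensitivity)) {
    props <- load_property_table()
    v <- props[[property_sensitivity$property]]
    z <- (v - mean(v)) / sd(v)
    g <- exp(property_sensitivity$beta * z)
    names(g) <- props$letter
  }
  g
}

# gains for a letter vector; NA letters (window padding) get gain 1
gains_for <- function(model, letters) {
  g <- rep(1, length(letters))
  ok <- !is.na(letters)
  g[ok] <- model$gains[letters[ok]]
  g
}

#' Build a toy embedder model
#'
#' A two-layer rectifier network standing in for a protein language model.
#' Position mixing uses fixed weights `exp(-lambda * |i - j|)`, so large
#' `lambda` makes the model effectively local.
#'
#' @param e Embedding dimension (>= 2; the real models use 768-1024, the
#'   desk-scale default is 8).
#' @param lambda Locality decay (>= 0); 0 means all positions mix equally.
#' @param property_sensitivity Optional `list(property =, beta =)` planting a
#'   multiplicative dependence of every residue's influence on one numerical
#'   amino-acid property.
#' @param seed Integer seed for the parameters.
#' @param hidden Hidden width (default 16).
#' @param nonlinearity `"relu"` (default) or `"linear"` (used by exactness
#'   oracles; the modified backpropagation rules require rectifiers).
#' @return An object of class `toy_embedder`.
#' @examples
#' emb <- build_toy_embedder(e = 4, lambda = 1, seed = 1)
#' h <- as_handle(emb, letters = seq_letters("ACDEF"))
#' dim(h$forward(embedder_input(emb, seq_letters("ACDEF"))))
#' @export
build_toy_embedder <- function(e = 8, lambda = 1, property_sensitivity = NULL,
                               seed = 1, hidden = 16,
                               nonlinearity = c("relu", "linear")) {
  if (e < 2) abort("`e` must be >= 2")
  if (lambda < 0) abort("`lambda` must be >= 0")
  nonlinearity <- match.arg(nonlinearity)
  property_sensitivity <- validate_sensitivity(property_sensitivity)
  params <- withr::with_seed(as.integer(seed), {
    list(
      lookup = matrix(rnorm(20 * e), 20, e,
                      dimnames = list(AA_ALPHABET, NULL)),
      W1 = matrix(rnorm(e * hidden, sd = sqrt(2 / e)), e, hidden),
      b1 = rnorm(hidden, sd = 0.1),
      W2 = matrix(rnorm(hidden * e, sd = sqrt(2 / hidden)), hidden, e),
      b2 = rnorm(e, sd = 0.1)
    )
  })
  structure(
    c(params, list(
      e = e, hidden = hidden, lambda = lambda,
      nonlinearity = nonlinearity, seed = as.integer(seed),
      sensitivity = property_sensitivity,
      gains = letter_gains(property_sensitivity)
    )),
    class = "toy_embedder"
  )
}

#' Embedding-layer output activations for a sequence
#'
#' The continuous activations the attribution operators act on: row j is the
#' look-up vector of residue j. This is the natural input `x` for an
#' embedder handle.
#'
#' @param model A `toy_embedder`.
#' @param letters Character vector of residue letters.
#' @return An `n x e` matrix.
#' @export
embedder_input <- function(model, letters) {
  stopifnot(inherits(model, "toy_embedder"))
  model$lookup[letters, , drop = FALSE]
}

locality_weights <- function(n, lambda) {
  idx <- seq_len(n)
  exp(-lambda * abs(outer(idx, idx, "-")))
}

embedder_cache <- function(model, x, letters) {
  n <- nrow(x)
  g <- gains_for(model, letters)
  D <- locality_weights(n, model$lambda)
  XG <- x * g
  Z <- D %*% XG %*% model$W1 + matrix(model$b1, n, model$hidden, byrow = TRUE)
  H <- if (model$nonlinearity == "relu") relu(Z) else Z
  O <- H %*% model$W2 + matrix(model$b2, n, model$e, byrow = TRUE)
  list(g = g, D = D, Z = Z, H = H, O = O)
}

#' Build a toy window predictor
#'
#' A one-hidden-layer rectifier network with a sigmoidal head standing in for
#' a windowed interaction-site predictor: it maps the embedding vectors of
#' the `2w+1` residues centred on the residue of interest to a propensity
#' strictly inside (0, 1).
#'
#' @param e Embedding dimension (must match the paired embedder).
#' @param w Half-window (>= 1); the input is a `(2w+1) x e` matrix.
#' @param property_sensitivity As in [build_toy_embedder()].
#' @param seed Integer seed.
#' @param hidden Hidden width (default 16).
#' @return An object of class `window_predictor`.
#' @export
build_window_predictor <- function(e = 8, w = 4, property_sensitivity = NULL,
                                   seed = 1, hidden = 16) {
  if (w < 1) abort("`w` must be >= 1")
  if (e < 2) abort("`e` must be >= 2")
  property_sensitivity <- validate_sensitivity(property_sensitivity)
  d <- (2 * w + 1) * e
  params <- withr::with_seed(as.integer(seed), {
    list(
      Wp1 = matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
      bp1 = rnorm(hidden, sd = 0.1),
      wp2 = rnorm(hidden, sd = sqrt(2 / hidden)),
      bp2 = rnorm(1, sd = 0.5)
    )
  })
  structure(
    c(params, list(
      e = e, w = w, hidden = hidden, seed = as.integer(seed),
      sensitivity = property_sensitivity,
      gains = letter_gains(property_sensitivity)
    )),
    class = "window_predictor"
  )
}

predictor_cache <- function(model, V, letters) {
  g <- gains_for(model, letters)
  v <- as.vector(V * g)
  z1 <- as.vector(crossprod(model$Wp1, v)) + model$bp1
  h1 <- relu(z1)
  y <- sum(model$wp2 * h1) + model$bp2
  list(g = g, v = v, z1 = z1, h1 = h1, y = y, out = plogis(y))
}

#' Wrap a model in the differentiable-model handle contract
#'
#' A handle exposes the interface the attribution operators consume:
#' `forward(x)`, `scalar_forward(x, selector)`, `scalar_gradient(x,
#' selector)` and `deeplift_attr(x, baseline, selector)`, together with the
#' backpropagation rule it was built with. The three rules differ only at
#' rectifiers: `true_gradient` is exact reverse-mode differentiation;
#' `deconvolution` back-propagates only positive upstream signal regardless
#' of the forward activation; `guided` additionally zeroes the signal where
#' the forward pre-activation is non-positive. Any conforming object (for
#' example a linear adapter over a real model, see [linear_handle()]) runs
#' through the downstream pipeline unchanged.
#'
#' @param model A `toy_embedder` or `window_predictor`.
#' @param backprop_rule One of `"true_gradient"`, `"deconvolution"`,
#'   `"guided"`.
#' @param letters For an embedder: the residue letters of the sequence (used
#'   for the look-up input and planted gains). For a predictor: the letters
#'   of the window slots, `NA` for padded slots.
#' @return A list of class `model_handle`.
#' @export
as_handle <- function(model,
                      backprop_rule = c("true_gradient", "deconvolution",
                                        "guided"),
                      letters = NULL) {
  UseMethod("as_handle")
}

#' @export
as_handle.toy_embedder <- function(model,
                                   backprop_rule = c("true_gradient",
                                                     "deconvolution",
                                                     "guided"),
                                   letters = NULL) {
  backprop_rule <- match.arg(backprop_rule)
  if (model$nonlinearity != "relu" && backprop_rule != "true_gradient") {
    abort("modified backprop rules require a rectifier model")
  }
  if (is.null(letters)) abort("an embedder handle needs the sequence letters")
  force(model)
  h <- list(
    type = "embedder",
    rule = backprop_rule,
    letters = letters,
    model = model,
    output_shape = c(length(letters), model$e),
    forward = function(x) embedder_cache(model, x, letters)$O,
    scalar_forward = function(x, selector) {
      embedder_cache(model, x, letters)$O[selector[1], selector[2]]
    },
    scalar_gradient = function(x, selector) {
      cache <- embedder_cache(model, x, letters)
      i <- selector[1]; k <- selector[2]
      dH <- model$W2[, k]
      dZ <- if (model$nonlinearity == "relu") {
        rule_backward(dH, cache$Z[i, ], backprop_rule)
      } else dH
      u <- as.vector(model$W1 %*% dZ)
      outer(cache$D[i, ] * cache$g, u)
    },
    deeplift_attr = function(x, baseline, selector) {
      cache <- embedder_cache(model, x, letters)
      cache0 <- embedder_cache(model, baseline, letters)
      i <- selector[1]; k <- selector[2]
      dH <- model$W2[, k]
      m <- if (model$nonlinearity == "relu") {
        rescale_multiplier(cache$H[i, ], cache0$H[i, ],
                           cache$Z[i, ], cache0$Z[i, ],
                           as.numeric(cache$Z[i, ] > 0))
      } else rep(1, model$hidden)
      u <- as.vector(model$W1 %*% (dH * m))
      outer(cache$D[i, ] * cache$g, u) * (x - baseline)
    }
  )
  structure(h, class = "model_handle")
}

#' @export
as_handle.window_predictor <- function(model,
                                       backprop_rule = c("true_gradient",
                                                         "deconvolution",
                                                         "guided"),
                                       letters = NULL) {
  backprop_rule <- match.arg(backprop_rule)
  win <- 2 * model$w + 1
  if (is.null(letters)) letters <- rep(NA_character_, win)
  if (length(letters) != win) {
    abort(sprintf("predictor handle needs %d window letters (NA for padding)",
                  win))
  }
  force(model)
  h <- list(
    type = "predictor",
    rule = backprop_rule,
    letters = letters,
    model = model,
    output_shape = c(1L),
    forward = function(x) predictor_cache(model, x, letters)$out,
    scalar_forward = function(x, selector = NULL) {
      predictor_cache(model, x, letters)$out
    },
    scalar_gradient = function(x, selector = NULL) {
      cache <- predictor_cache(model, x, letters)
      ds <- cache$out * (1 - cache$out)
      dh1 <- model$wp2 * ds
      dz1 <- rule_backward(dh1, cache$z1, backprop_rule)
      dv <- as.vector(model$Wp1 %*% dz1)
      matrix(dv, nrow = 2 * model$w + 1) * cache$g
    },
    deeplift_attr = function(x, baseline, selector = NULL) {
      cache <- predictor_cache(model, x, letters)
      cache0 <- predictor_cache(model, baseline, letters)
      dy <- cache$y - cache0$y
      msig <- if (abs(dy) < 1e-9) {
        cache$out * (1 - cache$out)
      } else {
        (cache$out - cache0$out) / dy
      }
      dh1 <- model$wp2 * msig
      mrelu <- rescale_multiplier(cache$h1, cache0$h1, cache$z1, cache0$z1,
                                  as.numeric(cache$z1 > 0))
      dv <- as.vector(model$Wp1 %*% (dh1 * mrelu))
      matrix(dv, nrow = 2 * model$w + 1) * cache$g * (x - baseline)
    }
  )
  structure(h, class = "model_handle")
}

#' A linear model handle (adapter example and oracle)
#'
#' Wraps the scalar linear map `f(x) = sum(A * x) + b` in the handle
#' contract. On a purely linear model the three backpropagation rules
#' coincide, so any rule is accepted for convenience in cross-method
#' consistency checks; attribution methods see exact gradients.
#'
#' @param A Coefficient array (any shape); inputs must share its shape.
#' @param b Intercept.
#' @return A `model_handle` with scalar output.
#' @export
linear_handle <- function(A, b = 0) {
  force(A); force(b)
  structure(list(
    type = "linear",
    rule = "true_gradient",
    model = list(A = A, b = b),
    output_shape = c(1L),
    forward = function(x) sum(A * x) + b,
    scalar_forward = function(x, selector = NULL) sum(A * x) + b,
    scalar_gradient = function(x, selector = NULL) A,
    deeplift_attr = function(x, baseline, selector = NULL) A * (x - baseline)
  ), class = "model_handle")
}

#' Serialize a toy model to JSON
#'
#' Plain-text round-trip of all parameters, dimensions and provenance
#' (seed, locality decay, planted sensitivity).
#'
#' @param model A `toy_embedder` or `window_predictor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_toy_model <- function(model, path) {
  stopifnot(inherits(model, c("toy_embedder", "window_predictor")))
  payload <- lapply(unclass(model), function(v) {
    if (is.matrix(v)) list(.dim = dim(v), .data = as.vector(v)) else v
  })
  payload$model_class <- class(model)[1]
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a toy model saved by [save_toy_model()]
#'
#' @param path JSON path.
#' @return The reconstructed model.
#' @export
load_toy_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$model_class
  p$model_class <- NULL
  p <- lapply(p, function(v) {
    if (is.list(v) && all(c(".dim", ".data") %in% names(v))) {
      matrix(v$.data, v$.dim[1], v$.dim[2])
    } else v
  })
  if (!is.null(p$lookup)) rownames(p$lookup) <- AA_ALPHABET
  if (!is.null(p$sensitivity) && length(p$sensitivity) == 0) {
    p$sensitivity <- NULL
  }
  if (!is.null(p$gains)) names(p$gains) <- AA_ALPHABET
  structure(p, class = cls)
}
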