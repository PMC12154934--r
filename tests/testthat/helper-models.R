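# shared builders for small seeded fixtures

random_letters <- function(n, seed) {
  withr::with_seed(seed, sample(AA_ALPHABET, n, replace = TRUE))
}

# a small seeded one-hidden-layer rectifier net wrapped as a scalar handle,
# with its weights exposed so tests can hand-roll independent backward passes
scalar_relu_net <- function(d, hidden = 8, seed = 1, weight_sd = 0.5) {
  params <- withr::with_seed(seed, list(
    W = matrix(rnorm(d * hidden, sd = weight_sd), d, hidden),
    b = rnorm(hidden, sd = 0.1),
    v = rnorm(hidden)
  ))
  f <- function(x) {
    sum(params$v * pmax(as.vector(crossprod(params$W, as.vector(x))) +
                          params$b, 0))
  }
  g <- function(x, selector = NULL) {
    z <- as.vector(crossprod(params$W, as.vector(x))) + params$b
    out <- as.vector(params$W %*% (params$v * (z > 0)))
    shaped <- x
    shaped[] <- out
    shaped
  }
  structure(list(
    type = "custom", rule = "true_gradient", params = params,
    forward = f,
    scalar_forward = function(x, selector = NULL) f(x),
    scalar_gradient = g,
    deeplift_attr = function(x, baseline, selector = NULL) {
      z <- as.vector(crossprod(params$W, as.vector(x))) + params$b
      z0 <- as.vector(crossprod(params$W, as.vector(baseline))) + params$b
      m <- ifelse(abs(z - z0) < 1e-9, as.numeric(z > 0),
                  (pmax(z, 0) - pmax(z0, 0)) / (z - z0))
      out <- as.vector(params$W %*% (params$v * m))
      shaped <- x
      shaped[] <- out * (as.vector(x) - as.vector(baseline))
      shaped
    }
  ), class = "model_handle")
}

# exact Shapley values by full enumeration with the factorial weights --
# the brute-force oracle KernelSHAP is checked against
brute_force_shapley <- function(f, x, baseline = NULL) {
  d <- length(x)
  baseline <- baseline %||% (x * 0)
  masks <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  vals <- apply(masks, 1, function(m) {
    xm <- x
    xm[m == 0] <- baseline[m == 0]
    f(xm)
  })
  key <- as.vector(masks %*% 2^(0:(d - 1))) + 1
  lookup <- numeric(2^d)
  lookup[key] <- vals
  fact <- factorial(0:d)
  vapply(seq_len(d), function(i) {
    sub <- masks[masks[, i] == 0, , drop = FALSE]
    s <- rowSums(sub)
    wts <- fact[s + 1] * fact[d - s] / fact[d + 1]
    k0 <- as.vector(sub %*% 2^(0:(d - 1))) + 1
    k1 <- k0 + 2^(i - 1)
    sum(wts * (lookup[k1] - lookup[k0]))
  }, numeric(1))
}

# build the (model, method, mode, protein) grid tibble for a single toy
# embedder/predictor pair over synthetic proteins, using streamed XE / XP
toy_grid <- function(embedder, predictor = NULL, proteins,
                     method = "saliency", modes = "embedding",
                     model_id = "toy", seed = 1) {
  cfg <- attribution_config(method, seed = seed)
  purrr::map_dfr(seq_len(nrow(proteins)), function(p) {
    lp <- strsplit(proteins$sequence[p], "")[[1]]
    h <- as_handle(embedder, rule_for_method(method), letters = lp)
    x <- embedder_input(embedder, lp)
    st <- compute_embedding_attribution(h, x, cfg, materialize = FALSE)
    rows <- list()
    if ("embedding" %in% modes) {
      rows$embedding <- st$XE
    }
    if ("prediction" %in% modes) {
      P <- compute_prediction_attribution(predictor, h$forward(x), cfg,
                                          letters = lp)
      rows$prediction <- compose_XP(P, st$T, predictor$w)
    }
    purrr::map_dfr(names(rows), function(mode) {
      tibble::tibble(model = model_id, method = method, mode = mode,
                     protein_id = proteins$protein_id[p],
                     X = list(unclass(rows[[mode]])),
                     sequence = proteins$sequence[p],
                     labels = proteins$labels[p])
    })
  })
}
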