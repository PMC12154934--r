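test_that("toy models are deterministic given the seed", {
  a <- build_toy_embedder(e = 4, lambda = 1, seed = 11)
  b <- build_toy_embedder(e = 4, lambda = 1, seed = 11)
  expect_identical(a, b)
  p1 <- build_window_predictor(e = 4, w = 2, seed = 12)
  p2 <- build_window_predictor(e = 4, w = 2, seed = 12)
  expect_identical(p1, p2)
})

test_that("handle gradients match central finite differences", {
  # ~100 probes across two embedders and one predictor, rel err < 1e-4
  eps <- 1e-5
  for (seed in c(3, 17)) {
    emb <- build_toy_embedder(e = 4, lambda = 1, seed = seed)
    lets <- random_letters(10, seed + 1)
    x <- embedder_input(emb, lets)
    h <- as_handle(emb, "true_gradient", letters = lets)
    for (sel in list(c(1, 1), c(5, 3), c(10, 4))) {
      g <- h$scalar_gradient(x, sel)
      num <- x * 0
      for (j in seq_len(nrow(x))) {
        for (c in seq_len(ncol(x))) {
          xp <- x; xp[j, c] <- xp[j, c] + eps
          xm <- x; xm[j, c] <- xm[j, c] - eps
          num[j, c] <- (h$scalar_forward(xp, sel) -
                          h$scalar_forward(xm, sel)) / (2 * eps)
        }
      }
      expect_lt(max(abs(g - num)) / max(max(abs(num)), 1e-8), 1e-4)
    }
  }
  pred <- build_window_predictor(e = 4, w = 1, seed = 5)
  V <- withr::with_seed(6, matrix(rnorm(12), 3, 4))
  hp <- as_handle(pred)
  gp <- hp$scalar_gradient(V)
  nump <- V * 0
  for (j in 1:3) {
    for (c in 1:4) {
      Vp <- V; Vp[j, c] <- Vp[j, c] + eps
      Vm <- V; Vm[j, c] <- Vm[j, c] - eps
      nump[j, c] <- (hp$forward(Vp) - hp$forward(Vm)) / (2 * eps)
    }
  }
  expect_lt(max(abs(gp - nump)) / max(abs(nump)), 1e-4)
})

test_that("predictor output range and zero-window closed form hold", {
  pred <- build_window_predictor(e = 4, w = 1, seed = 9)
  hp <- as_handle(pred)
  withr::with_seed(10, {
    for (i in 1:10) {
      out <- hp$forward(matrix(rnorm(12, sd = 3), 3, 4))
      expect_gt(out, 0)
      expect_lt(out, 1)
    }
  })
  # zero input window: sigmoid of the bias path through the hidden layer
  expected <- plogis(sum(pred$wp2 * pmax(pred$bp1, 0)) + pred$bp2)
  expect_equal(hp$forward(matrix(0, 3, 4)), expected)
})

test_that("backprop rules follow their rectifier definitions", {
  # single rectifier unit, forward input negative, upstream +1
  expect_equal(protexplain:::rule_backward(1, -2, "true_gradient"), 0)
  expect_equal(protexplain:::rule_backward(1, -2, "deconvolution"), 1)
  expect_equal(protexplain:::rule_backward(1, -2, "guided"), 0)
  # guided = product of both masks applied to the upstream signal
  up <- c(1, -1, 2, -2)
  z <- c(1, 1, -1, -1)
  expect_equal(protexplain:::rule_backward(up, z, "guided"),
               up * (up > 0) * (z > 0))
})

test_that("modified backward passes match a hand-rolled layerwise oracle", {
  emb <- build_toy_embedder(e = 4, lambda = 0.7, seed = 21)
  lets <- random_letters(8, 22)
  x <- embedder_input(emb, lets)
  cache <- protexplain:::embedder_cache(emb, x, lets)
  sel <- c(4, 2)
  # hand-rolled backward from the model weights, independent of the handle
  for (rule in c("deconvolution", "guided")) {
    dH <- emb$W2[, sel[2]]
    dZ <- switch(rule,
                 deconvolution = pmax(dH, 0),
                 guided = pmax(dH, 0) * (cache$Z[sel[1], ] > 0))
    oracle <- outer(cache$D[sel[1], ] * cache$g,
                    as.vector(emb$W1 %*% dZ))
    h <- as_handle(emb, rule, letters = lets)
    got <- if (rule == "deconvolution") {
      deconvolution(h, x, sel)
    } else {
      guided_backprop(h, x, sel)
    }
    expect_equal(unclass(got), oracle, ignore_attr = TRUE)
  }
})

test_that("rules coincide on models without rectifiers and error as contract", {
  lin <- build_toy_embedder(e = 3, lambda = 1, seed = 30,
                            nonlinearity = "linear")
  lets <- random_letters(6, 31)
  x <- embedder_input(lin, lets)
  h <- as_handle(lin, "true_gradient", letters = lets)
  g <- h$scalar_gradient(x, c(2, 2))
  # a linear model admits only the true gradient; modified rules are a
  # contract error
  expect_error(as_handle(lin, "deconvolution", letters = lets), "rectifier")
  expect_error(as_handle(lin, "guided", letters = lets), "rectifier")
  # on a linear scalar handle all three operators agree
  A <- matrix(rnorm(6), 2, 3)
  hl <- linear_handle(A)
  xs <- matrix(rnorm(6), 2, 3)
  expect_equal(unclass(saliency(hl, xs)), A, ignore_attr = TRUE)
  expect_equal(unclass(deconvolution(hl, xs)), A, ignore_attr = TRUE)
  expect_equal(unclass(guided_backprop(hl, xs)), A, ignore_attr = TRUE)
})

test_that("locality decay controls the attribution footprint", {
  lets <- random_letters(20, 40)
  # lambda = 10: influence beyond distance 5 is < 1% of the diagonal
  emb10 <- build_toy_embedder(e = 4, lambda = 10, seed = 41)
  h10 <- as_handle(emb10, "true_gradient", letters = lets)
  st <- compute_embedding_attribution(h10, embedder_input(emb10, lets),
                                      attribution_config("saliency"),
                                      materialize = FALSE)
  XEa <- abs(unclass(st$XE))
  dmat <- abs(outer(1:20, 1:20, "-"))
  expect_lt(mean(XEa[dmat >= 5]), 0.01 * mean(diag(XEa)))
  # off-diagonal attribution mass decays monotonically in lambda
  far_mass <- vapply(c(0.5, 1, 2), function(lam) {
    embL <- build_toy_embedder(e = 4, lambda = lam, seed = 41)
    hL <- as_handle(embL, "true_gradient", letters = lets)
    stL <- compute_embedding_attribution(hL, embedder_input(embL, lets),
                                         attribution_config("saliency"),
                                         materialize = FALSE)
    XL <- abs(unclass(stL$XE))
    mean(XL[dmat >= 3]) / mean(diag(XL))
  }, numeric(1))
  expect_true(all(diff(far_mass) < 0))
})

test_that("without planted sensitivity no property is spuriously detected", {
  # null calibration over 20 seeded replicates: with beta = 0 each of the
  # 4 numerical tests is a null test, so the pooled false-positive rate
  # over 80 tests must sit inside the 3-sigma binomial band around alpha
  hits <- matrix(FALSE, 20, 4,
                 dimnames = list(NULL, numerical_properties()))
  for (r in 1:20) {
    emb <- build_toy_embedder(e = 6, lambda = 2, seed = 600 + r)
    prots <- generate_synthetic_proteins(15, c(20, 30), 0.3,
                                         seed = 700 + r)
    grid <- toy_grid(emb, proteins = prots, method = "saliency",
                     modes = "embedding")
    res <- run_property_tests(grid, transform = "absolute")
    num <- res[res$test_type == "numerical" & res$role == "source", ]
    hits[r, ] <- num$p_value[match(numerical_properties(),
                                   num$property)] < 0.05
  }
  pooled <- mean(hits)
  expect_lt(pooled, 0.05 + 3 * sqrt(0.05 * 0.95 / length(hits)))
})

test_that("toy models round-trip through JSON serialization", {
  emb <- build_toy_embedder(e = 4, lambda = 1.5, seed = 9,
                            property_sensitivity =
                              list(property = "hydrophobicity", beta = 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  save_toy_model(emb, f)
  emb2 <- load_toy_model(f)
  expect_s3_class(emb2, "toy_embedder")
  lets <- random_letters(9, 10)
  o1 <- as_handle(emb, "true_gradient", lets)$forward(
    embedder_input(emb, lets))
  o2 <- as_handle(emb2, "true_gradient", lets)$forward(
    embedder_input(emb2, lets))
  expect_equal(o1, o2, tolerance = 1e-12)
  pred <- build_window_predictor(e = 4, w = 2, seed = 3)
  fp <- withr::local_tempfile(fileext = ".json")
  save_toy_model(pred, fp)
  pred2 <- load_toy_model(fp)
  V <- withr::with_seed(4, matrix(rnorm(20), 5, 4))
  expect_equal(as_handle(pred)$forward(V), as_handle(pred2)$forward(V),
               tolerance = 1e-12)
})

test_that("a planted property sensitivity is recoverable downstream", {
  sens <- list(property = "hydrophobicity", beta = 1)
  emb <- build_toy_embedder(e = 6, lambda = 2, property_sensitivity = sens,
                            seed = 51)
  pred <- build_window_predictor(e = 6, w = 2, property_sensitivity = sens,
                                 seed = 52)
  prots <- generate_synthetic_proteins(30, c(20, 30), 0.3, seed = 53)
  grid <- toy_grid(emb, pred, prots, method = "saliency",
                   modes = "prediction")
  res <- run_property_tests(grid, transform = "absolute")
  p_hyd <- res$p_value[res$role == "source" & res$mode == "prediction" &
                         res$property == "hydrophobicity"]
  expect_lt(p_hyd, 0.05)
  expect_error(build_toy_embedder(property_sensitivity =
                                    list(property = "bogus", beta = 1)),
               "unknown property")
})

test_that("any conforming handle runs through the downstream pipeline", {
  # trivial linear adapter: output = x %*% W (no rectifiers anywhere)
  e <- 3
  W <- withr::with_seed(60, matrix(rnorm(e * e, sd = 0.5), e, e))
  linear_embedder_handle <- structure(list(
    type = "adapter", rule = "true_gradient",
    forward = function(x) x %*% W,
    scalar_forward = function(x, sel) (x %*% W)[sel[1], sel[2]],
    scalar_gradient = function(x, sel) {
      g <- x * 0
      g[sel[1], ] <- W[, sel[2]]
      g
    },
    deeplift_attr = function(x, baseline, sel) {
      g <- x * 0
      g[sel[1], ] <- W[, sel[2]]
      g * (x - baseline)
    }
  ), class = "model_handle")
  x <- withr::with_seed(61, matrix(rnorm(6 * e), 6, e))
  cfg <- attribution_config("saliency")
  st <- compute_embedding_attribution(linear_embedder_handle, x, cfg,
                                      materialize = FALSE)
  expect_equal(dim(st$XE), c(6, 6))
  # predictor adapter: mean of the window entries
  w <- 1
  pred_factory <- function(wl) linear_handle(matrix(1 / (3 * e), 3, e))
  P <- compute_prediction_attribution(pred_factory, x %*% W, cfg, w = w)
  XP <- compose_XP(P, st$T, w)
  grid <- tibble::tibble(model = "adapter", method = "saliency",
                         mode = "prediction", protein_id = "p1",
                         X = list(unclass(XP)),
                         sequence = paste(random_letters(6, 62),
                                          collapse = ""))
  res <- run_property_tests(grid)
  expect_equal(nrow(res), 14)
  expect_true(all(is.na(res$p_value[res$property == "interactivity"])))
})
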