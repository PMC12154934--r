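lin_fixture <- function(d = 6, seed = 1, b = 0.5) {
  withr::with_seed(seed, list(a = rnorm(d), x = rnorm(d), b = b))
}

test_that("gradient-family operators are exact on linear models", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  expect_equal(unclass(saliency(h, fx$x)), fx$a, ignore_attr = TRUE)
  expect_equal(unclass(input_x_gradient(h, fx$x)), fx$a * fx$x,
               ignore_attr = TRUE)
  expect_equal(unclass(input_x_gradient(h, fx$x * 0)), fx$x * 0,
               ignore_attr = TRUE)
  # constant model: all zeros
  h0 <- linear_handle(fx$a * 0, 3)
  expect_equal(unclass(saliency(h0, fx$x)), fx$a * 0, ignore_attr = TRUE)
})

test_that("saliency matches finite differences on a seeded rectifier net", {
  h <- scalar_relu_net(d = 8, seed = 2)
  eps <- 1e-5
  withr::with_seed(3, {
    for (probe in 1:20) {
      x <- rnorm(8)
      g <- saliency(h, x)
      num <- vapply(1:8, function(j) {
        xp <- x; xp[j] <- xp[j] + eps
        xm <- x; xm[j] <- xm[j] - eps
        (h$forward(xp) - h$forward(xm)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(g - num)) / max(max(abs(num)), 1e-8), 1e-4)
    }
  })
  # input_x_gradient is saliency times the input
  x <- withr::with_seed(4, rnorm(8))
  expect_equal(unclass(input_x_gradient(h, x)),
               unclass(saliency(h, x)) * x, ignore_attr = TRUE)
})

test_that("DeepLIFT obeys its reference semantics and conservation", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  expect_equal(unclass(deeplift(h, fx$x, baseline = fx$x)), fx$x * 0,
               ignore_attr = TRUE)
  expect_equal(unclass(deeplift(h, fx$x)), fx$a * fx$x, ignore_attr = TRUE)
  expect_error(deeplift(h, fx$x, baseline = fx$x[1:3]), "shape")
  # summation-to-delta on 20 seeded rectifier nets
  for (seed in 1:20) {
    hn <- scalar_relu_net(d = 6, seed = seed)
    x <- withr::with_seed(100 + seed, rnorm(6))
    dl <- deeplift(hn, x)
    expect_lt(abs(sum(dl) - (hn$forward(x) - hn$forward(x * 0))), 1e-6)
  }
})

test_that("integrated gradients is exact on linear models and complete", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  expect_equal(unclass(integrated_gradients(h, fx$x, ig_steps = 2)),
               fx$a * fx$x, ignore_attr = TRUE)
  expect_equal(unclass(integrated_gradients(h, fx$x, baseline = fx$x)),
               fx$x * 0, ignore_attr = TRUE)
  expect_error(integrated_gradients(h, fx$x, ig_steps = 1), "ig_steps")
  hn <- scalar_relu_net(d = 8, seed = 5)
  x <- withr::with_seed(6, rnorm(8))
  ig <- integrated_gradients(hn, x, ig_steps = 512)
  expect_lt(abs(sum(ig) - (hn$forward(x) - hn$forward(x * 0))), 1e-3)
})

test_that("GradientSHAP matches its linear closed form and the IG limit", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  # zero-baseline sampler: a * (x - E[b]) = a * x, exactly, noise or not
  gs <- gradientshap(h, fx$x, mc_samples = 50, seed = 7)
  expect_equal(unclass(gs), fx$a * fx$x, ignore_attr = TRUE)
  expect_identical(unclass(gradientshap(h, fx$x, seed = 8)),
                   unclass(gradientshap(h, fx$x, seed = 8)))
  expect_error(gradientshap(h, fx$x, baseline_sampler = "nope"),
               "function")
  # noise 0, zero baseline, many samples: approaches integrated gradients
  hn <- scalar_relu_net(d = 8, seed = 9)
  x <- withr::with_seed(10, rnorm(8))
  ig <- integrated_gradients(hn, x, ig_steps = 512)
  gs2 <- gradientshap(hn, x, mc_samples = 4000, noise_std = 0, seed = 11)
  expect_lt(max(abs(gs2 - ig)) / max(abs(ig)), 0.05)
})

test_that("LIME recovers additive models exactly under full enumeration", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  lm1 <- lime(h, fx$x, enumerate = TRUE, surrogate_ridge = 0)
  expect_lt(max(abs(lm1 - fx$a * fx$x)), 1e-6)
  hconst <- linear_handle(fx$a * 0, 2)
  lm0 <- lime(hconst, fx$x, enumerate = TRUE, surrogate_ridge = 0)
  expect_lt(max(abs(lm0)), 1e-6)
  expect_identical(unclass(lime(h, fx$x, mc_samples = 20, seed = 3)),
                   unclass(lime(h, fx$x, mc_samples = 20, seed = 3)))
  expect_error(lime(h, fx$x, mc_samples = 4), "d \\+ 1")
})

test_that("KernelSHAP is exact under enumeration and efficient always", {
  fx <- lin_fixture()
  h <- linear_handle(fx$a, fx$b)
  ks <- kernelshap(h, fx$x)
  expect_lt(max(abs(ks - fx$a * fx$x)), 1e-8)
  # symmetry: two interchangeable features get equal values
  hsym <- structure(list(
    type = "custom", rule = "true_gradient",
    forward = function(x) x[1] * x[2],
    scalar_forward = function(x, s = NULL) x[1] * x[2]
  ), class = "model_handle")
  kss <- kernelshap(hsym, c(2, 2, 0))
  expect_equal(kss[1], kss[2])
  # brute-force Shapley oracle on a seeded rectifier net, d = 6
  hn <- scalar_relu_net(d = 6, seed = 12)
  x <- withr::with_seed(13, rnorm(6))
  expect_equal(unclass(kernelshap(hn, x)),
               brute_force_shapley(hn$forward, x),
               tolerance = 1e-8, ignore_attr = TRUE)
  # efficiency on seeded nets
  for (seed in 14:16) {
    hn2 <- scalar_relu_net(d = 7, seed = seed)
    x2 <- withr::with_seed(seed + 50, rnorm(7))
    ks2 <- kernelshap(hn2, x2)
    expect_lt(abs(sum(ks2) - (hn2$forward(x2) - hn2$forward(x2 * 0))),
              1e-8)
  }
  expect_identical(
    unclass(kernelshap(hn, x, mc_samples = 100, seed = 1,
                       enumerate = FALSE)),
    unclass(kernelshap(hn, x, mc_samples = 100, seed = 1,
                       enumerate = FALSE)))
})

test_that("sampled KernelSHAP stays within 5% of exact enumeration", {
  # at d = 10 a 2000-coalition budget covers every size stratum, so the
  # budgeted sampler reduces to exact enumeration
  for (seed in c(101, 104)) {
    hn <- scalar_relu_net(d = 10, seed = seed, weight_sd = 0.4)
    x <- withr::with_seed(seed + 1, rnorm(10))
    exact <- kernelshap(hn, x)
    sampled <- kernelshap(hn, x, mc_samples = 2000, seed = seed,
                          enumerate = FALSE)
    expect_lt(max(abs(sampled - exact)) / max(abs(exact)), 0.05)
  }
  # at d = 13 the budget genuinely samples the middle strata
  for (s in 1:2) {
    hn <- scalar_relu_net(d = 13, seed = 200 + s, weight_sd = 0.4)
    x <- withr::with_seed(300 + s, rnorm(13))
    oracle <- brute_force_shapley(hn$forward, x)
    sampled <- kernelshap(hn, x, mc_samples = 2000, seed = s,
                          enumerate = FALSE)
    expect_lt(max(abs(sampled - oracle)) / max(abs(oracle)), 0.05)
  }
})

test_that("all nine methods agree on linear models with zero baseline", {
  fx <- lin_fixture(d = 5, seed = 20)
  h <- linear_handle(fx$a, fx$b)
  ax <- fx$a * fx$x
  expect_equal(unclass(saliency(h, fx$x)), fx$a, ignore_attr = TRUE)
  expect_equal(unclass(deconvolution(h, fx$x)), fx$a, ignore_attr = TRUE)
  expect_equal(unclass(guided_backprop(h, fx$x)), fx$a, ignore_attr = TRUE)
  expect_equal(unclass(input_x_gradient(h, fx$x)), ax, ignore_attr = TRUE)
  expect_equal(unclass(deeplift(h, fx$x)), ax, ignore_attr = TRUE)
  expect_equal(unclass(integrated_gradients(h, fx$x)), ax,
               ignore_attr = TRUE)
  expect_equal(unclass(gradientshap(h, fx$x, seed = 21)), ax,
               ignore_attr = TRUE)
  expect_equal(unclass(lime(h, fx$x, enumerate = TRUE,
                            surrogate_ridge = 0)), ax,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(kernelshap(h, fx$x)), ax, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rule mismatches between handle and method are contract errors", {
  emb <- build_toy_embedder(e = 3, lambda = 1, seed = 22)
  lets <- random_letters(5, 23)
  x <- embedder_input(emb, lets)
  h_true <- as_handle(emb, "true_gradient", letters = lets)
  h_dec <- as_handle(emb, "deconvolution", letters = lets)
  expect_error(deconvolution(h_true, x, c(1, 1)), "deconvolution")
  expect_error(saliency(h_dec, x, c(1, 1)), "true_gradient")
  expect_error(guided_backprop(h_dec, x, c(1, 1)), "guided")
})
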