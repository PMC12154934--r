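#' @title Attribution operators
#' @description
#' Nine feature-attribution operators over the differentiable-model handle
#' contract (see [as_handle()]). Each returns an attribution map shaped like
#' the model input: the importance of every input element for one scalar
#' output. Gradient-family methods need only `scalar_gradient`; the local
#' surrogate methods (LIME, KernelSHAP) need only `forward`; DeepLIFT uses
#' the handle's rescale-rule backward pass. None of the published
#' hyperparameters were stated for these operators, so the defaults in
#' [attribution_config()] follow common practice and are recorded with every
#' run.
#' @name attribution_methods
NULL

#' Attribution configuration
#'
#' Collects the hyperparameters of the stochastic/path operators so a whole
#' grid run can pin them once. `mc_samples` defaults to 200 for LIME and
#' KernelSHAP and 50 for GradientSHAP; `lime_kernel_width` defaults to
#' `0.75 * sqrt(d)` at call time.
#'
#' @param method One of [XAI_METHODS].
#' @param baseline Reference input for path methods (default: all zeros,
#'   the activation of an absent token).
#' @param ig_steps Integrated-gradients resolution (midpoint rule, >= 2).
#' @param mc_samples Monte-Carlo sample count for lime/kernelshap/gradientshap.
#' @param noise_std GradientSHAP interpolation jitter.
#' @param lime_kernel_width LIME proximity kernel width (`NULL` = default).
#' @param surrogate_ridge Ridge penalty of the LIME surrogate.
#' @param seed Integer seed used by every stochastic operator.
#' @return A list of class `attribution_config`.
#' @export
attribution_config <- function(method, baseline = NULL, ig_steps = 50,
                               mc_samples = NULL, noise_std = 0.1,
                               lime_kernel_width = NULL,
                               surrogate_ridge = 1e-3, seed = 1) {
  method <- match.arg(method, XAI_METHODS)
  if (ig_steps < 2) abort("`ig_steps` must be >= 2")
  if (is.null(mc_samples)) {
    mc_samples <- switch(method, lime = 200L, kernelshap = 200L,
                         gradientshap = 50L, 0L)
  }
  structure(list(method = method, baseline = baseline, ig_steps = ig_steps,
                 mc_samples = as.integer(mc_samples), noise_std = noise_std,
                 lime_kernel_width = lime_kernel_width,
                 surrogate_ridge = surrogate_ridge, seed = as.integer(seed)),
            class = "attribution_config")
}

as_map <- function(values, method, selector = NULL) {
  if (any(!is.finite(values))) {
    abort(sprintf("%s produced non-finite attribution values", method))
  }
  attr(values, "method") <- method
  attr(values, "selector") <- selector
  values
}

zero_like <- function(x) {
  z <- x
  z[] <- 0
  z
}

check_rule <- function(handle, expected, method) {
  if (!identical(handle$rule, expected)) {
    abort(sprintf(
      "%s requires a handle built with backprop_rule = '%s' (got '%s')",
      method, expected, handle$rule))
  }
}

#' Saliency (vanilla gradient)
#'
#' The gradient of the selected scalar output with respect to the input
#' activations.
#'
#' @param handle A `model_handle` built with the `true_gradient` rule.
#' @param x Input activations (array shaped as the model expects).
#' @param output_selector Which scalar output to explain (e.g. `c(i, k)` for
#'   an embedder; ignored for scalar-output models).
#' @return An attribution map shaped like `x`.
#' @export
saliency <- function(handle, x, output_selector = NULL) {
  check_rule(handle, "true_gradient", "saliency")
  as_map(handle$scalar_gradient(x, output_selector), "saliency",
         output_selector)
}

#' Input-times-gradient
#'
#' Elementwise product of the saliency map with the input itself.
#'
#' @inheritParams saliency
#' @return An attribution map shaped like `x`.
#' @export
input_x_gradient <- function(handle, x, output_selector = NULL) {
  check_rule(handle, "true_gradient", "input_x_gradient")
  as_map(handle$scalar_gradient(x, output_selector) * x,
         "input_x_gradient", output_selector)
}

#' Deconvolution
#'
#' Backward pass in which rectifiers pass through only the positive part of
#' the upstream signal, regardless of the forward activation.
#'
#' @param handle A `model_handle` built with `backprop_rule =
#'   "deconvolution"` (linear handles, which have no rectifiers, are also
#'   accepted: all rules coincide there).
#' @inheritParams saliency
#' @return An attribution map shaped like `x`.
#' @export
deconvolution <- function(handle, x, output_selector = NULL) {
  if (handle$type != "linear") check_rule(handle, "deconvolution",
                                          "deconvolution")
  as_map(handle$scalar_gradient(x, output_selector), "deconvolution",
         output_selector)
}

#' Guided backpropagation
#'
#' Backward pass combining the saliency and deconvolution masks: signal is
#' zeroed where either the forward pre-activation or the upstream signal is
#' non-positive.
#'
#' @param handle A `model_handle` built with `backprop_rule = "guided"`
#'   (linear handles accepted, as for [deconvolution()]).
#' @inheritParams saliency
#' @return An attribution map shaped like `x`.
#' @export
guided_backprop <- function(handle, x, output_selector = NULL) {
  if (handle$type != "linear") check_rule(handle, "guided", "guided_backprop")
  as_map(handle$scalar_gradient(x, output_selector), "guided_backprop",
         output_selector)
}

#' DeepLIFT (rescale rule)
#'
#' Reference-based contributions: each nonlinearity propagates the ratio of
#' activation difference to pre-activation difference, so contributions are
#' non-zero even where gradients vanish and satisfy summation-to-delta:
#' the map sums to `f(x) - f(baseline)`.
#'
#' @inheritParams saliency
#' @param baseline Reference input, same shape as `x` (default all zeros).
#' @return An attribution map shaped like `x`.
#' @export
deeplift <- function(handle, x, baseline = NULL, output_selector = NULL) {
  baseline <- baseline %||% zero_like(x)
  if (!identical(dim(baseline), dim(x)) ||
      length(baseline) != length(x)) {
    abort("`baseline` must have the shape of `x`")
  }
  if (is.null(handle$deeplift_attr)) {
    abort("this handle does not implement the DeepLIFT backward pass")
  }
  as_map(handle$deeplift_attr(x, baseline, output_selector), "deeplift",
         output_selector)
}

#' Integrated gradients
#'
#' Path integral of the gradient along the straight line from the baseline
#' to `x`, approximated with a midpoint Riemann sum of `ig_steps` points and
#' multiplied elementwise by `x - baseline`. Satisfies completeness in the
#' many-step limit.
#'
#' @inheritParams deeplift
#' @param ig_steps Number of midpoint evaluations (>= 2).
#' @return An attribution map shaped like `x`.
#' @export
integrated_gradients <- function(handle, x, baseline = NULL, ig_steps = 50,
                                 output_selector = NULL) {
  check_rule(handle, "true_gradient", "integrated_gradients")
  if (ig_steps < 2) abort("`ig_steps` must be >= 2")
  baseline <- baseline %||% zero_like(x)
  diffs <- x - baseline
  acc <- zero_like(x)
  for (s in seq_len(ig_steps)) {
    alpha <- (s - 0.5) / ig_steps
    acc <- acc + handle$scalar_gradient(baseline + alpha * diffs,
                                        output_selector)
  }
  as_map(diffs * acc / ig_steps, "integrated_gradients", output_selector)
}

#' GradientSHAP
#'
#' Monte-Carlo SHAP estimate under the assumptions of feature independence
#' and a linear explanation model: the mean over samples of
#' `(x - b) * grad(f)` evaluated at a jittered random interpolation between
#' a sampled baseline `b` and `x`.
#'
#' @inheritParams saliency
#' @param baseline_sampler Function of one argument (the draw index)
#'   returning a baseline shaped like `x`; default returns all zeros.
#' @param mc_samples Number of draws (>= 1).
#' @param noise_std Standard deviation of the Gaussian jitter.
#' @param seed Integer seed (bit-reproducible output).
#' @return An attribution map shaped like `x`.
#' @export
gradientshap <- function(handle, x, baseline_sampler = NULL, mc_samples = 50,
                         noise_std = 0.1, seed = 1, output_selector = NULL) {
  check_rule(handle, "true_gradient", "gradientshap")
  if (mc_samples < 1) abort("`mc_samples` must be >= 1")
  baseline_sampler <- baseline_sampler %||% function(i) zero_like(x)
  if (!is.function(baseline_sampler)) {
    abort("`baseline_sampler` must be a function of the draw index")
  }
  d <- length(x)
  withr::with_seed(as.integer(seed), {
    acc <- zero_like(x)
    for (s in seq_len(mc_samples)) {
      b <- baseline_sampler(s)
      if (length(b) != d) abort("degenerate baseline sampler output")
      u <- runif(1)
      noise <- rnorm(d, 0, noise_std)
      point <- b + u * (x - b) + noise
      acc <- acc + (x - b) * handle$scalar_gradient(point, output_selector)
    }
    as_map(acc / mc_samples, "gradientshap", output_selector)
  })
}

# all 2^d mask rows (d small), or mc_samples random rows
lime_masks <- function(d, mc_samples, enumerate) {
  if (enumerate) {
    m <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    dimnames(m) <- NULL
    m
  } else {
    matrix(as.numeric(runif(mc_samples * d) < 0.5), mc_samples, d)
  }
}

#' LIME
#'
#' Fits a proximity-weighted ridge linear surrogate to the model's outputs
#' on binary-mask perturbations of `x` (masked elements set to the
#' baseline); the surrogate coefficients are the attributions. One feature
#' per input element.
#'
#' @inheritParams saliency
#' @param mc_samples Number of mask draws (must be at least `d + 1` for an
#'   identifiable surrogate); ignored when `enumerate = TRUE`.
#' @param lime_kernel_width Proximity kernel width; the weight of a mask
#'   with `m` masked elements is `exp(-m / width^2)`. Default
#'   `0.75 * sqrt(d)`.
#' @param surrogate_ridge Ridge penalty on the surrogate coefficients
#'   (the intercept is unpenalized); 0 gives ordinary weighted least squares.
#' @param seed Integer seed.
#' @param baseline Values replacing masked elements (default zeros).
#' @param enumerate Evaluate all `2^d` masks instead of sampling (only
#'   sensible for small `d`).
#' @return An attribution map shaped like `x`.
#' @export
lime <- function(handle, x, mc_samples = 200, lime_kernel_width = NULL,
                 surrogate_ridge = 1e-3, seed = 1, output_selector = NULL,
                 baseline = NULL, enumerate = FALSE) {
  d <- length(x)
  if (!enumerate && mc_samples < d + 1) {
    abort(sprintf("LIME needs mc_samples >= d + 1 = %d", d + 1))
  }
  baseline <- baseline %||% zero_like(x)
  width <- lime_kernel_width %||% (0.75 * sqrt(d))
  withr::with_seed(as.integer(seed), {
    Z <- lime_masks(d, mc_samples, enumerate)
    y <- apply(Z, 1, function(m) {
      xm <- x
      xm[m == 0] <- baseline[m == 0]
      handle$scalar_forward(xm, output_selector)
    })
    wts <- exp(-(d - rowSums(Z)) / width^2)
    Xd <- cbind(1, Z)
    XtW <- t(Xd * wts)
    A <- XtW %*% Xd
    pen <- diag(c(0, rep(surrogate_ridge, d)), d + 1)
    coefs <- tryCatch(solve(A + pen, XtW %*% y), error = function(e) {
      abort("singular weighted design in the LIME surrogate fit")
    })
    values <- zero_like(x)
    values[] <- coefs[-1]
    as_map(values, "lime", output_selector)
  })
}

shapley_kernel_weights <- function(d, sizes) {
  (d - 1) / (choose(d, sizes) * sizes * (d - sizes))
}

#' KernelSHAP
#'
#' Shapley values estimated by Shapley-kernel-weighted least squares over
#' feature coalitions (masked elements set to the baseline), with the
#' efficiency constraint that the attributions sum to
#' `f(x) - f(baseline)` enforced exactly. All `2^d` coalitions are
#' enumerated automatically when `2^d <= 4096`, in which case the result
#' equals the exact Shapley values; otherwise coalitions are sampled from
#' the Shapley kernel distribution.
#'
#' @inheritParams saliency
#' @param mc_samples Number of sampled coalitions when not enumerating.
#' @param seed Integer seed.
#' @param baseline Values for masked-out elements (default zeros).
#' @param enumerate Force (`TRUE`) or forbid (`FALSE`) full enumeration;
#'   `NULL` (default) enumerates automatically when `2^d <= 4096`.
#' @return An attribution map shaped like `x`.
#' @export
kernelshap <- function(handle, x, mc_samples = 200, seed = 1,
                       output_selector = NULL, baseline = NULL,
                       enumerate = NULL) {
  d <- length(x)
  if (d < 2) abort("KernelSHAP needs at least 2 input elements")
  baseline <- baseline %||% zero_like(x)
  f_empty <- handle$scalar_forward(baseline, output_selector)
  f_full <- handle$scalar_forward(x, output_selector)
  eval_mask <- function(m) {
    xm <- x
    xm[m == 0] <- baseline[m == 0]
    handle$scalar_forward(xm, output_selector)
  }
  enumerate <- enumerate %||% (2^d <= 4096)
  if (enumerate) {
    Z <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    dimnames(Z) <- NULL
    sizes <- rowSums(Z)
    keep <- sizes > 0 & sizes < d
    Z <- Z[keep, , drop = FALSE]
    sizes <- sizes[keep]
    wts <- shapley_kernel_weights(d, sizes)
    y <- apply(Z, 1, eval_mask)
  } else {
    # budgeted stratified sampling in the style of the reference SHAP
    # implementation: complete coalition-size strata (paired s and d-s,
    # which carry the largest kernel mass) are enumerated outright while
    # the budget allows; the remaining budget samples the leftover sizes
    # from the kernel law, with antithetic complements
    size_support <- seq_len(d - 1)
    size_mass <- shapley_kernel_weights(d, size_support) *
      choose(d, size_support)
    pair_of <- pmin(size_support, d - size_support)
    enum_pairs <- integer(0)
    budget <- mc_samples
    for (s in seq_len(floor(d / 2))) {
      stratum_sizes <- unique(c(s, d - s))
      n_stratum <- sum(choose(d, stratum_sizes))
      if (n_stratum <= budget) {
        enum_pairs <- c(enum_pairs, s)
        budget <- budget - n_stratum
      } else break
    }
    enum_sizes <- size_support[pair_of %in% enum_pairs]
    Z_enum <- NULL
    if (length(enum_sizes) > 0) {
      Z_enum <- do.call(rbind, lapply(enum_sizes, function(s) {
        t(combn(d, s, function(idx) {
          m <- numeric(d)
          m[idx] <- 1
          m
        }))
      }))
    }
    samp_sizes <- setdiff(size_support, enum_sizes)
    Z_samp <- NULL
    if (length(samp_sizes) > 0 && budget >= 2) {
      Z_samp <- withr::with_seed(as.integer(seed), {
        prob <- size_mass[samp_sizes]
        sz <- sample(samp_sizes, ceiling(budget / 2), replace = TRUE,
                     prob = prob / sum(prob))
        half <- t(vapply(sz, function(s) {
          m <- numeric(d)
          m[sample.int(d, s)] <- 1
          m
        }, numeric(d)))
        rbind(half, 1 - half)
      })
    }
    Z <- rbind(Z_enum, Z_samp)
    if (is.null(Z) || nrow(unique(Z)) < 2) {
      abort("degenerate coalition sample")
    }
    sizes <- rowSums(Z)
    # enumerated rows carry their exact kernel weight; sampled rows share
    # the residual kernel mass of the un-enumerated sizes
    wts <- shapley_kernel_weights(d, sizes)
    if (!is.null(Z_samp)) {
      resid_mass <- sum(size_mass[samp_sizes])
      idx_samp <- seq(nrow(Z) - nrow(Z_samp) + 1, nrow(Z))
      wts[idx_samp] <- resid_mass / nrow(Z_samp)
    }
    y <- apply(Z, 1, eval_mask)
  }
  # constrained weighted least squares via KKT:
  # minimize sum_S w_S (f_empty + phi.Z_S - y_S)^2  s.t.  sum(phi) = f_full - f_empty
  A <- crossprod(Z * wts, Z)
  rhs <- crossprod(Z * wts, y - f_empty)
  KKT <- rbind(cbind(2 * A, rep(1, d)), c(rep(1, d), 0))
  sol <- tryCatch(solve(KKT, c(2 * rhs, f_full - f_empty)),
                  error = function(e) abort("singular KernelSHAP system"))
  values <- zero_like(x)
  values[] <- sol[seq_len(d)]
  as_map(values, "kernelshap", output_selector)
}

#' Run one configured attribution method
#'
#' Dispatch wrapper mapping an [attribution_config()] to the corresponding
#' operator; used by the tensor drivers and the pipeline.
#'
#' @param handle A `model_handle` whose rule matches the method (see
#'   [rule_for_method()]).
#' @param x Input activations.
#' @param config An `attribution_config`.
#' @param output_selector Scalar output selector.
#' @return An attribution map shaped like `x`.
#' @export
run_attribution <- function(handle, x, config, output_selector = NULL) {
  stopifnot(inherits(config, "attribution_config"))
  switch(config$method,
    saliency = saliency(handle, x, output_selector),
    input_x_gradient = input_x_gradient(handle, x, output_selector),
    deconvolution = deconvolution(handle, x, output_selector),
    guided_backprop = guided_backprop(handle, x, output_selector),
    deeplift = deeplift(handle, x, config$baseline, output_selector),
    integrated_gradients = integrated_gradients(handle, x, config$baseline,
                                                config$ig_steps,
                                                output_selector),
    gradientshap = gradientshap(handle, x, NULL, config$mc_samples,
                                config$noise_std, config$seed,
                                output_selector),
    lime = lime(handle, x, config$mc_samples, config$lime_kernel_width,
                config$surrogate_ridge, config$seed, output_selector,
                config$baseline),
    kernelshap = kernelshap(handle, x, config$mc_samples, config$seed,
                            output_selector, config$baseline)
  )
}

#' Backpropagation rule required by a method
#'
#' @param method One of [XAI_METHODS].
#' @return The `backprop_rule` string the handle must be built with.
#' @export
rule_for_method <- function(method) {
  switch(match.arg(method, XAI_METHODS),
         deconvolution = "deconvolution",
         guided_backprop = "guided",
         "true_gradient")
}
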