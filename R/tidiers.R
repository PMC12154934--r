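#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a property-test result set
#'
#' @param x A `property_tests` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per statistical test.
#' @export
tidy.property_tests <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a property-test result set
#'
#' @param x A `property_tests` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of tests, passes, not-evaluable tests,
#'   and the significance level used.
#' @export
glance.property_tests <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_passed = sum(x$passed, na.rm = TRUE),
    n_not_evaluable = sum(is.na(x$passed)),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' Tidy a pass-count summary
#'
#' @param x A `pass_summary` object.
#' @param ... Unused.
#' @return The method x model pass-count table as a tibble.
#' @export
tidy.pass_summary <- function(x, ...) x$by_method_model

#' One-row overview of a pass-count summary
#'
#' @param x A `pass_summary` object.
#' @param ... Unused.
#' @return A one-row tibble with grand totals and pass percentages.
#' @export
glance.pass_summary <- function(x, ...) {
  t <- x$totals
  tibble(
    n_tests = t$n_tests[t$test_type == "all"],
    n_passed = t$n_passed[t$test_type == "all"],
    pct_passed = t$pct_passed[t$test_type == "all"],
    pct_categorical = t$pct_passed[t$test_type == "categorical"],
    pct_numerical = t$pct_passed[t$test_type == "numerical"],
    alpha = x$alpha
  )
}

#' Tidy an infidelity record
#'
#' @param x An `infidelity_record`.
#' @param ... Unused.
#' @return A long tibble of the per-element (`I_E`) or per-residue (`I_P`)
#'   infidelities.
#' @export
tidy.infidelity_record <- function(x, ...) {
  if (!is.null(x$I_E)) {
    tibble(
      residue = rep(seq_len(nrow(x$I_E)), ncol(x$I_E)),
      element = rep(seq_len(ncol(x$I_E)), each = nrow(x$I_E)),
      infidelity = as.vector(x$I_E)
    )
  } else {
    tibble(residue = seq_along(x$I_P), infidelity = x$I_P)
  }
}

#' One-row summary of an infidelity record
#'
#' @param x An `infidelity_record`.
#' @param ... Unused.
#' @return A one-row tibble with the scalar aggregate (`INFD_E` or
#'   `INFD_P`) and the perturbation parameters.
#' @export
glance.infidelity_record <- function(x, ...) {
  tibble(
    infd = x$INFD_E %||% x$INFD_P,
    mode = if (!is.null(x$INFD_E)) "embedding" else "prediction",
    sd = x$perturbation$sd,
    n_samples = x$perturbation$n_samples
  )
}
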