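#' Mann-Whitney U test
#'
#' Nonparametric two-sample test of distribution equality, reported as the
#' U statistic of the first group (midrank tie handling). The two-sided
#' p-value comes from exact enumeration when `n1 * n2 <= 200` and the data
#' are tie-free, and from the tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A one-row tibble: `statistic` (U of `group_a`), `p_value`,
#'   `n_a`, `n_b`, `exact` (logical).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n1 * n2 <= 200) && !ties
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  tibble(statistic = unname(u), p_value = ht$p.value,
         n_a = n1, n_b = n2, exact = exact)
}

#' Kendall rank correlation test
#'
#' Kendall's tau-b with tie correction; the two-sided p-value uses the
#' tie-corrected normal approximation (the published 20-vector tests are at
#' the edge of exactness, and ties in property columns rule exact
#' enumeration out in general).
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return A one-row tibble: `statistic` (tau-b), `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must share length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Kendall's tau is undefined for constant input")
  }
  ht <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = FALSE, continuity = FALSE)
  )
  tibble(statistic = unname(ht$estimate), p_value = ht$p.value,
         n = length(x))
}

# split pooled residue scores into the two groups of a categorical property
categorical_groups <- function(pooled, property, score_col) {
  switch(property,
    interactivity = {
      if (all(is.na(pooled$label))) return(NULL)
      ok <- !is.na(pooled$label)
      list(a = pooled[[score_col]][ok & pooled$label == 1],
           b = pooled[[score_col]][ok & pooled$label == 0])
    },
    aromaticity = {
      arom <- pooled$letter %in% c("F", "Y", "W")
      list(a = pooled[[score_col]][arom], b = pooled[[score_col]][!arom])
    },
    acid_base = {
      # only acidic (D, E) vs basic (H, K, R) residues enter this test
      acid <- pooled$letter %in% c("D", "E")
      base <- pooled$letter %in% c("H", "K", "R")
      list(a = pooled[[score_col]][acid], b = pooled[[score_col]][base])
    },
    abort(sprintf("unknown categorical property '%s'", property))
  )
}

#' Run the property test battery over a grid of impact matrices
#'
#' For every `(model, method, mode)` cell and each role (target, source)
#' this runs the three Mann-Whitney categorical tests on the pooled
#' per-residue scores -- interacting vs non-interacting residues, aromatic
#' (F, Y, W) vs non-aromatic, and acidic (D, E) vs basic (H, K, R) -- and
#' the four Kendall tests of the per-amino-acid 20-vector of mean scores
#' against hydrophobicity, molecular mass, van der Waals volume and dipole
#' moment: 7 properties x 2 roles x 2 modes per (model, method). A test
#' whose category is empty in the corpus (e.g. no labels available for
#' interactivity) is marked not evaluable (`NA` p-value, `NA` pass), never
#' silently passed.
#'
#' @param grid Tibble with one row per (model, method, mode, protein):
#'   columns `model`, `method`, `mode`, `protein_id`, `X` (list of square
#'   matrices), `sequence`, and optionally `labels` (list of 0/1 vectors).
#' @param property_table Output of [load_property_table()].
#' @param alpha Significance level (default 0.05).
#' @param transform Score transform, `"signed"` (default) or `"absolute"`.
#' @return A tibble of class `property_tests`: one row per test with
#'   `model`, `method`, `mode`, `role`, `property`, `test_type`,
#'   `statistic`, `tau`, `p_value`, `passed`.
#' @export
run_property_tests <- function(grid, property_table = load_property_table(),
                               alpha = 0.05,
                               transform = c("signed", "absolute")) {
  transform <- match.arg(transform)
  needed <- c("model", "method", "mode", "protein_id", "X", "sequence")
  if (!all(needed %in% names(grid))) {
    abort(paste0("`grid` must have columns ", paste(needed, collapse = ", ")))
  }
  has_labels <- "labels" %in% names(grid)
  cells <- grid %>% distinct(.data$model, .data$method, .data$mode)
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    sub <- grid %>%
      filter(.data$model == cell$model, .data$method == cell$method,
             .data$mode == cell$mode)
    pooled <- pool_scores(sub$X, sub$sequence,
                          if (has_labels) sub$labels else NULL, transform)
    purrr::map_dfr(c("target", "source"), function(role) {
      score_col <- paste0(role, "_score")
      cat_rows <- purrr::map_dfr(categorical_properties(), function(prop) {
        groups <- categorical_groups(pooled, prop, score_col)
        if (is.null(groups) || length(groups$a) == 0 ||
            length(groups$b) == 0) {
          return(tibble(property = prop, test_type = "categorical",
                        statistic = NA_real_, tau = NA_real_,
                        p_value = NA_real_))
        }
        mw <- mann_whitney_u(groups$a, groups$b)
        tibble(property = prop, test_type = "categorical",
               statistic = mw$statistic, tau = NA_real_,
               p_value = mw$p_value)
      })
      vec <- amino_acid_mean_scores(pooled, role)
      num_rows <- purrr::map_dfr(numerical_properties(), function(prop) {
        props <- property_table[[prop]][match(vec$letter,
                                              property_table$letter)]
        ok <- !is.na(vec$mean_score)
        # degenerate (too few letters, constant scores): not evaluable
        if (sum(ok) < 3 || sd(vec$mean_score[ok]) == 0) {
          return(tibble(property = prop, test_type = "numerical",
                        statistic = NA_real_, tau = NA_real_,
                        p_value = NA_real_))
        }
        kt <- kendall_tau(vec$mean_score[ok], props[ok])
        tibble(property = prop, test_type = "numerical",
               statistic = kt$statistic, tau = kt$statistic,
               p_value = kt$p_value)
      })
      bind_rows(cat_rows, num_rows) %>%
        mutate(model = cell$model, method = cell$method, mode = cell$mode,
               role = role, .before = 1)
    })
  })
  res <- res %>% mutate(passed = ifelse(is.na(.data$p_value), NA,
                                        .data$p_value < alpha))
  attr(res, "alpha") <- alpha
  attr(res, "transform") <- transform
  class(res) <- c("property_tests", class(res))
  res
}
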