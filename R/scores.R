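#' Per-residue target and source scores of a residue-impact matrix
#'
#' Row means give the target score (impact the residue receives), column
#' means the source score (impact it exerts). The transform is applied to
#' the matrix entries first: `"signed"` keeps the raw signed sums (the
#' default for the property tests), `"absolute"` takes magnitudes (the
#' default for distance profiles).
#'
#' @param X A square numeric matrix or [impact_matrix()].
#' @param transform `"signed"` or `"absolute"`.
#' @return A tibble with columns `residue`, `target_score`, `source_score`
#'   and a `transform` attribute.
#' @export
residue_scores <- function(X, transform = c("signed", "absolute")) {
  transform <- match.arg(transform)
  if (!is.matrix(X) || nrow(X) != ncol(X)) abort("`X` must be square")
  if (any(!is.finite(X))) abort("`X` has non-finite entries")
  M <- if (transform == "absolute") abs(X) else unclass(X)
  out <- tibble(
    residue = seq_len(nrow(X)),
    target_score = rowMeans(M),
    source_score = colMeans(M)
  )
  attr(out, "transform") <- transform
  out
}

# pool per-residue scores across a corpus: one row per residue with its
# amino-acid letter and (optional) interaction label
pool_scores <- function(matrices, sequences, labels = NULL,
                        transform = "signed") {
  stopifnot(length(matrices) == length(sequences))
  purrr::map_dfr(seq_along(matrices), function(p) {
    sc <- residue_scores(matrices[[p]], transform)
    sc$letter <- seq_letters(sequences[[p]])
    sc$label <- if (!is.null(labels) && !is.null(labels[[p]])) {
      labels[[p]]
    } else {
      NA_integer_
    }
    sc$protein <- p
    sc
  })
}

#' Per-amino-acid mean score vector
#'
#' Pools residue scores across proteins and averages them per amino-acid
#' letter, yielding the 20-vector (alphabetical order) used by the Kendall
#' property tests. Letters absent from the corpus are flagged with `NA`.
#'
#' @param scores Tibble with columns `letter` and the chosen score column
#'   (e.g. the output of pooling [residue_scores()] over proteins).
#' @param role `"target"` or `"source"` (selects `target_score` /
#'   `source_score`).
#' @return A tibble with 20 rows: `letter`, `mean_score`, `n_residues`.
#' @export
amino_acid_mean_scores <- function(scores, role = c("target", "source")) {
  role <- match.arg(role)
  if (nrow(scores) == 0) abort("empty score corpus")
  col <- paste0(role, "_score")
  if (!col %in% names(scores)) {
    abort(sprintf("`scores` must carry a `%s` column", col))
  }
  agg <- scores %>%
    group_by(.data$letter) %>%
    summarise(mean_score = mean(.data[[col]]), n_residues = dplyr::n(),
              .groups = "drop")
  tibble(letter = AA_ALPHABET) %>%
    left_join(agg, by = "letter") %>%
    mutate(n_residues = ifelse(is.na(.data$n_residues), 0L,
                               .data$n_residues))
}

#' Mean impact as a function of sequence separation
#'
#' For each linear distance `d` in `0..max_distance`, the mean transformed
#' impact over all ordered residue pairs with `|i - j| = d`, pooled across
#' the supplied matrices. Distances with no pairs in the corpus are flagged
#' with `NA` means and `n_pairs = 0`.
#'
#' @param matrices A list of square matrices (or a single matrix).
#' @param max_distance Largest separation to profile (default 20).
#' @param transform `"absolute"` (default) or `"signed"`.
#' @return A tibble of class `distance_profile` with columns `distance`,
#'   `mean_impact`, `n_pairs`.
#' @export
distance_profile <- function(matrices, max_distance = 20,
                             transform = c("absolute", "signed")) {
  transform <- match.arg(transform)
  if (is.matrix(matrices)) matrices <- list(matrices)
  sums <- numeric(max_distance + 1)
  counts <- integer(max_distance + 1)
  for (X in matrices) {
    if (!is.matrix(X) || nrow(X) != ncol(X)) abort("matrices must be square")
    M <- if (transform == "absolute") abs(X) else unclass(X)
    n <- nrow(M)
    idx <- abs(outer(seq_len(n), seq_len(n), "-"))
    for (d in 0:min(max_distance, n - 1)) {
      vals <- M[idx == d]
      sums[d + 1] <- sums[d + 1] + sum(vals)
      counts[d + 1] <- counts[d + 1] + length(vals)
    }
  }
  out <- tibble(
    distance = 0:max_distance,
    mean_impact = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
    n_pairs = counts
  )
  attr(out, "transform") <- transform
  class(out) <- c("distance_profile", class(out))
  out
}
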