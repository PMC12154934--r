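#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   scale_fill_gradient2 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heat map of a residue-impact matrix
#'
#' Rows are target residues (impact received), columns are source residues
#' (impact exerted), matching the orientation of the published matrix
#' figures.
#'
#' @param X A square matrix or [impact_matrix()].
#' @param letters Optional residue letters for axis labels.
#' @return A ggplot object.
#' @export
plot_impact_matrix <- function(X, letters = NULL) {
  n <- nrow(X)
  df <- tibble(
    target = rep(seq_len(n), n),
    source = rep(seq_len(n), each = n),
    impact = as.vector(unclass(X))
  )
  p <- ggplot(df, aes(x = .data$source, y = .data$target,
                      fill = .data$impact)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "source residue", y = "target residue",
         fill = "impact",
         title = attr(X, "mode") %||% NULL) +
    theme_minimal()
  p
}

#' @export
autoplot.residue_impact <- function(object, ...) plot_impact_matrix(object)

#' Line plot of a distance profile
#'
#' @param object A [distance_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot(dplyr::filter(object, !is.na(.data$mean_impact)),
         aes(x = .data$distance, y = .data$mean_impact)) +
    geom_line() + geom_point() +
    labs(x = "sequence separation |i - j|",
         y = "mean impact") +
    theme_minimal()
}

#' @rdname autoplot.distance_profile
#' @param profile A [distance_profile()] tibble.
#' @export
plot_distance_profile <- function(profile) autoplot.distance_profile(profile)
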