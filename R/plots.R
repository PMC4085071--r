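## ggplot2 displays for the two result types: diversity profiles over q and
## similarity/differentiation profiles.

#' Plot a diversity profile
#'
#' One panel per measure (Hill number, functional Hill number, mean and
#' total functional diversity) against the order q, one line per assemblage
#' where several are present.
#'
#' @param object A `funhill_profile` tibble from [func_diversity()] or
#'   [diversity_profile()].
#' @param measures Measures to show, subset of `c("hill", "D", "MD", "FD")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funhill_profile <- function(object, measures = c("hill", "D", "MD", "FD"), ...) {
  measures <- match.arg(measures, several.ok = TRUE)
  df <- as_tibble(object)
  if (!"assemblage" %in% names(df)) df$assemblage <- "assemblage"
  long <- tidyr::pivot_longer(df, cols = dplyr::any_of(measures),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("hill", "D", "MD", "FD"),
                         labels = c("Hill number", "functional Hill number",
                                    "mean functional diversity",
                                    "total functional diversity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q, y = .data$value,
                                     colour = .data$assemblage)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "order q", y = "effective diversity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot differentiation profiles
#'
#' Differentiation (one minus similarity) against the order q, one line per
#' comparison, one panel per similarity class.
#'
#' @param object A `funhill_similarity` tibble from [func_similarity()].
#' @param what `"differentiation"` (default) or `"similarity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funhill_similarity <- function(object, what = c("differentiation", "similarity"), ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data[[what]],
                                   colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "order q", y = what, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.funhill_profile
#' @param data Community table passed to [func_diversity()].
#' @param dist Distance matrix.
#' @param q Grid of orders.
#' @export
plot_diversity_profile <- function(data, dist, q = seq(0, 5, by = 0.05)) {
  autoplot(func_diversity(data, dist, q = q))
}

#' @rdname autoplot.funhill_similarity
#' @param data Community table passed to [func_similarity()].
#' @param dist Distance matrix.
#' @param q Grid of orders.
#' @param classes Similarity classes to profile.
#' @param pairwise Profile assemblage pairs separately.
#' @export
plot_differentiation_profile <- function(data, dist, q = seq(0, 5, by = 0.05),
                                         classes = c("local", "regional"),
                                         pairwise = FALSE) {
  autoplot(func_similarity(data, dist, q = q, classes = classes, pairwise = pairwise))
}
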