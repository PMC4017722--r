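#' Plot a diversity rank/score graph
#'
#' The rank/score curve of one system pair: diversity score against
#' descending rank. Pairs whose curve lies higher disagree more across the
#' compound set and are stronger fusion candidates.
#'
#' @param object A [diversity_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diversity_profile
#' @export
autoplot.diversity_profile <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "rank j", y = "diversity score f(j)",
      title = paste0("Diversity rank/score graph: ",
                     pair[1], " vs ", pair[2]),
      subtitle = paste0("aggregate = ",
                        signif(attr(object, "aggregate"), 4),
                        " (", attr(object, "scale"), " scale)")
    )
}

#' Overlay all pairwise diversity rank/score graphs
#'
#' One curve per system pair, coloured by pair, for visual comparison of
#' which pairs are the most diverse.
#'
#' @param profiles Output of [all_pair_profiles()].
#' @return A ggplot object.
#' @export
plot_divgraphs <- function(profiles) {
  long <- profiles %>%
    mutate(pair = paste0(.data$system_a, "+", .data$system_b)) %>%
    select("pair", "profile") %>%
    tidyr::unnest("profile")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$score,
                                     colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank j", y = "diversity score f(j)",
                  colour = "pair",
                  title = "Diversity rank/score graphs")
}

#' Plot a fusion leaderboard
#'
#' Correlation of every score combination, ordered best-first, with subset
#' size mapped to colour; the dashed line marks the best individual system.
#'
#' @param object A [fusion_leaderboard()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_leaderboard
#' @export
autoplot.fusion_leaderboard <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(label = factor(.data$label, levels = rev(.data$label)))
  best_single <- max(df$r_test[df$size == 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_test, y = .data$label,
                                   colour = factor(.data$size))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best_single, linetype = "dashed") +
    ggplot2::labs(x = "correlation (r)", y = NULL, colour = "subset size",
                  title = "Score-combination leaderboard")
}
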