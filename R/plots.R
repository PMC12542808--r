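# ggplot2 views of the main result types.

#' Heatmap of per-sample locus recovery
#'
#' @param records Long-format recovery tibble (see [build_sample_stats()]).
#' @param what `"recovery"` (fraction of target length, capped at 1) or
#'   `"paralogs"`.
#' @return A ggplot object.
#' @export
plot_recovery_heatmap <- function(records, what = c("recovery", "paralogs")) {
  what <- match.arg(what)
  mats <- recovery_matrix(records)
  m <- mats[[what]]
  df <- tibble(
    sample = rep(rownames(m), times = ncol(m)),
    locus = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$sample,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "locus", y = NULL)
}

#' Scatter of parsimony-informative sites against alignment length
#'
#' @param stats Tibble from [alignment_stats_table()].
#' @return A ggplot object.
#' @export
plot_alignment_stats <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$length,
                                      y = .data$n_parsimony_informative)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "alignment length (bp)",
                  y = "parsimony-informative sites")
}

#' Stacked per-branch quartet support
#'
#' One bar per internal branch showing the normalized frequencies of the
#' main and the two alternative quartet topologies.
#'
#' @param object A `quartet_support` tibble from [quartet_frequencies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quartet_support <- function(object, ...) {
  df <- object %>%
    filter(!is.na(.data$f_main)) %>%
    mutate(branch = factor(.data$branch, levels = .data$branch)) %>%
    tidyr::pivot_longer(c("f_main", "f_alt1", "f_alt2"),
                        names_to = "topology", values_to = "frequency") %>%
    mutate(topology = factor(.data$topology,
                             levels = c("f_main", "f_alt1", "f_alt2"),
                             labels = c("main", "alt 1", "alt 2")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$frequency,
                                   fill = .data$topology)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("#2a9d4e", "#e9c46a", "#e76f51")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "quartet frequency")
}

#' Scatter with fitted trend line for a recovery trend
#'
#' @param object A `recovery_trend` from [fit_recovery_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_trend <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("y", "x")
  r2 <- round(summary(object$fit)$r.squared, 3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = paste0("R² = ", r2))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
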