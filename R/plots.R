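# ggplot2 visualisations for the main result types.

#' Scree plot of a network model
#'
#' Explained variation per latent network, in component order.
#'
#' @param object A [fit_networks()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$network,
                                 y = .data$explained_variation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "network (component)",
                  y = "explained variation",
                  title = "Stress-stage network scree") +
    ggplot2::theme_minimal()
}

#' Loading profile of one network
#'
#' Signed region loadings of a single network, the bar-graph view of which
#' regions drive it and in which direction.
#'
#' @param model A [fit_networks()] model.
#' @param network Component index.
#' @param top_n Show only the `top_n` regions by absolute loading
#'   (default 25).
#' @return A ggplot.
#' @export
plot_network_loadings <- function(model, network = 1, top_n = 25) {
  l <- model$loadings[, network]
  d <- tibble(region = names(l), loading = unname(l)) |>
    arrange(dplyr::desc(abs(.data$loading))) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$region, .data$loading),
    y = .data$loading)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "component loading",
                  title = sprintf("Network %d region loadings", network)) +
    ggplot2::theme_minimal()
}

#' Significance map of the network prediction analysis
#'
#' `-log10` family-wise corrected p-values per network, faceted by neural
#' process and HAQUAMS scale, with the family threshold drawn as a line.
#'
#' @param object A [predict_hrql_from_networks()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrql_prediction <- function(object, ...) {
  d <- mutate(object,
              network_index = as.integer(sub("net_", "", .data$network)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$network_index,
                                  y = -log10(.data$p_fwe),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(.data$alpha_fwe)),
                        linetype = 2) +
    ggplot2::facet_grid(scale ~ process) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "network", y = expression(-log[10](p[FWE]))) +
    ggplot2::theme_minimal()
}

#' Psychophysiological stage profiles
#'
#' Mean and standard deviation of perceived-stress ratings and pulse per
#' experimental stage.
#'
#' @param psychophys Long table from [generate_psychophys()].
#' @return A ggplot.
#' @export
plot_psychophys <- function(psychophys) {
  d <- psychophys |>
    group_by(.data$parameter, .data$stage) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = "experimental stage", y = NULL) +
    ggplot2::theme_minimal()
}
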