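# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selected panel into one row per design
#'
#' @param x an `episcope_panel`
#' @param ... unused
#' @return tibble with design id, mutation label, size, spread, stability,
#'   disruptiveness and covered-model count
#' @export
tidy.episcope_panel <- function(x, ...) {
  d <- x$designs
  tibble::tibble(
    design_id = d$design_id, mutations = d$label,
    n_mutations = d$n_mutations, spread = d$spread,
    stability_delta = d$stability_delta,
    total_disruption = d$total_disruption, n_covered = d$n_covered
  )
}

#' One-row summary of a selected panel
#'
#' @param x an `episcope_panel`
#' @param ... unused
#' @return tibble with panel size, K, model counts and the objective
#' @export
glance.episcope_panel <- function(x, ...) {
  tibble::tibble(
    n_designs = nrow(x$designs), K = x$K,
    n_models = nrow(x$coverage),
    n_covered = sum(lengths(x$coverage$design_ids) > 0),
    n_uncoverable = length(x$uncovered),
    objective = x$objective, method = x$method
  )
}

#' @export
tidy.episcope_run <- function(x, ...) tidy(x$panel, ...)

#' @export
glance.episcope_run <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$panel),
    tibble::tibble(n_candidate_designs = nrow(x$designs),
                   n_surface = length(x$surface))
  )
}

#' Tidy the retrospective summary
#'
#' @param x a `retro_summary`
#' @param ... unused
#' @return the long success-rate/correlation table
#' @export
tidy.retro_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$success_rates, statistic = "success_rate",
                  value = .data$rate)[, c("statistic", "epitope_definition",
                                          "structure_source", "value")],
    dplyr::mutate(x$correlations[, c("statistic", "structure_source",
                                     "value")],
                  epitope_definition = NA_character_)
  )
}

#' Coverage heat map of a selected panel
#'
#' Tiles are docking models (x) by panel designs (y); filled tiles mark
#' models predicted to be disrupted by the design.
#'
#' @param object an `episcope_panel`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.episcope_panel <- function(object, ...) {
  d <- object$designs
  grid <- tidyr::expand_grid(design_id = d$design_id,
                             model_id = object$coverage$model_id)
  cov <- dplyr::bind_rows(lapply(seq_len(nrow(d)), function(i) {
    tibble::tibble(design_id = d$design_id[i],
                   model_id = d$covered_models[[i]])
  }))
  grid$covered <- paste(grid$design_id, grid$model_id) %in%
    paste(cov$design_id, cov$model_id)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$model_id, y = .data$design_id,
                                     fill = .data$covered)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey95"),
                               name = "disrupted") +
    ggplot2::labs(x = "docking model", y = "design") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heat map of a pairwise antibody matrix
#'
#' Works for both the dock-overlap matrix ([dock_overlap_matrix()]) and the
#' average design-distance matrix ([design_distance_matrix()]).
#'
#' @param M square numeric matrix with dimnames
#' @param value_name legend title
#' @return a ggplot object
#' @export
plot_ab_matrix <- function(M, value_name = "value") {
  df <- tibble::as_tibble(as.table(M), .name_repair = ~c("row", "col", "value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
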