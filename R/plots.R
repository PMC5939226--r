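# ggplot2 displays for the task space, choice maps and fits.

#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_point facet_wrap
#'   scale_fill_viridis_c labs theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Heatmaps of the five task-space variables
#'
#' @param grid a [task_space()] tibble.
#' @return a ggplot: 6 x 6 tiles faceted by variable.
#' @export
plot_task_space <- function(grid) {
  long <- grid %>%
    tidyr::pivot_longer(
      all_of(c("p_act_bomb", "entropy", "ev")),
      names_to = "variable", values_to = "value"
    )
  ggplot(long, aes(.data$n_tokens, .data$env_threat_level,
                   fill = .data$value)) +
    geom_tile() +
    facet_wrap(~variable, scales = "free") +
    scale_fill_viridis_c() +
    labs(
      x = "activated tokens (n)", y = "environmental threat level",
      title = paste("Task space,", grid$condition[1])
    ) +
    theme_minimal()
}

#' Heatmap of stage-1 choice frequencies across the task space
#'
#' The simulated analogue of the observed accept/reject/explore maps: one
#' 6 x 6 panel per action.
#'
#' @param map output of [choice_probability_map()].
#' @return a ggplot.
#' @export
plot_choice_map <- function(map) {
  ggplot(map, aes(.data$n_tokens, .data$env_threat_level,
                  fill = .data$freq)) +
    geom_tile() +
    facet_wrap(~choice) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(
      x = "activated tokens (n)", y = "environmental threat level",
      fill = "frequency"
    ) +
    theme_minimal()
}

#' EM trace of a group fit
#'
#' Total Laplace log evidence across EM iterations; should be
#' non-decreasing up to the convergence tolerance.
#'
#' @param object an `aac_group_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aac_group_fit <- function(object, ...) {
  ggplot(object$trace, aes(.data$iteration, .data$total_evidence)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "EM iteration", y = "total Laplace log evidence",
      title = paste(object$spec$condition, object$spec$label)
    ) +
    theme_minimal()
}

#' Generating vs. recovered subject parameters
#'
#' One panel per free parameter, unconstrained scale, with the identity
#' line.
#'
#' @param object an `aac_recovery`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aac_recovery <- function(object, ...) {
  free <- object$config$spec$free_all
  truth <- object$truth %>%
    select("subject_id", "param", truth = "unconstrained")
  est <- tidy(object$fit, "subjects") %>%
    dplyr::rename(recovered = "estimate") %>%
    mutate(recovered = ifelse(
      param_transform(.data$param) == "log", log(.data$recovered),
      .data$recovered
    ))
  both <- dplyr::inner_join(truth, est, by = c("subject_id", "param"))
  ggplot(both, aes(.data$truth, .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    geom_point() +
    facet_wrap(~param, scales = "free") +
    labs(x = "generating value (unconstrained)",
         y = "recovered MAP (unconstrained)") +
    theme_minimal()
}
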