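# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hierarchical group fit
#'
#' @param x an `aac_group_fit`.
#' @param effects `"group"` (default) for one row per free parameter with
#'   the group mean/sd on both scales, or `"subjects"` for per-subject MAP
#'   estimates in long form.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.aac_group_fit <- function(x, effects = c("group", "subjects"), ...) {
  effects <- match.arg(effects)
  if (effects == "group") {
    x$group %>%
      mutate(
        estimate = ifelse(.data$transform == "log", exp(.data$mean), .data$mean)
      ) %>%
      select("param", "transform", "mean", "sd", "estimate")
  } else {
    x$subjects %>%
      tidyr::pivot_longer(all_of(x$spec$free_all),
                          names_to = "param", values_to = "estimate") %>%
      select("subject_id", "param", "estimate", "nll", "log_evidence")
  }
}

#' One-row summary of a hierarchical group fit
#'
#' @param x an `aac_group_fit`.
#' @param ... unused.
#' @return a one-row tibble: label, condition, sizes, total log evidence,
#'   iBIC, pseudo-r2, EM iterations, convergence flag.
#' @export
glance.aac_group_fit <- function(x, ...) {
  tibble(
    label = x$spec$label,
    condition = x$spec$condition,
    n_subjects = x$n_subjects,
    n_choices = x$n_choices,
    n_free_params = length(x$spec$free_all),
    total_log_evidence = x$total_log_evidence,
    ibic = x$ibic,
    pseudo_r2 = x$pseudo_r2,
    em_iterations = nrow(x$trace),
    converged = x$converged
  )
}

#' Tidy a recovery experiment
#'
#' @param x an `aac_recovery`.
#' @param ... unused.
#' @return per-parameter recovery correlations joined with the generating
#'   and recovered group hyperparameters.
#' @export
tidy.aac_recovery <- function(x, ...) {
  dplyr::left_join(x$correlations, x$hyper, by = "param")
}

#' One-row summary of a recovery experiment
#' @param x an `aac_recovery`.
#' @param ... unused.
#' @return a one-row tibble with cohort size and the min/median recovery r.
#' @export
glance.aac_recovery <- function(x, ...) {
  tibble(
    label = x$config$spec$label,
    condition = x$config$spec$condition,
    n_subjects = x$config$n_subjects,
    n_trials_per_subject = x$fit$n_choices / x$config$n_subjects,
    min_r = min(x$correlations$r),
    median_r = stats::median(x$correlations$r),
    ibic = x$fit$ibic
  )
}
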