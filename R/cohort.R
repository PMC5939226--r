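# Synthetic cohorts: subjects whose parameters are drawn from group-level
# Gaussians (on the unconstrained scale), simulated through the task, plus
# the parameter-recovery and model-identification experiments that validate
# the whole pipeline.

#' Winning-model specification
#'
#' The model structure that best accounted for behaviour in each condition:
#' loss perception `f`, threat distortion `j` and exploration bonus `w` in
#' the conflict (Ap/Av) condition; threat distortion `j`, stage-2 bias `i`
#' and exploration bonus `w` in the no-loss (Ap/Ap) condition; softmax
#' temperature free in both.
#'
#' @param condition `"APAV"` or `"APAP"`.
#' @return an [model_spec()].
#' @export
winning_spec <- function(condition = "APAV") {
  condition <- match_condition(condition)
  if (condition == "APAV") {
    model_spec("APAV", c("f", "j", "w"))
  } else {
    model_spec("APAP", c("j", "i", "w"))
  }
}

# Default generating hyperparameters (unconstrained scale) for a spec:
# f ~ N(-10, 2) tokens (slight undervaluation of the -12 loss),
# log j ~ N(0, 0.3) (distortion centred on veridical),
# w ~ N(2, 0.75) tokens/bit (positive exploration bonus),
# i ~ N(2, 1) tokens, e ~ N(1, 0.5) tokens, log m ~ N(0, 0.3),
# log beta ~ N(log 2, 0.4).
default_group_mean <- function(free_all) {
  full <- c(f = -10, j = 0, m = 0, w = 2, e = 1, i = 2, beta = log(2))
  full[free_all]
}

default_group_sd <- function(free_all) {
  full <- c(f = 2, j = 0.3, m = 0.3, w = 0.75, e = 0.5, i = 1, beta = 0.4)
  full[free_all]
}

#' Configure a synthetic cohort
#'
#' @param spec generating [model_spec()] (default: the Ap/Av winning model).
#' @param n_subjects cohort size (default 20).
#' @param n_reps gamble repetitions per condition per subject (default 18,
#'   i.e. 648 modelled trials per condition).
#' @param group_mean,group_sd named vectors over `spec$free_all` on the
#'   unconstrained scale; defaults echo the fitted-group descriptions (see
#'   the vignette).
#' @param seed master seed; every derived stream is a function of it.
#' @return a list of class `aac_cohort_config`.
#' @export
cohort_config <- function(spec = winning_spec("APAV"), n_subjects = 20,
                          n_reps = 18,
                          group_mean = default_group_mean(spec$free_all),
                          group_sd = default_group_sd(spec$free_all),
                          seed = 1L) {
  stopifnot(inherits(spec, "aac_model_spec"))
  group_mean <- group_mean[spec$free_all]
  group_sd <- group_sd[spec$free_all]
  if (anyNA(group_mean) || anyNA(group_sd) || any(group_sd < 0)) {
    abort("group_mean/group_sd must cover every free parameter, sd >= 0.")
  }
  structure(
    list(spec = spec, n_subjects = as.integer(n_subjects),
         n_reps = as.integer(n_reps), group_mean = group_mean,
         group_sd = group_sd, seed = as.integer(seed)),
    class = "aac_cohort_config"
  )
}

#' Draw one subject's parameters from the group distribution
#'
#' Unconstrained parameters are drawn from the group Gaussians and mapped
#' through the transforms; disabled parameters take their defaults.
#' Deterministic per `(config$seed, subject_index)`.
#'
#' @param config an [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return an [subject_params()] object.
#' @export
sample_subject_params <- function(config, subject_index) {
  stopifnot(inherits(config, "aac_cohort_config"))
  free <- config$spec$free_all
  theta <- withr::with_seed(
    combine_seed(config$seed, 1L, subject_index),
    rnorm(length(free), config$group_mean, config$group_sd)
  )
  params_from_theta(config$spec, setNames(theta, free))
}

#' Simulate a subject through a session
#'
#' Stage-1 choices are sampled from the softmax over the subject's action
#' values; exploration reveals are sampled (an activated bomb is seen with
#' probability 1/2); stage-2 choices follow the deterministic stage-2 policy
#' (reject/"bomb" after seeing a bomb, otherwise the stage-2 argmax); payoffs
#' are settled per the task rules.
#'
#' @param session trials from [generate_session()], or a one-condition
#'   subset.
#' @param params a single [subject_params()] (applied to its condition's
#'   trials) or a named list of them, e.g.
#'   `list(APAV = ..., APAP = ...)`, covering every condition present.
#' @param seed integer seed for choice and reveal sampling.
#' @return the session with choices, reveals and payoffs filled.
#' @export
simulate_subject <- function(session, params, seed = 1L) {
  if (inherits(params, "aac_params")) {
    params <- setNames(list(params), params$condition)
  }
  missing_cond <- setdiff(unique(session$condition), names(params))
  if (length(missing_cond) > 0) {
    abort(paste0("no parameters supplied for condition ",
                 paste(missing_cond, collapse = ", "), "."))
  }
  out <- session
  for (cond in names(params)) {
    pc <- params[[cond]]
    stopifnot(inherits(pc, "aac_params"), pc$condition == cond)
    rows <- which(session$condition == cond)
    if (length(rows) == 0) next
    sub <- session[rows, ]
    vals <- action_values(sub$env_threat, sub$n_tokens, pc)
    pr <- choice_probs(vals, pc$values[["beta"]])
    cseed <- combine_seed(seed, match(cond, CONDITIONS))
    stage1 <- withr::with_seed(cseed, {
      un <- runif(nrow(pr))
      cum <- t(apply(pr, 1, cumsum))
      idx <- 1L + rowSums(un > cum)
      CHOICES[pmin(idx, 3L)]
    })
    explored <- stage1 == "EXPLORE"
    reveal <- rep(NA, length(rows))
    reveal[explored] <- withr::with_seed(combine_seed(cseed, 7L), {
      sub$bomb_activated[explored] & runif(sum(explored)) < 0.5
    })
    stage2 <- rep(NA_character_, length(rows))
    stage2[explored] <- stage2_policy(vals[explored, ], reveal[explored])
    out$stage1_choice[rows] <- stage1
    out$reveal_saw_bomb[rows] <- reveal
    out$stage2_choice[rows] <- stage2
    out$payoff_pence[rows] <- payoff_pence_vec(
      sub$condition, sub$n_tokens, sub$bomb_activated, stage1, reveal, stage2
    )
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws each subject's parameters from the group distribution, generates a
#' seeded session, and simulates choices for the generating spec's
#' condition.
#'
#' @param config an [cohort_config()].
#' @return a list with `trials` (all subjects' completed trials for the
#'   spec's condition), `params` (tibble of true parameters per subject, on
#'   both scales), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "aac_cohort_config"))
  cond <- config$spec$condition
  sims <- purrr::map(seq_len(config$n_subjects), function(s) {
    pars <- sample_subject_params(config, s)
    sess <- generate_session(
      n_reps = config$n_reps, seed = combine_seed(config$seed, 2L, s),
      subject_id = sprintf("s%02d", s)
    )
    sess <- sess[sess$condition == cond, ]
    done <- simulate_subject(sess, pars,
                             seed = combine_seed(config$seed, 3L, s))
    list(trials = done, params = pars)
  })
  true_params <- purrr::map_dfr(seq_along(sims), function(s) {
    v <- sims[[s]]$params$values
    free <- config$spec$free_all
    tibble(
      subject_id = sprintf("s%02d", s),
      param = free,
      value = unname(v[free]),
      unconstrained = unname(to_unconstrained(v[free]))
    )
  })
  list(
    trials = purrr::map_dfr(sims, "trials"),
    params = true_params,
    config = config
  )
}

#' Empirical stage-1 choice frequencies per task-space cell
#'
#' @param trials completed trials of one condition.
#' @return a tibble with one row per observed cell and choice:
#'   `env_threat_level`, `n_tokens`, `choice`, `n`, `freq`. Cells with no
#'   trials are absent (missing), never reported as zero.
#' @export
choice_probability_map <- function(trials) {
  if (length(unique(trials$condition)) > 1) {
    abort("supply trials from a single condition.")
  }
  if (anyNA(trials$stage1_choice)) abort("stage-1 choices missing.")
  counts <- trials %>%
    count(.data$env_threat_level, .data$n_tokens, .data$stage1_choice)
  cells <- dplyr::distinct(counts, .data$env_threat_level, .data$n_tokens)
  tidyr::expand_grid(cells, stage1_choice = CHOICES) %>%
    left_join(counts, by = c("env_threat_level", "n_tokens", "stage1_choice")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    group_by(.data$env_threat_level, .data$n_tokens) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    dplyr::rename(choice = "stage1_choice") %>%
    arrange(.data$env_threat_level, .data$n_tokens, .data$choice)
}

#' Per-cell entropy of the empirical choice distribution, in bits
#'
#' Shannon entropy of the three-way stage-1 choice frequencies in each
#' task-space cell — an index of behavioural (subjective) uncertainty.
#'
#' @inheritParams choice_probability_map
#' @return tibble `env_threat_level`, `n_tokens`, `n`, `entropy_bits`.
#' @export
choice_entropy_map <- function(trials) {
  choice_probability_map(trials) %>%
    group_by(.data$env_threat_level, .data$n_tokens) %>%
    summarise(
      n = sum(.data$n),
      entropy_bits = {
        f <- .data$freq[.data$freq > 0]
        -sum(f * log2(f))
      },
      .groups = "drop"
    )
}

#' Parameter-recovery experiment
#'
#' Simulates a cohort from known group distributions, fits it with
#' [em_fit_group()] under the generating spec, and reports
#' generating-vs-recovered correlations per parameter (on the unconstrained
#' scale) together with group-hyperparameter errors. Fully seeded.
#'
#' @param config an [cohort_config()].
#' @param ... further arguments passed to [em_fit_group()].
#' @return a list of class `aac_recovery`: `correlations` (tibble `param`,
#'   `r`), `hyper` (generating vs. recovered group means/sds), `fit`,
#'   `truth`, `config`.
#' @export
recovery_experiment <- function(config, ...) {
  stopifnot(inherits(config, "aac_cohort_config"))
  cohort <- simulate_cohort(config)
  fit <- em_fit_group(cohort$trials, config$spec,
                      seed = combine_seed(config$seed, 4L), ...)
  free <- config$spec$free_all
  truth_wide <- cohort$params %>%
    select("subject_id", "param", "unconstrained") %>%
    tidyr::pivot_wider(names_from = "param", values_from = "unconstrained") %>%
    arrange(.data$subject_id)
  est <- fit$theta[truth_wide$subject_id, , drop = FALSE]
  correlations <- tibble(
    param = free,
    r = purrr::map_dbl(free, function(p) {
      suppressWarnings(cor(truth_wide[[p]], est[, p]))
    })
  )
  hyper <- tibble(
    param = free,
    true_mean = unname(config$group_mean),
    fit_mean = fit$group$mean,
    true_sd = unname(config$group_sd),
    fit_sd = fit$group$sd
  )
  structure(
    list(correlations = correlations, hyper = hyper, fit = fit,
         truth = cohort$params, config = config),
    class = "aac_recovery"
  )
}

#' @export
print.aac_recovery <- function(x, ...) {
  cat("<aac_recovery>", x$config$spec$condition, x$config$spec$label,
      sprintf("(%d subjects x %d trials)\n",
              x$config$n_subjects, x$fit$n_choices / x$config$n_subjects))
  print(dplyr::left_join(x$correlations, x$hyper, by = "param"))
  invisible(x)
}

#' Model-identification experiment
#'
#' Repeatedly simulates cohorts from a known generating spec, runs
#' [compare_models()] over a candidate set, and reports how often the
#' generating model wins by minimum iBIC.
#'
#' @param config generating [cohort_config()] (typically scaled down).
#' @param candidate_specs list of candidate [model_spec()] objects that
#'   includes the generating spec.
#' @param n_replicates number of seeded replicates (default 20).
#' @param ... further arguments to [em_fit_group()].
#' @return a list of class `aac_identification`: `replicates` (tibble
#'   `replicate`, `winner`, `correct`), `rate`, `config`.
#' @export
identification_experiment <- function(config, candidate_specs,
                                      n_replicates = 20, ...) {
  stopifnot(inherits(config, "aac_cohort_config"))
  true_label <- config$spec$label
  if (!true_label %in% purrr::map_chr(candidate_specs, "label")) {
    abort("the generating spec must be among the candidates.")
  }
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg_r <- config
    cfg_r$seed <- combine_seed(config$seed, 5L, r)
    cohort <- simulate_cohort(cfg_r)
    tab <- compare_models(cohort$trials, candidate_specs,
                          seed = combine_seed(cfg_r$seed, 6L), ...)
    tibble(
      replicate = r,
      winner = tab$label[tab$winner],
      correct = tab$label[tab$winner] == true_label
    )
  })
  structure(
    list(replicates = reps, rate = mean(reps$correct),
         true_label = true_label, config = config),
    class = "aac_identification"
  )
}

#' @export
print.aac_identification <- function(x, ...) {
  cat(sprintf(
    "<aac_identification> true model %s identified in %.0f%% of %d replicates\n",
    x$true_label, 100 * x$rate, nrow(x$replicates)
  ))
  invisible(x)
}
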