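# The subjective-value choice model. Stage-1 action values are built from a
# subjective activated-bomb probability `a` (a power-law distortion of
# environmental threat), the Bayes posterior `k` after a null exploration
# reveal (itself distorted by the exponent m), an entropy-scaled exploration
# bonus, and condition-specific payoff structure. A softmax over the three
# stage-1 values yields choice probabilities.

#' Subjective probability of an activated bomb
#'
#' `a = env_threat^j * n_tokens / 12`, clamped to \[0, 1\]. `j = 1` recovers
#' the objective [p_act_bomb()].
#'
#' @inheritParams p_act_bomb
#' @param j power-law distortion exponent of environmental threat (> 0).
#' @return subjective probability vector.
#' @export
subjective_p <- function(env_threat, n_tokens, j = 1) {
  if (any(j <= 0)) abort("`j` must be > 0.")
  pmin(pmax(env_threat^j * n_tokens / 12, 0), 1)
}

#' Posterior bomb probability after a null exploration reveal
#'
#' Exploration uncovers half of the token sites, so an activated bomb is seen
#' with probability 1/2. By Bayes rule, the probability that a bomb is
#' present given that none was seen is `k = (a/2) / (1 - a/2)`.
#'
#' @param a prior probability of an activated bomb, in \[0, 1\].
#' @return posterior probability vector.
#' @examples
#' posterior_no_see(0.5) # 1/3
#' @export
posterior_no_see <- function(a) {
  if (any(a < 0 | a > 1)) abort("`a` must lie in [0, 1].")
  (a / 2) / (1 - a / 2)
}

# bare computational kernel shared by action_values() and the likelihood hot
# path: v is the full named parameter vector on the natural scale.
value_core <- function(env_threat, n_tokens, condition, v) {
  a <- pmin(pmax(env_threat^v[["j"]] * n_tokens / 12, 0), 1)
  u <- binary_entropy(a)
  k <- (a / 2) / (1 - a / 2)
  km <- k^v[["m"]]
  if (condition == "APAV") {
    v_accept <- a * v[["f"]] + (1 - a) * n_tokens
    v_reject <- numeric(length(a))
    v_nosee_raw <- km * v[["f"]] + (1 - km) * n_tokens
    stage2_accept <- v_nosee_raw > 0
    v_explore <- (1 - a / 2) * pmax(v_nosee_raw, 0) - 2 + u * v[["w"]]
  } else {
    v_accept <- (1 - a) * n_tokens
    v_reject <- a * n_tokens
    s2_accept <- (1 - km) * n_tokens + v[["i"]]
    s2_reject <- km * n_tokens
    stage2_accept <- s2_accept > s2_reject
    v_explore <- (a / 2) * n_tokens +
      (1 - a / 2) * ifelse(stage2_accept, s2_accept, s2_reject) - 2 +
      v[["e"]] + u * v[["w"]]
  }
  list(a = a, u = u, k = k, v_accept = v_accept, v_reject = v_reject,
       v_explore = v_explore, stage2_accept = stage2_accept)
}

softmax3 <- function(v_accept, v_reject, v_explore, beta) {
  v <- beta * cbind(v_accept, v_reject, v_explore)
  v <- v - v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  ev <- exp(v)
  ev / rowSums(ev)
}

#' Subjective stage-1 action values
#'
#' Computes the three stage-1 action values per gamble under a subject's
#' parameters, in token units. Ap/Av: `V(Accept) = a f + (1 - a) n`,
#' `V(Reject) = 0`, and `V(Explore)` averages over seeing a bomb (value 0,
#' the gamble is then rejected) and not seeing one (value
#' `max(k^m f + (1 - k^m) n, 0)`), minus the 2-token fee, plus the entropy
#' bonus `u * w`. Ap/Ap: `V(NoBomb) = (1 - a) n`, `V(Bomb) = a n`, and
#' exploring pays `n` after a reveal, otherwise the better of the stage-2
#' guesses (`(1 - k^m) n + i` vs. `k^m n`), minus the fee, plus `e + u w`.
#'
#' @param env_threat,n_tokens gamble coordinates (vectorised).
#' @param params an [subject_params()] object; its `condition` selects the
#'   value recursion.
#' @return a tibble with columns `a` (subjective P(ActBomb)), `u` (its
#'   entropy, bits), `k` (null-reveal posterior), `v_accept`, `v_reject`,
#'   `v_explore`, and `stage2_accept` (the deterministic stage-2 policy after
#'   a null reveal).
#' @export
action_values <- function(env_threat, n_tokens, params) {
  stopifnot(inherits(params, "aac_params"))
  if (any(env_threat <= 0 | env_threat > 1)) {
    abort("`env_threat` must lie in (0, 1].")
  }
  as_tibble(value_core(env_threat, n_tokens, params$condition,
                       params$values))
}

#' Softmax choice probabilities over the three stage-1 actions
#'
#' `p_c` is proportional to `exp(beta * V_c)`, computed with max-subtraction
#' for overflow safety. `beta = 0` gives the uniform distribution.
#'
#' @param values a tibble from [action_values()] (or any data frame with
#'   columns `v_accept`, `v_reject`, `v_explore`).
#' @param beta softmax inverse temperature (>= 0).
#' @return a numeric matrix, one row per gamble, columns
#'   `ACCEPT_NOBOMB`, `REJECT_BOMB`, `EXPLORE`; rows sum to 1.
#' @export
choice_probs <- function(values, beta) {
  if (beta < 0) abort("`beta` must be >= 0.")
  pr <- softmax3(values$v_accept, values$v_reject, values$v_explore, beta)
  colnames(pr) <- CHOICES
  pr
}

# Deterministic stage-2 policy after exploring. Seeing an activated bomb
# always leads to "reject"/"bomb"; after a null reveal the stage-2 argmax
# from action_values() decides.
stage2_policy <- function(values, saw_bomb) {
  ifelse(saw_bomb, "REJECT_BOMB",
    ifelse(values$stage2_accept, "ACCEPT_NOBOMB", "REJECT_BOMB")
  )
}

# Tally stage-1 choices per unique gamble cell; returns the per-cell design
# (env_threat, n_tokens) and a cells x 3 count matrix. The likelihood only
# depends on these tallies, which makes repeated evaluation cheap.
choice_count_matrix <- function(trials) {
  key <- paste(trials$env_threat_level, trials$n_tokens)
  cells <- !duplicated(key)
  idx <- match(key, key[cells])
  counts <- matrix(0L, nrow = sum(cells), ncol = 3L,
                   dimnames = list(NULL, CHOICES))
  ch <- match(trials$stage1_choice, CHOICES)
  for (c3 in 1:3) {
    tab <- tabulate(idx[ch == c3], nbins = sum(cells))
    counts[, c3] <- tab
  }
  list(
    env_threat = trials$env_threat[cells],
    n_tokens = trials$n_tokens[cells],
    counts = counts
  )
}

nll_from_design <- function(design, params) {
  nll_from_design_v(design, params$condition, params$values)
}

nll_from_design_v <- function(design, condition, v) {
  vc <- value_core(design$env_threat, design$n_tokens, condition, v)
  pr <- softmax3(vc$v_accept, vc$v_reject, vc$v_explore, v[["beta"]])
  -sum(design$counts * log(pmax(pr, 1e-300)))
}

#' Negative log likelihood of observed stage-1 choices
#'
#' Sum over trials of `-log p(observed stage-1 choice)` under the softmax
#' subjective-value model. Trials are assumed independent; stage-2 choices
#' follow the deterministic stage-2 policy and do not enter the likelihood.
#'
#' @param trials a trial tibble with `stage1_choice` set, all from
#'   `params$condition`.
#' @param params an [subject_params()] object.
#' @return a single non-negative number.
#' @export
negative_log_likelihood <- function(trials, params) {
  stopifnot(inherits(params, "aac_params"))
  if (nrow(trials) == 0) abort("empty trial set.")
  if (!all(trials$condition == params$condition)) {
    abort("all trials must come from the parameter set's condition.")
  }
  if (anyNA(trials$stage1_choice)) abort("stage-1 choices missing.")
  nll_from_design(choice_count_matrix(trials), params)
}

#' Trial-wise model latents
#'
#' Per-trial subjective quantities under fitted parameters: the subjective
#' probability `a` and its entropy `u`, the objective EV, the three action
#' values, the value of the chosen option, the best unchosen value, and their
#' difference — the regressors used to interrogate value signals trial by
#' trial. The `rejected` flag marks "reject"/"bomb" stage-1 choices for the
#' choice-by-value-difference split.
#'
#' @param trials trial tibble with `stage1_choice` set, all of one condition.
#' @param params an [subject_params()] object for that condition.
#' @return `trials` columns `subject_id`, `trial_index`, `condition`, gamble
#'   coordinates, plus `a`, `u`, `ev_true`, `v_accept`, `v_reject`,
#'   `v_explore`, `v_chosen`, `v_best_unchosen`, `value_difference`,
#'   `rejected`.
#' @export
trial_latents <- function(trials, params) {
  stopifnot(inherits(params, "aac_params"))
  if (!all(trials$condition == params$condition)) {
    abort("all trials must come from the parameter set's condition.")
  }
  if (anyNA(trials$stage1_choice)) abort("stage-1 choices missing.")
  vals <- action_values(trials$env_threat, trials$n_tokens, params)
  vmat <- cbind(vals$v_accept, vals$v_reject, vals$v_explore)
  ci <- match(trials$stage1_choice, CHOICES)
  v_chosen <- vmat[cbind(seq_len(nrow(vmat)), ci)]
  v_best_unchosen <- purrr::map_dbl(seq_len(nrow(vmat)), function(r) {
    max(vmat[r, -ci[r]])
  })
  tibble(
    subject_id = trials$subject_id,
    trial_index = trials$trial_index,
    condition = trials$condition,
    env_threat_level = trials$env_threat_level,
    n_tokens = trials$n_tokens,
    stage1_choice = trials$stage1_choice,
    a = vals$a,
    u = vals$u,
    ev_true = ev_true(trials$env_threat, trials$n_tokens,
                      params$condition[1]),
    v_accept = vals$v_accept,
    v_reject = vals$v_reject,
    v_explore = vals$v_explore,
    v_chosen = v_chosen,
    v_best_unchosen = v_best_unchosen,
    value_difference = v_chosen - v_best_unchosen,
    rejected = trials$stage1_choice == "REJECT_BOMB"
  )
}
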