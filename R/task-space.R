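# The objective task: a 6 x 6 factorial gamble space. Background colour cues
# the prior probability that a bomb was planted somewhere in a 12-site array
# (environmental threat, 1/6 .. 1); 1-6 pairs of activated tokens (n = 2 .. 12)
# set both the potential reward (10 p per token) and the chance that a planted
# bomb sits under an activated token.

#' Probability of an activated bomb
#'
#' A planted bomb occupies one of 12 sites uniformly at random, so it is
#' "activated" (i.e. dangerous) only if it falls under one of the `n_tokens`
#' activated tokens: `P(ActBomb) = env_threat * n_tokens / 12`.
#'
#' @param env_threat prior probability a bomb was planted, in (0, 1].
#' @param n_tokens number of activated tokens, an integer in 2..12.
#' @return numeric vector of activated-bomb probabilities.
#' @examples
#' p_act_bomb(1 / 2, 6) # 0.25
#' @export
p_act_bomb <- function(env_threat, n_tokens) {
  if (any(env_threat <= 0 | env_threat > 1)) {
    abort("`env_threat` must lie in (0, 1].")
  }
  if (any(n_tokens < 2 | n_tokens > 12)) {
    abort("`n_tokens` must lie in 2..12.")
  }
  env_threat * n_tokens / 12
}

#' Shannon entropy of a Bernoulli probability, in bits
#'
#' `-p log2 p - (1 - p) log2(1 - p)`, with `0 log 0` taken as 0.
#'
#' @param p probability vector in \[0, 1\].
#' @return entropy in bits.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  term <- function(q) ifelse(q <= 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Objective expected value of the non-explore gamble, in tokens
#'
#' Ap/Av: the value of accepting, `-12 * P + n * (1 - P)` (fixed loss of 12
#' tokens = 120 p). Ap/Ap: the value of the better guess,
#' `max(P * n, (1 - P) * n)` (a correct guess pays n tokens, an incorrect one
#' nothing).
#'
#' @inheritParams p_act_bomb
#' @param condition `"APAV"` or `"APAP"`.
#' @return expected value in token units (1 token = 10 p).
#' @export
ev_true <- function(env_threat, n_tokens, condition) {
  condition <- match_condition(condition)
  p <- p_act_bomb(env_threat, n_tokens)
  if (condition == "APAV") {
    -12 * p + n_tokens * (1 - p)
  } else {
    pmax(p * n_tokens, (1 - p) * n_tokens)
  }
}

#' Build the 6 x 6 task-space grid
#'
#' One row per gamble (36 rows), with the five psychological variables that
#' characterise the task space: environmental threat, token count,
#' `P(ActBomb)`, its binary entropy, and the objective expected value for the
#' requested condition. All columns except `ev` are identical across
#' conditions.
#'
#' @param condition `"APAV"` or `"APAP"`.
#' @return a tibble with columns `condition`, `env_threat_level` (1-6),
#'   `env_threat`, `n_tokens`, `p_act_bomb`, `entropy`, `ev`.
#' @examples
#' task_space("APAV")
#' @export
task_space <- function(condition = "APAV") {
  cond <- match_condition(condition)
  grid <- tidyr::expand_grid(
    env_threat_level = 1:6,
    n_tokens = TOKEN_LEVELS
  )
  grid %>%
    mutate(
      condition = cond,
      env_threat = .data$env_threat_level / 6,
      p_act_bomb = p_act_bomb(.data$env_threat, .data$n_tokens),
      entropy = binary_entropy(.data$p_act_bomb),
      ev = ev_true(.data$env_threat, .data$n_tokens, cond)
    ) %>%
    select(
      "condition", "env_threat_level", "env_threat", "n_tokens",
      "p_act_bomb", "entropy", "ev"
    )
}

#' Pairwise correlations of the task-space variables
#'
#' Pearson correlations between the five grids (environmental threat, token
#' count, `P(ActBomb)`, entropy, EV) over the 36 gambles. With the Ap/Av EV
#' the strongest pairwise correlation is `P(ActBomb)` vs. EV, r = -0.86.
#'
#' @param grid a task-space tibble from [task_space()].
#' @return a tidy tibble of the 10 unordered variable pairs with column `r`.
#' @export
task_space_correlations <- function(grid) {
  vars <- c("env_threat", "n_tokens", "p_act_bomb", "entropy", "ev")
  cm <- stats::cor(as.matrix(grid[vars]))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    r = cm[pairs]
  ) %>%
    arrange(dplyr::desc(abs(.data$r)))
}
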