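# Session generation and outcome resolution. A session interleaves blocks of
# the two conditions; each trial's bomb state (planted? under which site?) is
# pre-sampled independently, so the activated-bomb rate of a gamble is exactly
# env_threat * n / 12. Choices are left unset until an agent (or a subject
# log) fills them in.

#' Generate a seeded task session
#'
#' Builds the full trial list for one session: each of the 36 gambles appears
#' exactly `n_reps` times per condition, trials are grouped into
#' `n_blocks` alternating condition blocks, and the latent bomb state is
#' pre-sampled per trial (planted with probability `env_threat`; if planted,
#' its site is uniform over the 12 locations and it is activated when the
#' site falls among the `n_tokens` activated tokens). Stage-1/stage-2 choices
#' and payoffs are `NA` until filled by [simulate_subject()] or
#' [resolve_outcome()].
#'
#' @param n_reps repetitions of each gamble per condition (default 18, giving
#'   the standard 1296-trial session).
#' @param n_blocks number of alternating condition blocks (even; default 12).
#'   Each condition's shuffled gamble sequence is split across its blocks in
#'   near-equal chunks.
#' @param start_condition condition of the first block.
#' @param seed integer seed; identical seeds give identical sessions.
#' @param subject_id identifier stamped on every trial.
#' @return a tibble with one row per trial: `subject_id`, `block`,
#'   `trial_index`, `condition`, `env_threat_level`, `env_threat`,
#'   `n_tokens`, `bomb_planted`, `bomb_activated`, `stage1_choice`,
#'   `reveal_saw_bomb`, `stage2_choice`, `payoff_pence`.
#' @examples
#' sess <- generate_session(n_reps = 18, seed = 1)
#' nrow(sess) # 1296
#' @export
generate_session <- function(n_reps = 18, n_blocks = 12,
                             start_condition = "APAV", seed = 1L,
                             subject_id = "s01") {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (n_blocks < 2 || n_blocks %% 2 != 0) abort("`n_blocks` must be even and >= 2.")
  start_condition <- match_condition(start_condition)
  bpc <- n_blocks / 2

  other <- setdiff(CONDITIONS, start_condition)
  block_cond <- rep(c(start_condition, other), length.out = n_blocks)
  cells <- tidyr::expand_grid(env_threat_level = 1:6, n_tokens = TOKEN_LEVELS)

  withr::with_seed(as.integer(seed), {
    per_cond <- purrr::map(CONDITIONS, function(cond) {
      seqn <- cells[rep(seq_len(nrow(cells)), n_reps), ]
      seqn <- seqn[sample.int(nrow(seqn)), ]
      # near-equal chunks, one per block of this condition
      chunk <- sort(rep_len(seq_len(bpc), nrow(seqn)))
      split(seqn, chunk)
    })
    names(per_cond) <- CONDITIONS
    used <- c(APAV = 0L, APAP = 0L)
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      cond <- block_cond[b]
      used[cond] <<- used[cond] + 1L
      block <- per_cond[[cond]][[used[cond]]]
      block$block <- b
      block$condition <- cond
      block
    })
    trials <- bind_rows(blocks) %>%
      mutate(
        subject_id = subject_id,
        trial_index = row_number(),
        env_threat = .data$env_threat_level / 6,
        bomb_planted = runif(dplyr::n()) < .data$env_threat,
        bomb_site = sample.int(12, dplyr::n(), replace = TRUE),
        bomb_activated = .data$bomb_planted & .data$bomb_site <= .data$n_tokens,
        stage1_choice = NA_character_,
        reveal_saw_bomb = NA,
        stage2_choice = NA_character_,
        payoff_pence = NA_integer_
      )
  })
  trials %>%
    select(
      "subject_id", "block", "trial_index", "condition",
      "env_threat_level", "env_threat", "n_tokens",
      "bomb_planted", "bomb_activated",
      "stage1_choice", "reveal_saw_bomb", "stage2_choice", "payoff_pence"
    )
}

# pure payoff arithmetic, vectorised; reveal already sampled for explores.
# Token pays 10 p; activated bomb costs 120 p in Ap/Av; explore fee 20 p.
payoff_pence_vec <- function(condition, n_tokens, bomb_activated,
                             stage1, reveal_saw_bomb, stage2) {
  explored <- stage1 == "EXPLORE"
  final <- ifelse(explored, stage2, stage1)
  apav <- condition == "APAV"
  base <- ifelse(
    apav,
    # accept: win unless an activated bomb; reject: nothing
    ifelse(final == "ACCEPT_NOBOMB",
      ifelse(bomb_activated, -120L, 10L * n_tokens), 0L
    ),
    # Ap/Ap: paid for a correct guess of the activated-bomb state
    ifelse((final == "REJECT_BOMB") == bomb_activated, 10L * n_tokens, 0L)
  )
  as.integer(base - ifelse(explored, 20L, 0L))
}

#' Resolve trial outcomes for given choices
#'
#' Fills `stage1_choice`, `reveal_saw_bomb`, `stage2_choice` and
#' `payoff_pence` for the supplied trials. Ap/Av: accepting pays 10 p per
#' token unless an activated bomb is present (fixed loss of 120 p); rejecting
#' pays nothing. Ap/Ap: a correct guess of the activated-bomb state pays 10 p
#' per token, an incorrect one nothing. Exploring always costs the 20 p fee
#' and reveals an activated bomb with probability 1/2 (half the token sites
#' are uncovered), after which the stage-2 choice is settled with the same
#' payoff rules.
#'
#' @param trials a trial tibble from [generate_session()] (or a subset).
#' @param stage1_choice character vector (recycled) of stage-1 actions among
#'   `"ACCEPT_NOBOMB"`, `"REJECT_BOMB"`, `"EXPLORE"`.
#' @param stage2_choice stage-2 actions for explored trials
#'   (`"ACCEPT_NOBOMB"` or `"REJECT_BOMB"`); must be non-`NA` exactly on
#'   explored trials.
#' @param seed integer seed for the exploration reveals.
#' @return `trials` with the choice, reveal and payoff columns filled.
#' @export
resolve_outcome <- function(trials, stage1_choice, stage2_choice = NULL,
                            seed = 1L) {
  n <- nrow(trials)
  stage1 <- rep_len(as.character(stage1_choice), n)
  if (!all(stage1 %in% CHOICES)) abort("unknown stage-1 choice label.")
  if (is.null(stage2_choice)) stage2_choice <- rep(NA_character_, n)
  stage2 <- rep_len(as.character(stage2_choice), n)
  explored <- stage1 == "EXPLORE"
  if (any(!is.na(stage2) & !explored)) {
    abort("stage-2 choice supplied for a trial that was not explored.")
  }
  if (any(explored & is.na(stage2))) {
    abort("explored trials require a stage-2 choice.")
  }
  if (any(explored & !stage2[explored] %in% CHOICES[1:2])) {
    abort("stage-2 choice must be ACCEPT_NOBOMB or REJECT_BOMB.")
  }
  reveal <- rep(NA, n)
  withr::with_seed(as.integer(seed), {
    reveal[explored] <- trials$bomb_activated[explored] &
      runif(sum(explored)) < 0.5
  })
  trials$stage1_choice <- stage1
  trials$reveal_saw_bomb <- reveal
  trials$stage2_choice <- stage2
  trials$payoff_pence <- payoff_pence_vec(
    trials$condition, trials$n_tokens, trials$bomb_activated,
    stage1, reveal, stage2
  )
  trials
}
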