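test_that("subjective probability distorts threat by a power law", {
  expect_equal(subjective_p(1, 12, 3), 1)
  expect_equal(subjective_p(1 / 2, 6, 1), 0.25)
  expect_equal(subjective_p(1 / 4, 12, 2), 1 / 16)
  expect_error(subjective_p(0.5, 6, 0), "j")
})

test_that("null-reveal posterior matches Bayes rule and a Monte-Carlo oracle", {
  expect_equal(posterior_no_see(0), 0)
  expect_equal(posterior_no_see(1), 1)
  expect_equal(posterior_no_see(0.5), 1 / 3)
  # simulate plant -> activate -> 50% reveal; condition on no reveal
  withr::with_seed(123, {
    for (a in c(0.1, 0.5, 0.9)) {
      act <- runif(1e6) < a
      seen <- act & runif(1e6) < 0.5
      k_hat <- mean(act[!seen])
      k <- posterior_no_see(a)
      se <- sqrt(k * (1 - k) / sum(!seen))
      expect_lt(abs(k_hat - k), 3 * se)
    }
  })
})

test_that("Ap/Av action values match the hand-derived closed forms", {
  v <- action_values(1 / 2, 6, subject_params("APAV"))
  expect_equal(v$v_accept, 1.5)
  expect_equal(v$v_explore, 1.0)
  expect_equal(v$v_reject, 0)
  expect_equal(v$k, 1 / 7)
  # the no-see continuation is floored at zero (gamble rejected)
  v2 <- action_values(1, 10, subject_params("APAV"))
  expect_equal(v2$a, 10 / 12)
  expect_gte(v2$v_explore, -2 - 1e-12) # fee is the worst case
  # reject is always worth exactly zero
  g <- task_space("APAV")
  vv <- action_values(g$env_threat, g$n_tokens, subject_params("APAV"))
  expect_true(all(vv$v_reject == 0))
  expect_true(all(vv$a >= 0 & vv$a <= 1))
  expect_true(all(vv$k <= vv$a / (1 - vv$a / 2) + 1e-12))
})

test_that("Ap/Ap action values match the hand-derived closed forms", {
  v <- action_values(1, 12, subject_params("APAP"))
  expect_equal(v$v_reject, 12) # "bomb" guess certain to pay
  expect_equal(v$v_accept, 0)
  v2 <- action_values(1 / 2, 12, subject_params("APAP"))
  expect_equal(v2$v_accept, v2$v_reject)
  v3 <- action_values(1 / 2, 6, subject_params("APAP"))
  expect_equal(v3$v_explore, 3.25)
})

test_that("defaults reproduce the objective agent's values", {
  g <- task_space("APAV")
  v <- action_values(g$env_threat, g$n_tokens, subject_params("APAV"))
  expect_equal(v$v_accept, g$ev)
  g2 <- task_space("APAP")
  v2 <- action_values(g2$env_threat, g2$n_tokens, subject_params("APAP"))
  expect_equal(pmax(v2$v_accept, v2$v_reject), g2$ev)
})

test_that("softmax choice probabilities behave as a proper simplex", {
  eq <- tibble::tibble(v_accept = 2, v_reject = 2, v_explore = 2)
  expect_equal(as.numeric(choice_probs(eq, 1)), rep(1 / 3, 3))
  any_v <- tibble::tibble(v_accept = 5, v_reject = -3, v_explore = 0.2)
  expect_equal(as.numeric(choice_probs(any_v, 0)), rep(1 / 3, 3))
  # frozen independent softmax evaluation for values (1.5, 0, 1.0), beta 1
  tri <- tibble::tibble(v_accept = 1.5, v_reject = 0, v_explore = 1.0)
  expect_equal(as.numeric(choice_probs(tri, 1)),
               c(0.5465493873, 0.1219516523, 0.3314989604),
               tolerance = 1e-9)
  # property: simplex and shift invariance over random value triples
  withr::with_seed(11, {
    for (rep in 1:25) {
      v <- tibble::tibble(v_accept = rnorm(4, 0, 5), v_reject = rnorm(4, 0, 5),
                          v_explore = rnorm(4, 0, 5))
      b <- runif(1, 0, 4)
      pr <- choice_probs(v, b)
      expect_equal(rowSums(pr), rep(1, 4))
      expect_true(all(pr >= 0))
      shifted <- dplyr::mutate(v, dplyr::across(dplyr::everything(), ~ .x + 7.3))
      expect_equal(choice_probs(shifted, b), pr, tolerance = 1e-12)
    }
  })
  # overflow safety at extreme temperatures
  expect_false(anyNA(choice_probs(tri, 1e4)))
})

test_that("likelihood sums -log p over observed stage-1 choices", {
  sim <- sim_small_apav(n_reps = 2, seed = 21)
  trials <- sim$trials[1:10, ]
  # beta = 0: uniform over three actions
  unif <- subject_params("APAV", beta = 0)
  expect_equal(negative_log_likelihood(trials, unif), 10 * log(3))
  # single trial with p(choice) = 1/2: the Ap/Ap P = 0.5 gamble at high beta
  # has v_bomb = v_nobomb = 3 and v_explore = 2.5, so accept/bomb split 50/50
  v <- action_values(1, 6, subject_params("APAP"))
  expect_equal(v$v_accept, v$v_reject)
  expect_lt(v$v_explore, v$v_accept)
  one <- trials[1, ]
  one$condition <- "APAP"
  one$env_threat_level <- 6L
  one$env_threat <- 1
  one$n_tokens <- 6L
  one$stage1_choice <- "ACCEPT_NOBOMB"
  nll1 <- negative_log_likelihood(one, subject_params("APAP", beta = 50))
  expect_equal(nll1, log(2), tolerance = 1e-4)
  expect_error(negative_log_likelihood(trials[0, ], unif), "empty")
})

test_that("the generating parameters beat perturbed ones on average", {
  deltas <- purrr::map_dbl(1:40, function(s) {
    sim <- sim_small_apav(beta = 2, f = -10, w = 2, n_reps = 1, seed = 500 + s)
    truth <- negative_log_likelihood(sim$trials, sim$params)
    pert <- subject_params("APAV", beta = 3.5, f = -16, w = 0.5)
    negative_log_likelihood(sim$trials, pert) - truth
  })
  expect_gt(mean(deltas), 0)
})

test_that("exploration bonus and loss aversion act monotonically", {
  g <- task_space("APAV")
  p0 <- choice_probs(action_values(g$env_threat, g$n_tokens,
                                   subject_params("APAV", beta = 1, w = 0)), 1)
  p1 <- choice_probs(action_values(g$env_threat, g$n_tokens,
                                   subject_params("APAV", beta = 1, w = 1)), 1)
  pos_u <- binary_entropy(g$p_act_bomb) > 0
  expect_true(all(p1[pos_u, "EXPLORE"] > p0[pos_u, "EXPLORE"]))
  # more negative f weakly decreases p(accept) everywhere
  pa0 <- choice_probs(action_values(g$env_threat, g$n_tokens,
                                    subject_params("APAV", beta = 1, f = -12)), 1)
  pa1 <- choice_probs(action_values(g$env_threat, g$n_tokens,
                                    subject_params("APAV", beta = 1, f = -30)), 1)
  expect_true(all(pa1[, "ACCEPT_NOBOMB"] <= pa0[, "ACCEPT_NOBOMB"] + 1e-12))
})

test_that("trial latents expose chosen, counterfactual and difference values", {
  sim <- sim_small_apav(n_reps = 2, seed = 31)
  lat <- trial_latents(sim$trials, sim$params)
  expect_equal(nrow(lat), nrow(sim$trials))
  # explore chosen with values (1.5, 0, 1.0): difference -0.5
  one <- sim$trials[1, ]
  one$env_threat_level <- 3L; one$env_threat <- 0.5; one$n_tokens <- 6L
  one$stage1_choice <- "EXPLORE"
  l1 <- trial_latents(one, subject_params("APAV"))
  expect_equal(l1$v_chosen, 1.0)
  expect_equal(l1$v_best_unchosen, 1.5)
  expect_equal(l1$value_difference, -0.5)
  # rejecting is always worth zero in Ap/Av
  rej <- lat[lat$stage1_choice == "REJECT_BOMB", ]
  expect_true(all(rej$v_chosen == 0))
  expect_true(all(rej$rejected))
  # an argmax agent would never have a negative difference
  best <- dplyr::mutate(lat,
    choice_by_max = c("ACCEPT_NOBOMB", "REJECT_BOMB", "EXPLORE")[
      max.col(cbind(v_accept, v_reject, v_explore))])
  agree <- best$stage1_choice == best$choice_by_max
  expect_true(all(lat$value_difference[agree] >= 0))
})
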