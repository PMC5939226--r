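# Hierarchical (type II maximum likelihood / empirical Bayes) fitting.
#
# Group-level distributions are independent Gaussians on the unconstrained
# parameter scale (log for j, m, beta; identity for f, w, e, i). The EM
# alternates per-subject MAP estimation under the current group prior
# (E-step) with moment updates of the group mean/variance that include the
# per-subject posterior variance from the inverse curvature (M-step).
# Per-subject marginal likelihoods are Laplace-approximated at the MAP, and
# models are compared with the integrated BIC.

subject_objective <- function(design, spec, prior_mean, prior_sd) {
  force(design); force(spec)
  base <- setNames(PARAM_INFO$default, PARAM_INFO$param)
  free <- spec$free_all
  lg <- param_transform(free) == "log"
  cond <- spec$condition
  function(theta) {
    v <- base
    v[free] <- ifelse(lg, exp(theta), theta)
    nll_from_design_v(design, cond, v) +
      0.5 * sum(((theta - prior_mean) / prior_sd)^2)
  }
}

#' Fit one subject's MAP parameter estimate
#'
#' Maximises `log p(choices | theta) + log p(theta | group prior)` on the
#' unconstrained scale by multi-start BFGS (prior mean, an optional warm
#' start, and `n_restarts` draws from the prior), and returns the arg-max
#' with the curvature (negative Hessian of the log posterior) at the
#' optimum. An indefinite curvature is ridge-regularised with a warning.
#'
#' @param trials one subject's trials (one condition, stage-1 choices set).
#' @param spec an [model_spec()].
#' @param prior_mean,prior_sd named numeric vectors over `spec$free_all`, on
#'   the unconstrained scale.
#' @param n_restarts random restarts drawn from the prior (default 5).
#' @param seed integer seed governing the restart draws.
#' @param start optional warm-start vector (unconstrained scale).
#' @return a list with `theta` (unconstrained MAP), `params`
#'   ([subject_params()] at the MAP), `nll` (data negative log likelihood at
#'   the MAP), `hessian` (curvature), `converged`, `n_trials`.
#' @export
fit_subject_map <- function(trials, spec, prior_mean, prior_sd,
                            n_restarts = 5, seed = 1L, start = NULL) {
  stopifnot(inherits(spec, "aac_model_spec"))
  if (nrow(trials) == 0) abort("cannot fit a subject with zero trials.")
  if (!all(trials$condition == spec$condition)) {
    abort("trials do not match the spec's condition.")
  }
  d <- length(spec$free_all)
  prior_mean <- prior_mean[spec$free_all]
  prior_sd <- prior_sd[spec$free_all]
  if (anyNA(prior_mean) || anyNA(prior_sd)) {
    abort("prior mean/sd must be named over all free parameters.")
  }
  design <- choice_count_matrix(trials)
  obj <- subject_objective(design, spec, prior_mean, prior_sd)

  starts <- list(prior_mean)
  if (!is.null(start)) starts <- c(starts, list(start[spec$free_all]))
  if (n_restarts > 0) {
    draws <- withr::with_seed(as.integer(seed), {
      purrr::map(seq_len(n_restarts), ~ rnorm(d, prior_mean, prior_sd))
    })
    starts <- c(starts, purrr::map(draws, setNames, spec$free_all))
  }

  runs <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, obj, method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) abort("all optimisation restarts failed.")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  theta <- setNames(best$par, spec$free_all)

  hess <- tryCatch(
    stats::optimHess(theta, obj),
    error = function(e) diag(1 / prior_sd^2, d)
  )
  hess <- (hess + t(hess)) / 2
  pd <- !inherits(try(chol(hess), silent = TRUE), "try-error")
  if (!pd) {
    # clamp the spectrum to a positive floor; the prior precision bounds how
    # flat the log posterior can truly be in any direction
    eig <- eigen(hess, symmetric = TRUE)
    floor_ev <- pmax(1e-6 * max(abs(eig$values), 1), 1 / max(prior_sd)^2 * 1e-3)
    vals <- pmax(eig$values, floor_ev)
    hess <- eig$vectors %*% diag(vals, d) %*% t(eig$vectors)
    hess <- (hess + t(hess)) / 2
    warn("indefinite curvature regularised by eigenvalue clamping.")
    if (inherits(try(chol(hess), silent = TRUE), "try-error")) {
      abort("curvature not positive definite after regularisation.")
    }
  }

  params <- params_from_theta(spec, theta)
  list(
    theta = theta,
    params = params,
    nll = nll_from_design(design, params),
    hessian = hess,
    converged = any(purrr::map_dbl(runs, "convergence") == 0),
    n_trials = nrow(trials)
  )
}

#' Laplace approximation to a subject's log marginal likelihood
#'
#' `log p(choices | group) ~ log p(choices | theta_MAP) +
#' log p(theta_MAP | group) + (d/2) log 2*pi - 1/2 log det(curvature)`.
#' With no free parameters the evidence is the likelihood itself.
#'
#' @param subject_fit result of [fit_subject_map()].
#' @param prior_mean,prior_sd the group prior used for the fit
#'   (unconstrained scale).
#' @return log marginal likelihood (a scalar).
#' @export
laplace_evidence <- function(subject_fit, prior_mean, prior_sd) {
  theta <- subject_fit$theta
  d <- length(theta)
  if (d == 0) return(-subject_fit$nll)
  prior_mean <- prior_mean[names(theta)]
  prior_sd <- prior_sd[names(theta)]
  logdet <- 2 * sum(log(diag(chol(subject_fit$hessian))))
  -subject_fit$nll +
    sum(dnorm(theta, prior_mean, prior_sd, log = TRUE)) +
    d / 2 * log(2 * pi) - 0.5 * logdet
}

#' Fit the hierarchical model to a cohort by EM
#'
#' Alternates per-subject MAP fits under the current group Gaussians
#' (E-step) with group mean/variance updates from the MAPs plus the
#' posterior-variance correction `diag(H^-1)` (M-step), until the largest
#' hyperparameter change falls below `tol`. Subjects are warm-started from
#' their previous MAP after the first iteration.
#'
#' @param trials cohort trial tibble (one condition, stage-1 choices set,
#'   `subject_id` distinguishing >= 2 subjects).
#' @param spec an [model_spec()].
#' @param max_iter,tol EM stopping rule (default 200 iterations, 1e-3).
#' @param tol_evidence secondary stopping rule: stop once the total Laplace
#'   log evidence has changed by less than this on three consecutive
#'   iterations (the hyperparameters can creep long after the fit has
#'   plateaued, especially under mis-specified models).
#' @param var_floor lower bound on group variances (default 1e-6).
#' @param n_restarts random restarts per subject in the first E-step.
#' @param seed integer seed for the restart draws.
#' @param init_sd group prior sd at initialisation (default 2).
#' @param verbose print the EM trace as it runs.
#' @return an object of class `aac_group_fit`: group hyperparameters,
#'   per-subject MAPs/curvatures/evidences, the EM trace, iBIC and
#'   pseudo-r2. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
em_fit_group <- function(trials, spec, max_iter = 200, tol = 1e-3,
                         tol_evidence = 0.01, var_floor = 1e-6,
                         n_restarts = 5, seed = 1L, init_sd = 2,
                         verbose = FALSE) {
  stopifnot(inherits(spec, "aac_model_spec"))
  if (!all(trials$condition == spec$condition)) {
    abort("trials do not match the spec's condition.")
  }
  if (anyNA(trials$stage1_choice)) abort("stage-1 choices missing.")
  ids <- sort(unique(trials$subject_id))
  if (length(ids) < 2) abort("the hierarchical fit needs >= 2 subjects.")
  by_subj <- purrr::map(ids, ~ trials[trials$subject_id == .x, ])
  d <- length(spec$free_all)

  # initial group prior: pinned-model defaults (beta = 1 -> log beta = 0)
  mu <- setNames(
    to_unconstrained(setNames(param_default(spec$free_all), spec$free_all)),
    spec$free_all
  )
  sd_g <- setNames(rep(init_sd, d), spec$free_all)

  fits <- vector("list", length(ids))
  trace <- list()
  prev_ev <- -Inf
  plateau <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fits <- purrr::map(seq_along(ids), function(s) {
      fit_subject_map(
        by_subj[[s]], spec, mu, sd_g,
        n_restarts = if (iter == 1) n_restarts else 0,
        seed = combine_seed(seed, s, iter),
        start = if (iter == 1) NULL else fits[[s]]$theta
      )
    })
    theta_mat <- do.call(rbind, purrr::map(fits, "theta"))
    post_var <- do.call(rbind, purrr::map(fits, function(f) {
      diag(solve(f$hessian))
    }))
    total_ev <- sum(purrr::map_dbl(fits, laplace_evidence, mu, sd_g))

    mu_new <- colMeans(theta_mat)
    var_new <- pmax(
      colMeans(theta_mat^2 + pmax(post_var, 0)) - mu_new^2,
      var_floor
    )
    sd_new <- sqrt(var_new)
    delta <- max(abs(c(mu_new - mu, sd_new - sd_g)))
    trace[[iter]] <- tibble(
      iteration = iter, total_evidence = total_ev, max_change = delta,
      evidence_decreased = total_ev < prev_ev - 1e-6
    )
    if (verbose) {
      message(sprintf("EM iter %3d  evidence %.3f  max change %.5f",
                      iter, total_ev, delta))
    }
    plateau <- if (abs(total_ev - prev_ev) < tol_evidence) plateau + 1L else 0L
    mu <- mu_new
    sd_g <- sd_new
    prev_ev <- total_ev
    if (delta < tol || plateau >= 3L) {
      converged <- TRUE
      break
    }
  }
  trace <- bind_rows(trace)
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations (last change %.4g).",
                 max_iter, trace$max_change[nrow(trace)]))
  }

  # final E-step quantities under the converged prior
  fits <- purrr::map(seq_along(ids), function(s) {
    fit_subject_map(by_subj[[s]], spec, mu, sd_g, n_restarts = 0,
                    seed = combine_seed(seed, s, 0L),
                    start = fits[[s]]$theta)
  })
  evidences <- purrr::map_dbl(fits, laplace_evidence, mu, sd_g)
  nlls <- purrr::map_dbl(fits, "nll")
  n_choices <- nrow(trials)
  total_ev <- sum(evidences)

  theta_mat <- do.call(rbind, purrr::map(fits, "theta"))
  rownames(theta_mat) <- ids
  subjects <- tibble(
    subject_id = ids,
    n_trials = purrr::map_int(fits, "n_trials"),
    nll = nlls,
    log_evidence = evidences,
    converged = purrr::map_lgl(fits, "converged")
  )
  natural <- as_tibble(do.call(rbind, lapply(seq_len(nrow(theta_mat)), function(r) {
    from_unconstrained(setNames(theta_mat[r, ], spec$free_all))
  })))
  subjects <- dplyr::bind_cols(subjects, natural)

  out <- structure(
    list(
      spec = spec,
      group = tibble(
        param = spec$free_all,
        transform = param_transform(spec$free_all),
        mean = unname(mu),
        sd = unname(sd_g)
      ),
      subjects = subjects,
      theta = theta_mat,
      hessians = purrr::map(fits, "hessian"),
      total_log_evidence = total_ev,
      n_choices = n_choices,
      n_subjects = length(ids),
      trace = trace,
      converged = converged,
      seed = as.integer(seed)
    ),
    class = "aac_group_fit"
  )
  out$ibic <- ibic(out)
  out$pseudo_r2 <- 1 - sum(nlls) / (n_choices * log(3))
  out
}

#' Integrated Bayesian information criterion
#'
#' `iBIC = -2 * total Laplace log evidence + n_hyper * log(n_total_choices)`,
#' with two hyperparameters (mean and sd) per free parameter. Smaller is
#' better; comparisons are only meaningful on the same data.
#'
#' @param group_fit an `aac_group_fit`.
#' @param n_total_choices number of modelled stage-1 choices (defaults to
#'   the count stored in the fit).
#' @return the iBIC value.
#' @export
ibic <- function(group_fit, n_total_choices = group_fit$n_choices) {
  n_hyper <- 2 * length(group_fit$spec$free_all)
  -2 * group_fit$total_log_evidence + n_hyper * log(n_total_choices)
}

#' McFadden pseudo-r-squared of a fitted cohort model
#'
#' `1 - sum(NLL_model) / sum(NLL_chance)` where chance is the uniform
#' three-choice model; 0 at chance, 1 for perfect prediction.
#'
#' @param group_fit an `aac_group_fit`.
#' @param trials optionally, trials to evaluate on (defaults to the fitted
#'   subjects' stored MAP likelihoods).
#' @return a number in \[0, 1\] for any model at least as good as chance.
#' @export
pseudo_r2 <- function(group_fit, trials = NULL) {
  if (is.null(trials)) return(group_fit$pseudo_r2)
  ids <- group_fit$subjects$subject_id
  nll <- sum(purrr::map_dbl(ids, function(id) {
    sub <- trials[trials$subject_id == id, ]
    theta <- group_fit$theta[id, ]
    negative_log_likelihood(
      sub, params_from_theta(group_fit$spec, setNames(theta, group_fit$spec$free_all))
    )
  }))
  1 - nll / (nrow(trials) * log(3))
}

#' Fit and compare candidate models on one cohort
#'
#' Fits every spec with [em_fit_group()] and tabulates iBIC, delta-iBIC
#' against the best model, and pseudo-r2. The winner is the minimum-iBIC
#' model; exact ties break towards fewer hyperparameters, then label order.
#'
#' @param trials cohort trial tibble (one condition).
#' @param specs list of [model_spec()] objects.
#' @param seed integer seed passed to each fit.
#' @param ... further arguments to [em_fit_group()].
#' @param keep_fits retain the full fit objects as an attribute.
#' @return a tibble (class `aac_model_comparison`) with one row per spec:
#'   `label`, `n_free`, `ibic`, `delta_ibic`, `pseudo_r2`, `winner`.
#' @export
compare_models <- function(trials, specs, seed = 1L, ..., keep_fits = FALSE) {
  if (inherits(specs, "aac_model_spec")) specs <- list(specs)
  if (length(specs) < 1) abort("need at least one model spec.")
  fits <- purrr::map(specs, function(sp) {
    em_fit_group(trials, sp, seed = seed, ...)
  })
  tab <- tibble(
    label = purrr::map_chr(specs, "label"),
    condition = purrr::map_chr(specs, "condition"),
    n_free = purrr::map_int(specs, ~ length(.x$free_all)),
    ibic = purrr::map_dbl(fits, "ibic"),
    pseudo_r2 = purrr::map_dbl(fits, "pseudo_r2"),
    total_log_evidence = purrr::map_dbl(fits, "total_log_evidence")
  )
  names(fits) <- tab$label
  tab$delta_ibic <- tab$ibic - min(tab$ibic)
  ord <- order(tab$ibic, tab$n_free, tab$label)
  tab$winner <- FALSE
  tab$winner[ord[1]] <- TRUE
  tab <- tab[ord, ]
  if (keep_fits) attr(tab, "fits") <- fits
  class(tab) <- c("aac_model_comparison", class(tab))
  tab
}

#' @export
print.aac_group_fit <- function(x, ...) {
  cat("<aac_group_fit>", x$spec$condition, x$spec$label, "\n")
  cat(sprintf(
    "  %d subjects, %d choices | iBIC %.2f | pseudo-r2 %.3f | %s\n",
    x$n_subjects, x$n_choices, x$ibic, x$pseudo_r2,
    if (x$converged) sprintf("converged in %d EM iterations", nrow(x$trace))
    else "NOT converged"
  ))
  print(x$group)
  invisible(x)
}
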