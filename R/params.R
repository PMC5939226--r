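# Subject-level parameters of the subjective-value model, the fitting-scale
# transforms, and candidate model specifications (subsets of free parameters).
#
# Parameter semantics (token units throughout; 1 token = 10 p):
#   f    perceived magnitude of the fixed loss (objective -12); Ap/Av only
#   j    power-law distortion of environmental threat, > 0
#   m    power-law distortion of the post-exploration posterior k, > 0
#   w    exploration bonus per bit of entropy of the subjective P(ActBomb)
#   e    additive over-valuation of exploring; Ap/Ap only
#   i    additive bonus on the stage-2 "no bomb" value after a null reveal;
#        Ap/Ap only
#   beta softmax inverse temperature, >= 0; always free when fitting
#
# With f = -12, j = m = 1 and w = e = i = 0 the model collapses to the
# objective-value agent.

PARAM_INFO <- tibble::tribble(
  ~param, ~default, ~transform, ~apav,  ~apap,
  "f",    -12,      "identity", TRUE,   FALSE,
  "j",    1,        "log",      TRUE,   TRUE,
  "m",    1,        "log",      TRUE,   TRUE,
  "w",    0,        "identity", TRUE,   TRUE,
  "e",    0,        "identity", FALSE,  TRUE,
  "i",    0,        "identity", FALSE,  TRUE,
  "beta", 1,        "log",      TRUE,   TRUE
)

param_transform <- function(name) {
  PARAM_INFO$transform[match(name, PARAM_INFO$param)]
}

param_default <- function(name) {
  PARAM_INFO$default[match(name, PARAM_INFO$param)]
}

#' Parameters allowed to vary in a given condition
#' @param condition `"APAV"` or `"APAP"`.
#' @param include_beta include the softmax temperature in the result.
#' @return character vector of parameter names.
#' @export
valid_params <- function(condition, include_beta = FALSE) {
  condition <- match_condition(condition)
  ok <- if (condition == "APAV") PARAM_INFO$apav else PARAM_INFO$apap
  out <- PARAM_INFO$param[ok]
  if (!include_beta) out <- setdiff(out, "beta")
  out
}

#' Construct a subject parameter set
#'
#' Defaults reproduce the objective-value agent; see the package vignette for
#' the meaning of each parameter.
#'
#' @param condition `"APAV"` or `"APAP"`.
#' @param beta softmax inverse temperature (>= 0, token-value scale).
#' @param f,j,m,w,e,i value-model parameters (see Details in the vignette).
#' @return an object of class `aac_params`.
#' @examples
#' subject_params("APAV", beta = 3, f = -10, w = 1.5)
#' @export
subject_params <- function(condition, beta = 1, f = -12, j = 1, m = 1,
                           w = 0, e = 0, i = 0) {
  condition <- match_condition(condition)
  if (j <= 0 || m <= 0) abort("`j` and `m` must be > 0.")
  if (beta < 0) abort("`beta` must be >= 0.")
  structure(
    list(condition = condition,
         values = c(f = f, j = j, m = m, w = w, e = e, i = i, beta = beta)),
    class = "aac_params"
  )
}

#' @export
print.aac_params <- function(x, ...) {
  cat("<aac_params> condition:", x$condition, "\n")
  print(round(x$values, 4))
  invisible(x)
}

# natural scale -> unconstrained fitting scale (log for j, m, beta)
to_unconstrained <- function(values) {
  lg <- param_transform(names(values)) == "log"
  out <- values
  out[lg] <- log(values[lg])
  out
}

from_unconstrained <- function(theta) {
  lg <- param_transform(names(theta)) == "log"
  out <- theta
  out[lg] <- exp(theta[lg])
  setNames(out, names(theta))
}

#' Define a candidate model (a subset of free parameters)
#'
#' The softmax temperature is always free; the listed parameters are fitted
#' on top of it and all others are pinned at their objective defaults.
#'
#' @param condition `"APAV"` or `"APAP"`.
#' @param free_params character subset of `valid_params(condition)`.
#' @param label optional label; defaults to `"f+w+beta"`-style.
#' @return an object of class `aac_model_spec`.
#' @examples
#' model_spec("APAV", c("f", "j", "w"))
#' @export
model_spec <- function(condition, free_params = character(), label = NULL) {
  condition <- match_condition(condition)
  free_params <- setdiff(unique(as.character(free_params)), "beta")
  bad <- setdiff(free_params, valid_params(condition))
  if (length(bad) > 0) {
    abort(paste0(
      "parameter(s) ", paste(bad, collapse = ", "),
      " are not valid for condition ", condition, "."
    ))
  }
  # canonical parameter order
  free_params <- intersect(PARAM_INFO$param, free_params)
  free_all <- c(free_params, "beta")
  if (is.null(label)) label <- paste(free_all, collapse = "+")
  structure(
    list(condition = condition, free_params = free_params,
         free_all = free_all, label = label),
    class = "aac_model_spec"
  )
}

#' @export
print.aac_model_spec <- function(x, ...) {
  cat("<aac_model_spec>", x$condition, x$label,
      sprintf("(%d free parameters)\n", length(x$free_all)))
  invisible(x)
}

#' Enumerate the candidate model space
#'
#' All subsets of the candidate parameters, each with a free softmax
#' temperature, in a deterministic label order.
#'
#' @param condition `"APAV"` or `"APAP"`.
#' @param candidate_params parameters to toggle (default: all valid for the
#'   condition).
#' @return list of [model_spec()] objects, ordered by label.
#' @examples
#' length(enumerate_model_space("APAV", c("f", "j", "m", "w"))) # 16
#' @export
enumerate_model_space <- function(condition,
                                  candidate_params = valid_params(condition)) {
  condition <- match_condition(condition)
  bad <- setdiff(candidate_params, valid_params(condition))
  if (length(bad) > 0) {
    abort(paste0("invalid candidate parameter(s): ", paste(bad, collapse = ", ")))
  }
  k <- length(candidate_params)
  subsets <- purrr::map(seq_len(2^k) - 1, function(bits) {
    candidate_params[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
  })
  specs <- purrr::map(subsets, ~ model_spec(condition, .x))
  specs[order(purrr::map_chr(specs, "label"))]
}

# Build an aac_params from a spec and an unconstrained free-parameter vector
# (named, in spec$free_all order); pinned parameters take their defaults.
params_from_theta <- function(spec, theta) {
  vals <- setNames(PARAM_INFO$default, PARAM_INFO$param)
  vals[names(theta)] <- from_unconstrained(theta)
  do.call(subject_params, c(list(condition = spec$condition), as.list(vals)))
}
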