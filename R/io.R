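# Readers and writers. Tables are tab-separated text with a single header
# row, "NA" for missing optional fields, floats at 6 significant digits;
# reports are JSON. Every writer stamps a provenance header (package
# version, content hash, seed where applicable) so outputs are diffable and
# traceable.

TRIAL_LOG_COLS <- c(
  "subject_id", "block", "trial_index", "condition", "env_threat_level",
  "n_tokens", "bomb_planted", "bomb_activated", "stage1_choice",
  "reveal_saw_bomb", "stage2_choice", "payoff_pence"
)

fmt6 <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g", digits = 6))
}

provenance <- function(seed = NULL, content = NULL) {
  out <- list(package = "aactask",
              version = as.character(packageVersion("aactask")))
  if (!is.null(seed)) out$seed <- as.integer(seed)
  if (!is.null(content)) out$content_hash <- rlang::hash(content)
  out
}

#' Write a trial log to tab-separated text
#'
#' Columns, in order: `subject_id`, `block`, `trial_index`, `condition`,
#' `env_threat_level` (1-6), `n_tokens`, `bomb_planted` (0/1),
#' `bomb_activated` (0/1), `stage1_choice`, `reveal_saw_bomb` (0/1/NA),
#' `stage2_choice` (or NA), `payoff_pence`. A `#`-prefixed provenance line
#' precedes the header.
#'
#' @param trials trial tibble (e.g. from [simulate_subject()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  out <- trials %>%
    mutate(
      bomb_planted = as.integer(.data$bomb_planted),
      bomb_activated = as.integer(.data$bomb_activated),
      reveal_saw_bomb = as.integer(.data$reveal_saw_bomb)
    ) %>%
    select(all_of(TRIAL_LOG_COLS))
  prov <- provenance(content = out)
  header <- sprintf("# aactask %s trial_log hash=%s",
                    prov$version, prov$content_hash)
  writeLines(header, path)
  readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Schema violations — unknown condition or choice labels, impossible states
#' such as a reveal on a non-explored trial or a reveal of a bomb that was
#' not activated — are rejected with the offending line numbers.
#'
#' @param path a file written by [write_trial_log()] (or matching its
#'   schema).
#' @return a validated trial tibble (with `env_threat` reconstructed).
#' @export
read_trial_log <- function(path) {
  raw <- readr::read_tsv(
    path, na = "NA", comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      block = readr::col_integer(),
      trial_index = readr::col_integer(),
      condition = readr::col_character(),
      env_threat_level = readr::col_integer(),
      n_tokens = readr::col_integer(),
      bomb_planted = readr::col_integer(),
      bomb_activated = readr::col_integer(),
      stage1_choice = readr::col_character(),
      reveal_saw_bomb = readr::col_integer(),
      stage2_choice = readr::col_character(),
      payoff_pence = readr::col_integer()
    )
  )
  missing_cols <- setdiff(TRIAL_LOG_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("trial log missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  line <- seq_len(nrow(raw))
  fail <- function(rows, msg) {
    if (any(rows)) {
      abort(sprintf("%s (line %s)", msg,
                    paste(head(line[rows], 5), collapse = ", ")))
    }
  }
  fail(!raw$condition %in% CONDITIONS, "unknown condition label")
  fail(!is.na(raw$stage1_choice) & !raw$stage1_choice %in% CHOICES,
       "unknown stage-1 choice label")
  fail(!raw$env_threat_level %in% 1:6, "env_threat_level outside 1..6")
  fail(!raw$n_tokens %in% TOKEN_LEVELS, "n_tokens outside {2,4,...,12}")
  explored <- !is.na(raw$stage1_choice) & raw$stage1_choice == "EXPLORE"
  fail(!is.na(raw$reveal_saw_bomb) & !explored,
       "reveal recorded on a non-explored trial")
  fail(!is.na(raw$stage2_choice) & !explored,
       "stage-2 choice recorded on a non-explored trial")
  fail(explored & (is.na(raw$reveal_saw_bomb) | is.na(raw$stage2_choice)),
       "explored trial missing reveal or stage-2 choice")
  fail(!is.na(raw$reveal_saw_bomb) & raw$reveal_saw_bomb == 1L &
         raw$bomb_activated == 0L,
       "reveal of a bomb that was not activated")
  fail(raw$bomb_activated == 1L & raw$bomb_planted == 0L,
       "activated bomb that was never planted")
  raw %>%
    mutate(
      env_threat = .data$env_threat_level / 6,
      bomb_planted = .data$bomb_planted == 1L,
      bomb_activated = .data$bomb_activated == 1L,
      reveal_saw_bomb = ifelse(is.na(.data$reveal_saw_bomb), NA,
                               .data$reveal_saw_bomb == 1L)
    ) %>%
    select(all_of(c(TRIAL_LOG_COLS[1:5], "env_threat",
                    TRIAL_LOG_COLS[6:12])))
}

#' Serialize subject parameters to flat JSON
#'
#' Parameters are written by name on the natural scale with their transform
#' annotation, so a fitted set can be reloaded unambiguously.
#'
#' @param params an [subject_params()] object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "aac_params"))
  obj <- list(
    provenance = provenance(content = params$values),
    condition = params$condition,
    params = as.list(params$values),
    transforms = as.list(setNames(param_transform(names(params$values)),
                                  names(params$values)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(subject_params, c(list(condition = obj$condition), obj$params))
}

#' Write a group-fit report to JSON
#'
#' Contains the spec label, group hyperparameters, per-subject MAPs and
#' evidences, iBIC, pseudo-r2 and the EM trace.
#'
#' @param fit an `aac_group_fit`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "aac_group_fit"))
  obj <- list(
    provenance = provenance(seed = fit$seed, content = fit$group),
    condition = fit$spec$condition,
    label = fit$spec$label,
    free_params = fit$spec$free_all,
    group = fit$group,
    subjects = fit$subjects,
    total_log_evidence = fit$total_log_evidence,
    n_choices = fit$n_choices,
    ibic = fit$ibic,
    pseudo_r2 = fit$pseudo_r2,
    converged = fit$converged,
    em_trace = fit$trace
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write a trial-latent table to tab-separated text
#'
#' @param latents output of [trial_latents()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_latents <- function(latents, path) {
  out <- latents %>%
    mutate(across(dplyr::where(is.double), ~ as.numeric(fmt6(.x))))
  prov <- provenance(content = out)
  writeLines(sprintf("# aactask %s latents hash=%s",
                     prov$version, prov$content_hash), path)
  readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a session configuration from JSON
#'
#' Expected keys: `n_reps`, `n_blocks`, `start_condition`, `seed` (missing
#' keys take [generate_session()] defaults).
#'
#' @param path JSON file.
#' @return a named list suitable for `do.call(generate_session, ...)`.
#' @export
read_session_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(n_reps = 18L, n_blocks = 12L,
                   start_condition = "APAV", seed = 1L)
  known <- intersect(names(obj), names(defaults))
  defaults[known] <- obj[known]
  defaults$start_condition <- match_condition(defaults$start_condition)
  defaults
}
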