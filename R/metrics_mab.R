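#' Total length of a union of intervals
#'
#' Overlapping scored intervals (double-scored video segments) are merged
#' before any time summation so that no second of footage is counted twice.
#'
#' @param start_s,end_s Numeric vectors of interval starts and ends
#'   (seconds), `start_s < end_s` elementwise.
#' @return Total covered length in seconds.
#' @examples
#' interval_union_length(c(0, 5), c(10, 15)) # two overlapping 10 s -> 15
#' @export
interval_union_length <- function(start_s, end_s) {
  if (length(start_s) == 0) return(0)
  stopifnot(length(start_s) == length(end_s))
  if (any(end_s <= start_s)) {
    abort("intervals must satisfy start_s < end_s",
          class = "behavsyn_validation_error")
  }
  ord <- order(start_s, end_s)
  start_s <- start_s[ord]
  end_s <- end_s[ord]
  # running maximum of ends defines merged blocks
  cover_end <- cummax(end_s)
  new_block <- c(TRUE, start_s[-1] > cover_end[-length(cover_end)])
  block <- cumsum(new_block)
  sum(vapply(split(seq_along(block), block), function(i) {
    max(end_s[i]) - min(start_s[i])
  }, numeric(1)))
}

#' Multi-access box: persistence within a trial
#'
#' Persistence is the proportion of trial time spent actively interacting
#' with the apparatus: the union of interaction intervals divided by the
#' trial duration, clipped to `[0, 1]`.
#'
#' @param events Events of one trial (tibble with `start_s`, `end_s`,
#'   `behaviour_code`).
#' @param trial_duration Trial length in seconds (> 0).
#' @param interaction_codes Behaviour codes counting as apparatus
#'   interaction; `NULL` (default) counts every event row.
#' @return Persistence in `[0, 1]`.
#' @export
mab_persistence <- function(events, trial_duration, interaction_codes = NULL) {
  if (!is.numeric(trial_duration) || trial_duration <= 0) {
    abort("trial_duration must be > 0", class = "behavsyn_validation_error")
  }
  if (!is.null(interaction_codes)) {
    events <- events[events$behaviour_code %in% interaction_codes, ]
  }
  min(1, interval_union_length(events$start_s, events$end_s) / trial_duration)
}

#' Multi-access box: inverse inhibitory control within a trial
#'
#' Time allocated to previously learned but now blocked solutions relative
#' to total exploration time. Larger values mean poorer inhibitory control.
#' Overlapping intervals are unioned per target before summation.
#'
#' @param events Exploration events of one trial (tibble with `start_s`,
#'   `end_s`, `target` naming the solution explored).
#' @param blocked Character vector of learned-and-blocked solution ids for
#'   this phase; an empty/missing set is an error (the measure is undefined
#'   before anything has been learned and blocked).
#' @return Ratio in `[0, 1]`; 0 (with attribute `no_exploration = TRUE`)
#'   when total exploration time is zero.
#' @export
mab_inhibitory_inverse <- function(events, blocked) {
  if (length(blocked) == 0 || all(is.na(blocked))) {
    abort("no blocked solutions defined for this phase",
          class = "behavsyn_validation_error")
  }
  total <- interval_union_length(events$start_s, events$end_s)
  if (total == 0) {
    out <- 0
    attr(out, "no_exploration") <- TRUE
    return(out)
  }
  on_blocked <- events[events$target %in% blocked, ]
  min(1, interval_union_length(on_blocked$start_s, on_blocked$end_s) / total)
}

#' Multi-access box: first-exposure neophobia latency
#'
#' Latency (s) from trial start to first contact with the apparatus during
#' the first familiarization trial. When the subject never contacts the box
#' the latency is right-censored at the trial duration and the returned
#' value carries attribute `censored = TRUE`.
#'
#' @inheritParams mab_persistence
#' @param contact_codes Behaviour codes counting as contact; `NULL` counts
#'   every event.
#' @return Latency in seconds.
#' @export
mab_neophobia <- function(events, trial_duration, contact_codes = NULL) {
  if (!is.null(contact_codes)) {
    events <- events[events$behaviour_code %in% contact_codes, ]
  }
  if (nrow(events) == 0) {
    out <- trial_duration
    attr(out, "censored") <- TRUE
    return(out)
  }
  min(events$start_s)
}

#' Multi-access box: first-exposure exploratory diversity
#'
#' Size of the behavioural repertoire expressed toward the apparatus on
#' first exposure: the number of distinct behaviour codes in the first
#' familiarization trial.
#'
#' @param events Events of the first familiarization trial.
#' @return Non-negative integer count of distinct behaviour codes.
#' @export
mab_exploratory_diversity <- function(events) {
  dplyr::n_distinct(events$behaviour_code[!is.na(events$behaviour_code)])
}

#' Multi-access box: phase outcome from per-trial successes
#'
#' A solution counts as learned once three successful trials have
#' accumulated in the phase; the phase ends early after three consecutive
#' unsuccessful trials. Trials after the terminating trial are not counted.
#'
#' @param success Logical vector of per-trial success flags, in trial order.
#' @param successes_to_learn,fail_run_to_stop Criterion parameters
#'   (defaults 3 and 3).
#' @return One-row tibble: `learned`, `learned_at` (trial index or `NA`),
#'   `trials_completed`.
#' @export
mab_phase_outcomes <- function(success, successes_to_learn = 3,
                               fail_run_to_stop = 3) {
  success <- as.logical(success)
  n_succ <- 0L
  fail_run <- 0L
  for (t in seq_along(success)) {
    if (isTRUE(success[t])) {
      n_succ <- n_succ + 1L
      fail_run <- 0L
      if (n_succ >= successes_to_learn) {
        return(tibble::tibble(learned = TRUE, learned_at = t,
                              trials_completed = t))
      }
    } else {
      fail_run <- fail_run + 1L
      if (fail_run >= fail_run_to_stop) {
        return(tibble::tibble(learned = FALSE, learned_at = NA_integer_,
                              trials_completed = t))
      }
    }
  }
  tibble::tibble(learned = FALSE, learned_at = NA_integer_,
                 trials_completed = length(success))
}

#' Multi-access box: individual learning rate
#'
#' Learning progress is summarized as the within-phase ordinary
#' least-squares slope of exploration duration against trial number,
#' averaged over phases per individual, then z-standardized across the
#' cohort. The sign is flipped so that larger values mean a faster decline
#' in exploration duration, i.e. higher = faster learner.
#'
#' @param trials Tibble with one row per trial: `individual_id`, `phase`,
#'   `trial_index`, `exploration_s`.
#' @return Tibble with `individual_id`, `mean_slope` (raw s/trial) and
#'   `learning_rate` (standardized, sign-flipped); individuals with no
#'   phase of two or more trials get `NA`.
#' @export
mab_learning_rate <- function(trials) {
  slopes <- trials |>
    dplyr::filter(!is.na(.data$exploration_s)) |>
    dplyr::group_by(.data$individual_id, .data$phase) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      slope = coef(lm(exploration_s ~ trial_index,
                      data = dplyr::pick(dplyr::everything())))[[2]],
      .groups = "drop"
    )
  means <- slopes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(mean_slope = mean(.data$slope), .groups = "drop")
  out <- tibble::tibble(individual_id = unique(trials$individual_id)) |>
    dplyr::left_join(means, by = "individual_id")
  s <- sd(out$mean_slope, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    out$learning_rate <- ifelse(is.na(out$mean_slope), NA_real_, 0)
  } else {
    out$learning_rate <-
      -(out$mean_slope - mean(out$mean_slope, na.rm = TRUE)) / s
  }
  out
}
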