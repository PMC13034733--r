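#' Resource depletion test: per-trial metrics from a bowl-visit sequence
#'
#' Scores one trial of the six-bowl resource depletion test from the ordered
#' sequence of bowl inspections ("picks"). The six metrics:
#' \describe{
#'   \item{pick_count}{picks required to locate the (first) reward; the full
#'     sequence length when no reward was found.}
#'   \item{wme}{working-memory errors: within-trial revisits to any bowl
#'     already inspected in the same trial.}
#'   \item{llvr}{learned-location visit ratio: visits to the learned
#'     location / total visits.}
#'   \item{llsd}{learned-location stay duration: time at the learned
#'     location / total exploration time (`NA` without durations).}
#'   \item{accuracy}{1 - unsuccessful picks / total picks.}
#'   \item{tlv}{total distinct locations visited.}
#' }
#'
#' @param visits Tibble for one trial, in visit order: `bowl` (integer 1-6),
#'   optional `duration_s`, optional `rewarded` (logical; defaults to all
#'   `FALSE`).
#' @param learned_location Bowl id (1-6) of the learned location.
#' @return One-row tibble with the six metrics.
#' @examples
#' v <- tibble::tibble(bowl = c(3, 1, 4), rewarded = c(FALSE, FALSE, TRUE))
#' rdt_trial_metrics(v, learned_location = 3)
#' @export
rdt_trial_metrics <- function(visits, learned_location) {
  if (nrow(visits) == 0) {
    abort("empty visit sequence", class = "behavsyn_validation_error")
  }
  if (!learned_location %in% 1:6) {
    abort("learned_location must be a bowl in 1..6",
          class = "behavsyn_validation_error")
  }
  bowl <- visits$bowl
  rewarded <- if ("rewarded" %in% names(visits)) visits$rewarded
              else rep(FALSE, nrow(visits))
  has_dur <- "duration_s" %in% names(visits)
  n <- length(bowl)
  first_reward <- which(rewarded)[1]
  tibble::tibble(
    pick_count = if (is.na(first_reward)) n else first_reward,
    wme = sum(duplicated(bowl)),
    llvr = mean(bowl == learned_location),
    llsd = if (has_dur && sum(visits$duration_s) > 0) {
      sum(visits$duration_s[bowl == learned_location]) / sum(visits$duration_s)
    } else NA_real_,
    accuracy = 1 - sum(!rewarded) / n,
    tlv = dplyr::n_distinct(bowl)
  )
}

#' Resource depletion test: learning criteria across trials
#'
#' Applies the two phase-level learning rules. In the fixed-reward phase the
#' spatial rule counts as learned at the third trial of the first run of
#' three consecutive trials needing at most `pick_threshold` picks; subjects
#' without such a run within `max_trials` trials are classed as not having
#' learned. In the depletion phase, delayed fixation trials (DFT) is the
#' number of trials elapsed before the first run of three consecutive trials
#' with no visit to the formerly rewarded location (0 when avoidance is
#' immediate; `NA`, censored, when the run never occurs).
#'
#' @param fixed_picks Numeric vector of per-trial pick counts in the
#'   fixed-reward phase, in trial order.
#' @param depletion_visited_learned Logical vector: did each depletion-phase
#'   trial contain a visit to the learned location?
#' @param pick_threshold,run_length Criterion parameters (defaults 2, 3).
#' @param max_trials Fixed-phase trial cap (default 20).
#' @return One-row tibble: `learned`, `trials_to_learn` (`NA` if not
#'   learned), `dft`.
#' @examples
#' rdt_learning(c(5, 2, 2, 2), c(TRUE, FALSE, FALSE, FALSE))
#' @export
rdt_learning <- function(fixed_picks, depletion_visited_learned,
                         pick_threshold = 2, run_length = 3,
                         max_trials = 20) {
  fixed_picks <- head(fixed_picks, max_trials)
  ttl <- NA_integer_
  if (length(fixed_picks) >= run_length) {
    ok <- fixed_picks <= pick_threshold
    runs <- .first_run_end(ok, run_length)
    if (!is.na(runs)) ttl <- runs
  }
  dft <- NA_integer_
  if (length(depletion_visited_learned) >= run_length) {
    run_end <- .first_run_end(!depletion_visited_learned, run_length)
    if (!is.na(run_end)) dft <- run_end - run_length
  }
  tibble::tibble(learned = !is.na(ttl), trials_to_learn = ttl, dft = dft)
}

# index of the last element of the first run of `len` consecutive TRUE
.first_run_end <- function(x, len) {
  if (length(x) < len) return(NA_integer_)
  run <- 0L
  for (i in seq_along(x)) {
    run <- if (isTRUE(x[i])) run + 1L else 0L
    if (run >= len) return(i)
  }
  NA_integer_
}

#' Resource depletion test: score a full visit table
#'
#' Table-level wrapper applying [rdt_trial_metrics()] to every trial and
#' [rdt_learning()] to every individual of a visit table covering the fixed
#' and depletion phases.
#'
#' @param visits Tibble with `individual_id`, `phase` (`"fixed"` or
#'   `"depletion"`), `trial_index`, `bowl`, and optionally `duration_s`,
#'   `rewarded`, in within-trial visit order.
#' @param learned_location Bowl id of the fixed-phase reward (default 3).
#' @return A list with `trials` (per-trial metric tibble) and `individuals`
#'   (per-individual learning summary: `learned`, `trials_to_learn`, `dft`).
#' @export
rdt_score_table <- function(visits, learned_location = 3) {
  if (!"rewarded" %in% names(visits)) visits$rewarded <- FALSE
  has_dur <- "duration_s" %in% names(visits)
  # vectorized equivalent of rdt_trial_metrics() per trial (kept in lock
  # step by a consistency test against the per-trial operation)
  trials <- visits |>
    dplyr::group_by(.data$individual_id, .data$phase, .data$trial_index) |>
    dplyr::summarise(
      pick_count = {
        r <- which(.data$rewarded)[1]
        as.numeric(if (is.na(r)) dplyr::n() else r)
      },
      wme = sum(duplicated(.data$bowl)),
      llvr = mean(.data$bowl == learned_location),
      llsd = if (has_dur && sum(.data$duration_s) > 0) {
        sum(.data$duration_s[.data$bowl == learned_location]) /
          sum(.data$duration_s)
      } else NA_real_,
      accuracy = 1 - sum(!.data$rewarded) / dplyr::n(),
      tlv = dplyr::n_distinct(.data$bowl),
      visited_learned = any(.data$bowl == learned_location),
      .groups = "drop"
    )
  individuals <- trials |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      fixed <- d[d$phase == "fixed", ]
      fixed <- fixed[order(fixed$trial_index), ]
      depl <- d[d$phase == "depletion", ]
      depl <- depl[order(depl$trial_index), ]
      rdt_learning(fixed$pick_count, depl$visited_learned)
    }) |>
    dplyr::ungroup()
  trials$visited_learned <- NULL
  list(trials = trials, individuals = individuals)
}
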