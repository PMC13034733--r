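#' String-pulling task: deductive reasoning score (DRS)
#'
#' Trials to criterion in a two-string choice phase. Learning is defined as
#' at least 80% success (8 of 10) in three consecutive overlapping 10-trial
#' moving windows; the DRS is the trial index at which the third qualifying
#' window closes. Non-learners within `max_trials` trials are assigned
#' `max_trials + 1` (151 under the defaults).
#'
#' @param success Logical (or 0/1) vector of per-trial success flags.
#' @param window Window width in trials (default 10).
#' @param criterion Successes required per window (default 8).
#' @param n_windows Number of consecutive qualifying windows (default 3).
#' @param max_trials Phase length cap (default 150).
#' @return Integer DRS in `[window + n_windows - 1, max_trials + 1]`.
#' @examples
#' sp_drs(rep(TRUE, 12)) # earliest possible criterion: 12
#' sp_drs(rep(FALSE, 150)) # non-learner: 151
#' @export
sp_drs <- function(success, window = 10, criterion = 8, n_windows = 3,
                   max_trials = 150) {
  success <- as.integer(head(as.logical(success), max_trials))
  n <- length(success)
  if (n >= window) {
    cs <- cumsum(success)
    # successes in window ending at trial e, e = window..n
    win <- cs[window:n] - c(0, cs)[seq_len(n - window + 1)]
    ok <- win >= criterion
    end <- .first_run_end(ok, n_windows)
    if (!is.na(end)) return(end + window - 1L)
  }
  as.integer(max_trials + 1L)
}

#' Forelimb handedness from pull events
#'
#' Handedness index HI = (R - L) / (R + L) over scored forelimb uses, its
#' binomial normal-approximation z statistic
#' z = (R - N/2) / sqrt(N/4), and a three-way label: `R` when
#' `hi_z >= z_crit`, `L` when `hi_z <= -z_crit`, else `N` (no significant
#' preference; default `z_crit = 1.96`, two-sided 5%).
#'
#' @param forelimb Character vector of forelimb labels per pull; entries
#'   other than `"L"`/`"R"` are ignored.
#' @param z_crit Critical z value for labelling (default 1.96).
#' @return One-row tibble: `n_pulls`, `n_left`, `n_right`, `hi`, `hi_z`,
#'   `hand_label`.
#' @examples
#' handedness(rep(c("L", "R"), c(10, 10))) # hi 0, label N
#' @export
handedness <- function(forelimb, z_crit = 1.96) {
  n_r <- sum(forelimb == "R", na.rm = TRUE)
  n_l <- sum(forelimb == "L", na.rm = TRUE)
  n <- n_r + n_l
  if (n == 0) {
    abort("no lateralized pull events; handedness undefined",
          class = "behavsyn_empty_data_error")
  }
  hi <- (n_r - n_l) / n
  z <- (n_r - n / 2) / sqrt(n / 4)
  tibble::tibble(
    n_pulls = n, n_left = n_l, n_right = n_r, hi = hi, hi_z = z,
    hand_label = if (z >= z_crit) "R" else if (z <= -z_crit) "L" else "N"
  )
}
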