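test_that("trial metrics match the worked bowl-visit example", {
  v <- tibble::tibble(bowl = c(3, 1, 4), duration_s = c(4, 2, 2),
                      rewarded = c(FALSE, FALSE, TRUE))
  m <- rdt_trial_metrics(v, learned_location = 3)
  expect_equal(m$pick_count, 3)
  expect_equal(m$accuracy, 1 - 2 / 3)
  expect_equal(m$llvr, 1 / 3)
  expect_equal(m$tlv, 3)
  expect_equal(m$wme, 0)
  expect_equal(m$llsd, 0.5)
  expect_equal(rdt_trial_metrics(tibble::tibble(bowl = c(2, 2)), 3)$wme, 1)
  expect_error(rdt_trial_metrics(tibble::tibble(bowl = integer()), 3),
               class = "behavsyn_validation_error")
  expect_error(rdt_trial_metrics(v, learned_location = 9),
               class = "behavsyn_validation_error")
})

test_that("all six metrics equal an independent recount on random trials", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(2:10, 1)
      bowl <- sample(1:6, n, replace = TRUE)
      rewarded <- runif(n) < 0.3
      dur <- round(runif(n, 1, 9), 2)
      got <- rdt_trial_metrics(
        tibble::tibble(bowl = bowl, duration_s = dur, rewarded = rewarded),
        learned_location = 3)
      want <- oracle_rdt(bowl, rewarded, dur, 3)
      expect_equal(got$pick_count, want$pick_count)
      expect_equal(got$wme, want$wme)
      expect_equal(got$llvr, want$llvr)
      expect_equal(got$llsd, want$llsd)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$tlv, want$tlv)
    }
  })
})

test_that("accuracy and the unsuccessful fraction sum to one exactly", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(1:8, 1)
      rewarded <- runif(n) < 0.4
      m <- rdt_trial_metrics(
        tibble::tibble(bowl = sample(1:6, n, TRUE), rewarded = rewarded), 3)
      expect_identical(m$accuracy + sum(!rewarded) / n, 1)
    }
  })
})

test_that("learning criteria follow the three-consecutive-trial rules", {
  out <- rdt_learning(c(5, 2, 2, 2), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(out$learned)
  expect_equal(out$trials_to_learn, 4L)
  # avoidance from depletion trial 1 onward: zero delayed fixation trials
  expect_equal(rdt_learning(c(5, 2, 2, 2), rep(FALSE, 5))$dft, 0L)
  # fewer than 3 fixed trials cannot satisfy the criterion
  expect_false(rdt_learning(c(1, 1), rep(TRUE, 5))$learned)
  # criterion must occur within the trial cap
  late <- c(rep(5, 19), 2, 2, 2)
  expect_false(rdt_learning(late, rep(TRUE, 5), max_trials = 20)$learned)
})

test_that("learning indices agree with a sliding-window oracle", {
  slide_first <- function(x, len) {
    for (s in seq_len(length(x) - len + 1)) {
      if (all(x[s:(s + len - 1)])) return(s + len - 1)
    }
    NA_integer_
  }
  withr::with_seed(13, {
    for (rep in 1:30) {
      picks <- sample(1:5, 15, replace = TRUE)
      visited <- runif(12) < 0.5
      got <- rdt_learning(picks, visited)
      expect_equal(got$trials_to_learn,
                   slide_first(picks <= 2, 3))
      want_dft <- slide_first(!visited, 3)
      expect_equal(got$dft,
                   if (is.na(want_dft)) NA_integer_ else want_dft - 3L)
    }
  })
})

test_that("table-level scoring nests trial and individual summaries", {
  visits <- dplyr::bind_rows(
    tidyr::expand_grid(individual_id = "A", phase = "fixed",
                       trial_index = 1:12) |>
      dplyr::mutate(bowl = 3, duration_s = 3, rewarded = TRUE,
                    visit_index = 1),
    tidyr::expand_grid(individual_id = "A", phase = "depletion",
                       trial_index = 1:5) |>
      dplyr::mutate(bowl = 2, duration_s = 3, rewarded = TRUE,
                    visit_index = 1)
  )
  out <- rdt_score_table(visits, learned_location = 3)
  expect_equal(nrow(out$trials), 17)
  expect_equal(out$individuals$trials_to_learn, 3L)
  expect_equal(out$individuals$dft, 0L)
})

test_that("vectorized table scoring agrees with the per-trial operation", {
  withr::with_seed(47, {
    visits <- purrr::map(1:15, function(t) {
      n <- sample(1:7, 1)
      tibble::tibble(individual_id = sample(c("A", "B"), 1),
                     phase = sample(c("fixed", "depletion"), 1),
                     trial_index = t, bowl = sample(1:6, n, TRUE),
                     duration_s = runif(n, 1, 8), rewarded = runif(n) < 0.3)
    }) |> purrr::list_rbind()
    fast <- rdt_score_table(visits, 3)$trials
    slow <- visits |>
      dplyr::group_by(individual_id, phase, trial_index) |>
      dplyr::group_modify(~ rdt_trial_metrics(.x, 3)) |>
      dplyr::ungroup()
    expect_equal(as.data.frame(fast), as.data.frame(slow))
  })
})
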