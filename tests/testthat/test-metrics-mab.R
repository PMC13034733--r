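ev <- function(start, end, code = "interact", target = "box") {
  tibble::tibble(start_s = start, end_s = end, behaviour_code = code,
                 target = target)
}

test_that("persistence is unioned interaction time over trial duration", {
  expect_equal(mab_persistence(ev(0, 30), 60), 0.5)
  expect_equal(mab_persistence(ev(numeric(), numeric()), 60), 0)
  # two overlapping 10 s intervals covering 15 s of a 60 s trial
  expect_equal(mab_persistence(ev(c(0, 5), c(10, 15)), 60), 0.25)
  expect_error(mab_persistence(ev(0, 30), 0),
               class = "behavsyn_validation_error")
})

test_that("interval union matches a grid-indicator oracle on random sets", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      k <- sample(1:8, 1)
      start <- round(runif(k, 0, 50), 2)
      end <- start + round(runif(k, 0.05, 20), 2)
      expect_equal(interval_union_length(start, end),
                   oracle_union_length(start, end), tolerance = 1e-9)
    }
  })
})

test_that("inverse inhibitory control is blocked time over exploration time", {
  e <- dplyr::bind_rows(ev(0, 20, "explore", "push"),
                        ev(20, 80, "explore", "slide"))
  expect_equal(mab_inhibitory_inverse(e, blocked = "push"), 0.25)
  expect_equal(mab_inhibitory_inverse(e, blocked = "drawer"), 0)
  expect_error(mab_inhibitory_inverse(e, blocked = character()),
               class = "behavsyn_validation_error")
  none <- ev(numeric(), numeric(), "explore", character())
  out <- mab_inhibitory_inverse(none, blocked = "push")
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "no_exploration"))
})

test_that("inhibitory ratio equals per-event summation for disjoint events", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      k <- sample(3:10, 1)
      lens <- round(runif(k, 1, 15), 2)
      start <- cumsum(c(0, lens[-k] + 0.5))
      target <- sample(c("push", "pull", "slide"), k, replace = TRUE)
      e <- ev(start, start + lens, "explore", target)
      blocked <- "push"
      expect_equal(mab_inhibitory_inverse(e, blocked),
                   sum(lens[target == "push"]) / sum(lens),
                   tolerance = 1e-9)
    }
  })
})

test_that("neophobia latency and diversity follow first-exposure scoring", {
  e <- dplyr::bind_rows(ev(12.5, 20, "contact"), ev(30, 40, "sniff"))
  expect_equal(as.numeric(mab_neophobia(e, 300)), 12.5)
  cens <- mab_neophobia(ev(numeric(), numeric()), 300)
  expect_equal(as.numeric(cens), 300)
  expect_true(attr(cens, "censored"))
  codes <- ev(c(1, 2, 3, 4), c(2, 3, 4, 5),
              c("sniff", "paw", "bite", "sniff"))
  expect_equal(mab_exploratory_diversity(codes), 3)
  # permutation invariance
  shuf <- codes[c(3, 1, 4, 2), ]
  expect_equal(mab_exploratory_diversity(shuf), 3)
  expect_equal(as.numeric(mab_neophobia(shuf, 300)),
               as.numeric(mab_neophobia(codes, 300)))
})

test_that("phase outcomes follow the learn-3 / fail-3 termination rules", {
  expect_equal(mab_phase_outcomes(c(TRUE, TRUE, TRUE)),
               tibble::tibble(learned = TRUE, learned_at = 3L,
                              trials_completed = 3L))
  out <- mab_phase_outcomes(c(FALSE, FALSE, FALSE))
  expect_false(out$learned)
  expect_equal(out$trials_completed, 3L)
  withr::with_seed(3, {
    for (rep in 1:30) {
      s <- runif(sample(3:12, 1)) < 0.45
      got <- mab_phase_outcomes(s)
      want <- oracle_phase_outcome(s)
      expect_equal(got$learned, want$learned)
      expect_equal(got$trials_completed, want$stop_at)
    }
  })
})

test_that("learning rate is the sign-flipped standardized mean slope", {
  trials <- tibble::tibble(
    individual_id = rep(c("A", "B"), each = 3),
    phase = "phase1", trial_index = rep(1:3, 2),
    exploration_s = c(100, 90, 80, 100, 100, 100)
  )
  out <- mab_learning_rate(trials)
  expect_equal(out$mean_slope, c(-10, 0))
  # faster decliner (A) standardizes to the higher learning rate
  expect_equal(out$learning_rate[1],
               -(out$mean_slope[1] - mean(out$mean_slope)) /
                 sd(out$mean_slope))
  expect_gt(out$learning_rate[1], out$learning_rate[2])
})

test_that("learning-rate ranks reverse the raw mean-slope ranks", {
  withr::with_seed(5, {
    trials <- tidyr::expand_grid(individual_id = sprintf("I%02d", 1:8),
                                 phase = c("p1", "p2"), trial_index = 1:6)
    slopes <- setNames(runif(8, -12, -2), sprintf("I%02d", 1:8))
    trials$exploration_s <- 150 +
      slopes[trials$individual_id] * trials$trial_index +
      rnorm(nrow(trials), 0, 4)
    out <- mab_learning_rate(trials)
    expect_equal(order(out$learning_rate), rev(order(out$mean_slope)))
  })
})
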