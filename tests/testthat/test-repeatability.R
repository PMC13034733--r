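test_that("REML on balanced designs equals the ANOVA moment estimators", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      k <- 10
      n0 <- 6
      g <- rep(sprintf("G%02d", 1:k), each = n0)
      y <- rnorm(k, 0, 1)[factor(g)] + rnorm(k * n0)
      d <- tibble::tibble(y = y, g = g)
      fit <- fit_random_intercept(d, "y", "g", method = "REML")
      want <- oracle_anova_vc(y, g)
      expect_equal(fit$v_individual, want$v_ind, tolerance = 1e-4)
      expect_equal(fit$v_residual, want$v_res, tolerance = 1e-4)
    }
  })
})

test_that("no between-group signal yields a flagged boundary fit", {
  d <- tibble::tibble(y = rep(c(-1, 1), 10),
                      g = rep(c("a", "b"), each = 10))
  fit <- fit_random_intercept(d, "y", "g")
  expect_true(fit$boundary)
  expect_equal(fit$v_individual, 0, tolerance = 1e-6)
  expect_equal(icc(fit), 0, tolerance = 1e-6)
})

test_that("variance components and likelihoods match lme4 on messy data", {
  skip_if_not_installed("lme4")
  withr::with_seed(202, {
    d <- tibble::tibble(
      g = rep(sprintf("G%02d", 1:12), times = sample(3:9, 12, TRUE))
    )
    d$x <- stats::ave(seq_len(nrow(d)), d$g, FUN = seq_along)
    d$y <- rnorm(12, 0, 0.8)[factor(d$g)] + 0.3 * d$x + rnorm(nrow(d))
    reml <- fit_random_intercept(d, "y", "g", fixed = ~x)
    lmod <- lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lmod))
    expect_equal(reml$v_individual, vc$vcov[1], tolerance = 1e-4)
    expect_equal(reml$v_residual, vc$vcov[2], tolerance = 1e-4)
    expect_equal(unname(reml$beta), unname(lme4::fixef(lmod)),
                 tolerance = 1e-5)
    ml <- fit_random_intercept(d, "y", "g", fixed = ~x, method = "ML")
    mlmod <- lme4::lmer(y ~ x + (1 | g), data = d, REML = FALSE)
    expect_equal(ml$logLik, as.numeric(logLik(mlmod)), tolerance = 1e-5)
  })
})

test_that("ICC arithmetic and affine invariance hold", {
  expect_equal(icc(list(v_individual = 1, v_residual = 1)), 0.5)
  expect_equal(icc(list(v_individual = 0, v_residual = 2)), 0)
  # the published persistence repeatability scale
  expect_equal(icc(list(v_individual = 0.318 / (1 - 0.318),
                        v_residual = 1)), 0.318, tolerance = 1e-12)
  expect_error(icc(list(v_individual = 0, v_residual = 0)),
               class = "behavsyn_validation_error")
  withr::with_seed(303, {
    d <- sim_trait_trials(15, 6, icc = 0.4, seed = 9)
    f1 <- fit_random_intercept(d, "value", "individual_id")
    d$value2 <- 3.7 * d$value - 11
    f2 <- fit_random_intercept(d, "value2", "individual_id")
    expect_equal(icc(f1), icc(f2), tolerance = 1e-6)
  })
})

test_that("variance-ratio recovery lands near truth at moderate size", {
  d <- sim_trait_trials(50, 10, icc = 0.5, total_var = 2, seed = 77)
  fit <- fit_random_intercept(d, "value", "individual_id")
  expect_gt(fit$v_individual, 0.6)
  expect_lt(fit$v_individual, 1.5)
})

test_that("boundary-corrected LRT halves the naive p-value", {
  d <- sim_trait_trials(20, 8, icc = 0.3, seed = 5)
  out <- lrt_random_intercept(d, "value", "individual_id")
  expect_equal(out$p_mixture, out$p_naive / 2)
  expect_gte(out$chi2, 0)
  # chi2 at the 5% naive cutoff maps to 2.5% under the mixture
  expect_equal(0.5 * pchisq(3.841, 1, lower.tail = FALSE), 0.025,
               tolerance = 1e-3)
  # null data: chi2 frequently 0, p then exactly 1
  d0 <- sim_trait_trials(10, 4, icc = 0, seed = 123)
  out0 <- lrt_random_intercept(d0, "value", "individual_id")
  if (out0$chi2 == 0) expect_equal(out0$p_mixture, 1)
})

test_that("parametric bootstrap is reproducible and respects the boundary", {
  d <- sim_trait_trials(12, 6, icc = 0.35, seed = 11)
  fit <- fit_random_intercept(d, "value", "individual_id")
  ci1 <- bootstrap_icc(fit, n_boot = 100, seed = 42)
  ci2 <- bootstrap_icc(fit, n_boot = 100, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$icc)
  expect_gte(ci1$ci_high, ci1$icc)
  # zero-ICC truth puts the lower bound on the boundary
  d0 <- sim_trait_trials(12, 6, icc = 0, seed = 13)
  f0 <- fit_random_intercept(d0, "value", "individual_id")
  ci0 <- bootstrap_icc(f0, n_boot = 100, seed = 7)
  expect_equal(ci0$ci_low, 0, tolerance = 1e-6)
  expect_error(bootstrap_icc(fit, n_boot = 10),
               class = "behavsyn_validation_error")
})

test_that("the repeatability gate keeps repeatable metrics and drops flat ones", {
  d <- sim_trait_trials(12, 20, icc = 0.5, seed = 21) |>
    dplyr::rename(stable = value)
  d$flat <- withr::with_seed(22, rnorm(nrow(d)))
  screen <- repeatability_filter(d, c("stable", "flat"),
                                 fixed = ~trial_index)
  expect_true(screen$repeatability$retained[
    screen$repeatability$metric == "stable"])
  expect_identical(screen$dropped, "flat")
  expect_equal(names(screen$scores), c("individual_id", "stable"))
  expect_equal(nrow(screen$scores), 12)
  td <- tidy(screen)
  expect_true(all(c("icc", "p_mixture", "retained") %in% names(td)))
})
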