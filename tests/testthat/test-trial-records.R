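test_that("event tables round-trip through write/read bit-exactly", {
  ev <- tibble::tibble(
    individual_id = c("A", "A", "B"), paradigm = "MAB",
    phase = c("phase1", "phase1", "phase2"), trial_index = c(1L, 1L, 2L),
    behaviour_code = c("interact", "explore", "interact"),
    target = c("box", "push", "box"),
    start_s = c(0, 10.25, 3.5), end_s = c(30, 20.75, 60),
    forelimb = c("none", "L", "R"), success = c(TRUE, NA, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_events(ev, path)
  back <- read_trial_events(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))
})

test_that("malformed events are rejected with row numbers", {
  ev <- tibble::tibble(
    individual_id = "A", paradigm = "MAB", phase = "p", trial_index = 1L,
    behaviour_code = "x", target = "box", start_s = c(0, 50), end_s = c(10, 40),
    forelimb = "none", success = NA
  )
  expect_error(validate_trial_events(ev), "row\\(s\\) 2",
               class = "behavsyn_validation_error")
  expect_error(validate_trial_events(ev[, -1]), "individual_id",
               class = "behavsyn_format_error")
  bad_bowl <- dplyr::mutate(ev[1, ], paradigm = "RDT", target = "7",
                            end_s = 10)
  expect_error(validate_trial_events(bad_bowl), "bowl",
               class = "behavsyn_validation_error")
})

test_that("baseline fGCM is the windowed mean and errors on empty input", {
  s <- tibble::tibble(
    sample_id = paste0("s", 1:3), individual_id = "A",
    collection_date = as.Date("2023-07-26") + 0:2,
    fgcm_ng_g = c(100, 200, 300), context = "captive"
  )
  expect_equal(baseline_fgcm(s)$baseline_fgcm, 200)
  expect_equal(baseline_fgcm(s[1, ])$baseline_fgcm, 100)
  # order invariance and linearity in a common scale factor
  shuffled <- s[c(3, 1, 2), ]
  expect_equal(baseline_fgcm(shuffled)$baseline_fgcm, 200)
  scaled <- dplyr::mutate(s, fgcm_ng_g = fgcm_ng_g * 2.5)
  expect_equal(baseline_fgcm(scaled)$baseline_fgcm, 500)
  # samples beyond the window are excluded
  late <- dplyr::bind_rows(s, dplyr::mutate(s[1, ], sample_id = "s9",
                                            collection_date = collection_date + 30,
                                            fgcm_ng_g = 1e6))
  expect_equal(baseline_fgcm(late, window_days = 5)$baseline_fgcm, 200)
  expect_error(baseline_fgcm(s, individuals = c("A", "Z")),
               class = "behavsyn_empty_data_error")
})

test_that("windowed means match direct summation on random draws", {
  withr::with_seed(42, {
    for (i in 1:5) {
      vals <- round(runif(5, 50, 500), 2)
      s <- tibble::tibble(sample_id = paste0("x", 1:5), individual_id = "Z",
                          collection_date = as.Date("2024-01-01") + 0:4,
                          fgcm_ng_g = vals)
      expect_equal(baseline_fgcm(s)$baseline_fgcm, sum(vals) / 5)
    }
  })
})

test_that("packaged captive table has the published structure", {
  cap <- panda_captive()
  expect_equal(nrow(cap), 12)
  expect_equal(sum(cap$sex == "F"), 3)
  # MAB axes unavailable for one relocated individual
  expect_equal(sum(is.na(cap$reactive)), 1)
  expect_equal(range(cap$fgcm_ng_g), c(165.94, 489.22))
})

test_that("mean-matched hormone samples recover the published baselines", {
  cap <- panda_captive()
  base <- baseline_fgcm(synthetic_hormone_samples(cap),
                        individuals = cap$individual_id)
  expect_equal(base$baseline_fgcm, cap$fgcm_ng_g)
  expect_equal(range(base$baseline_fgcm), c(165.94, 489.22))
})

test_that("profile and hormone validation enforce the schema", {
  p <- tibble::tibble(individual_id = c("A", "A"), sex = "M",
                      age_years = 3, body_mass_kg = 100)
  expect_error(validate_individual_profiles(p), "unique",
               class = "behavsyn_validation_error")
  p2 <- tibble::tibble(individual_id = c("A", "B"), sex = "M",
                       age_years = c(3, 8), body_mass_kg = 100)
  out <- validate_individual_profiles(p2, adult_min_years = 5)
  expect_equal(out$age_class, c("subadult", "adult"))
  h <- tibble::tibble(sample_id = "s1", individual_id = "A",
                      collection_date = "26/07/2023", fgcm_ng_g = 10)
  expect_error(validate_hormone_samples(h), "ISO-8601",
               class = "behavsyn_validation_error")
})

test_that("empty file with header reads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("individual_id", "paradigm", "phase", "trial_index",
                     "behaviour_code", "target", "start_s", "end_s",
                     "forelimb", "success"), collapse = "\t"), path)
  expect_equal(nrow(read_trial_events(path)), 0)
})
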