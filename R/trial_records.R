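#' Read a scored behavioural event table
#'
#' Reads a delimited text file of frame-by-frame scored behavioural events
#' (one row per event) for one of the three captive paradigms: the
#' multi-access box (`"MAB"`), the resource depletion test (`"RDT"`) or the
#' string-pulling task (`"SP"`). Times are seconds from trial start; trial
#' indices are 1-based.
#'
#' @param path Path to a UTF-8 delimited file with a header row.
#' @param paradigm One of `"MAB"`, `"RDT"`, `"SP"`. When supplied, rows whose
#'   `paradigm` column disagrees raise a validation error.
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `individual_id`, `paradigm`, `phase`,
#'   `trial_index`, `behaviour_code`, `target`, `start_s`, `end_s`,
#'   `forelimb`, `success`, validated against the event-table contract.
#' @seealso [write_trial_events()], [validate_trial_events()]
#' @export
read_trial_events <- function(path, paradigm = NULL, delim = "\t") {
  events <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(
      individual_id = readr::col_character(),
      paradigm = readr::col_character(),
      phase = readr::col_character(),
      trial_index = readr::col_integer(),
      behaviour_code = readr::col_character(),
      target = readr::col_character(),
      start_s = readr::col_double(),
      end_s = readr::col_double(),
      forelimb = readr::col_character(),
      success = readr::col_logical()
    ),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  validate_trial_events(events, paradigm = paradigm)
}

.event_columns <- c(
  "individual_id", "paradigm", "phase", "trial_index", "behaviour_code",
  "target", "start_s", "end_s", "forelimb", "success"
)

#' Validate a behavioural event table
#'
#' Enforces the event-table contract: mandatory columns present, event
#' intervals well formed (`0 <= start_s < end_s`), 1-based trial indices,
#' forelimb labels in `{L, R, none}` and, for the resource depletion test,
#' bowl targets in 1..6. Malformed rows are reported by row number.
#'
#' @param events A data frame of scored events.
#' @inheritParams read_trial_events
#' @return The validated events as a tibble (invisibly unchanged).
#' @export
validate_trial_events <- function(events, paradigm = NULL) {
  missing_cols <- setdiff(.event_columns, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "event table lacks mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "behavsyn_format_error")
  }
  events <- tibble::as_tibble(events)
  bad_rows <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "start_s >= end_s" = bad_rows(events$start_s >= events$end_s),
    "negative start_s" = bad_rows(events$start_s < 0),
    "trial_index < 1" = bad_rows(events$trial_index < 1),
    "forelimb not in {L, R, none}" =
      bad_rows(!events$forelimb %in% c("L", "R", "none") &
                 !is.na(events$forelimb))
  )
  if (!is.null(paradigm)) {
    paradigm <- match.arg(paradigm, c("MAB", "RDT", "SP"))
    problems[["paradigm mismatch"]] <- bad_rows(events$paradigm != paradigm)
  }
  rdt <- !is.na(events$paradigm) & events$paradigm == "RDT"
  problems[["RDT target bowl not in 1..6"]] <-
    which(rdt & !events$target %in% as.character(1:6))
  problems <- problems[vapply(problems, length, 1L) > 0]
  if (length(problems) > 0) {
    msg <- vapply(names(problems), function(nm) {
      paste0(nm, " at row(s) ", paste(head(problems[[nm]], 10), collapse = ", "))
    }, character(1))
    abort(paste0("invalid event rows:\n", paste("-", msg, collapse = "\n")),
          class = "behavsyn_validation_error")
  }
  events
}

#' Write a behavioural event table
#'
#' Inverse of [read_trial_events()]: writes tab-delimited UTF-8 text with a
#' header so that reading the file back reproduces the table exactly.
#'
#' @param events A validated event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_events <- function(events, path) {
  validate_trial_events(events)
  readr::write_tsv(events[.event_columns], path, na = "")
  invisible(path)
}

#' Read an individual profile table
#'
#' One row per study subject: `individual_id`, `sex` (M/F), `age_years`,
#' `body_mass_kg` and optionally a `handedness_label`. An `age_class`
#' column (`subadult`/`adult`) is derived from `age_years` when absent.
#'
#' @param path Delimited file with header.
#' @param adult_min_years Age (years) at or above which an individual is
#'   classed as adult when `age_class` is not supplied. The boundary is a
#'   study convention, recorded in the returned table's
#'   `adult_min_years` attribute.
#' @param delim Field delimiter, default tab.
#' @return A tibble of validated profiles.
#' @export
read_individual_profiles <- function(path, adult_min_years = 5, delim = "\t") {
  profiles <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                                progress = FALSE, show_col_types = FALSE)
  validate_individual_profiles(profiles, adult_min_years = adult_min_years)
}

#' @rdname read_individual_profiles
#' @param profiles A data frame of individual profiles.
#' @export
validate_individual_profiles <- function(profiles, adult_min_years = 5) {
  needed <- c("individual_id", "sex", "age_years", "body_mass_kg")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("profile table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "behavsyn_format_error")
  }
  profiles <- tibble::as_tibble(profiles)
  if (anyDuplicated(profiles$individual_id)) {
    abort("individual_id must be unique within a study",
          class = "behavsyn_validation_error")
  }
  bad <- which(!is.na(profiles$age_years) & profiles$age_years <= 0)
  bad <- union(bad, which(!is.na(profiles$body_mass_kg) &
                            profiles$body_mass_kg <= 0))
  bad <- union(bad, which(!profiles$sex %in% c("M", "F") &
                            !is.na(profiles$sex)))
  if (length(bad) > 0) {
    abort(paste0("invalid profile row(s): ",
                 paste(sort(bad), collapse = ", ")),
          class = "behavsyn_validation_error")
  }
  if (!"age_class" %in% names(profiles)) {
    profiles$age_class <-
      ifelse(profiles$age_years >= adult_min_years, "adult", "subadult")
  }
  attr(profiles, "adult_min_years") <- adult_min_years
  profiles
}

#' Read a hormone sample table
#'
#' One row per faecal sample: `sample_id`, `individual_id`,
#' `collection_date` (ISO-8601 `YYYY-MM-DD`; any other format is rejected),
#' `fgcm_ng_g` (faecal glucocorticoid metabolite concentration, ng per g dry
#' faeces, non-negative) and `context` (`captive` or `wild`).
#'
#' @param path Delimited file with header.
#' @param delim Field delimiter, default tab.
#' @return A tibble of validated hormone samples.
#' @export
read_hormone_samples <- function(path, delim = "\t") {
  samples <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(
      sample_id = readr::col_character(),
      individual_id = readr::col_character(),
      collection_date = readr::col_character(),
      fgcm_ng_g = readr::col_double(),
      context = readr::col_character()
    ),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  validate_hormone_samples(samples)
}

#' @rdname read_hormone_samples
#' @param samples A data frame of hormone samples.
#' @export
validate_hormone_samples <- function(samples) {
  needed <- c("sample_id", "individual_id", "collection_date", "fgcm_ng_g")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("hormone table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "behavsyn_format_error")
  }
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id must be unique", class = "behavsyn_validation_error")
  }
  if (is.character(samples$collection_date)) {
    iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", samples$collection_date)
    if (any(!iso & !is.na(samples$collection_date))) {
      abort(paste0("collection_date must be ISO-8601 (YYYY-MM-DD); bad row(s): ",
                   paste(which(!iso), collapse = ", ")),
            class = "behavsyn_validation_error")
    }
    samples$collection_date <- as.Date(samples$collection_date)
  }
  bad <- which(!is.na(samples$fgcm_ng_g) & samples$fgcm_ng_g < 0)
  if (length(bad) > 0) {
    abort(paste0("negative fgcm_ng_g at row(s): ", paste(bad, collapse = ", ")),
          class = "behavsyn_validation_error")
  }
  samples
}

#' Per-individual baseline fGCM concentration
#'
#' Averages each individual's faecal glucocorticoid metabolite
#' concentrations over a short standardized sampling window anchored at the
#' individual's first sample, yielding the study-entry "baseline" used by
#' all downstream hormone-behaviour analyses. Individuals with no sample in
#' the window are an explicit error, never a silent zero.
#'
#' @param samples A hormone sample tibble (see [read_hormone_samples()]).
#' @param window_days Width of the baseline window in days (default 5);
#'   samples collected within `window_days` days of the individual's first
#'   sample (inclusive) enter the mean.
#' @param individuals Optional character vector restricting and ordering the
#'   output; an individual with no usable samples raises an error.
#' @return A tibble with `individual_id`, `n_samples` and `baseline_fgcm`
#'   (arithmetic mean, ng/g).
#' @examples
#' samples <- tibble::tibble(
#'   sample_id = paste0("s", 1:3), individual_id = "A",
#'   collection_date = as.Date("2023-07-26") + 0:2,
#'   fgcm_ng_g = c(100, 200, 300)
#' )
#' baseline_fgcm(samples) # mean 200
#' @export
baseline_fgcm <- function(samples, window_days = 5, individuals = NULL) {
  samples <- validate_hormone_samples(samples)
  samples <- dplyr::filter(samples, !is.na(.data$fgcm_ng_g))
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, samples$individual_id)
    if (length(missing_ids) > 0) {
      abort(paste0("no hormone samples for individual(s): ",
                   paste(missing_ids, collapse = ", ")),
            class = "behavsyn_empty_data_error")
    }
    samples <- dplyr::filter(samples, .data$individual_id %in% individuals)
  }
  if (nrow(samples) == 0) {
    abort("no hormone samples available", class = "behavsyn_empty_data_error")
  }
  out <- samples |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(as.numeric(.data$collection_date -
                               min(.data$collection_date)) < window_days) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      baseline_fgcm = mean(.data$fgcm_ng_g),
      .groups = "drop"
    )
  if (!is.null(individuals)) {
    out <- out[match(individuals, out$individual_id), ]
  }
  out
}
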