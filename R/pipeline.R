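#' Run the captive behavioural-syndrome pipeline
#'
#' Executes the full captive analysis on a study bundle (real or from
#' [sim_captive_study()]): trial-level metric scoring, the repeatability
#' gate, collinearity-gated composite axes, and the hormone-behaviour
#' association scan.
#'
#' Stages:
#' \enumerate{
#'   \item Problem-solving (MAB): per-trial persistence and inverse
#'     inhibitory control, first-exposure neophobia latency and
#'     exploratory diversity, phase outcomes and the standardized learning
#'     rate.
#'   \item Spatial task (RDT): per-trial pick count, working-memory
#'     errors, learned-location visit ratio and stay duration, accuracy,
#'     locations visited; per-individual trials-to-learn and delayed
#'     fixation trials (censored values are set to the phase length so
#'     non-learners stay in the composite).
#'   \item Repeatability gate on the repeated trial-level metrics; only
#'     significantly repeatable metrics are averaged into individual
#'     scores.
#'   \item Collinearity gate (`|rho| > threshold`) and correlation-matrix
#'     PCA per paradigm. The reactive axis is the component of the cluster
#'     containing neophobia (oriented so its neophobia loading is
#'     positive); learning impediment the cluster containing
#'     trials-to-learn; exploratory adaptiveness the cluster containing
#'     accuracy. When a gate leaves the anchor variable unclustered the
#'     standardized anchor itself carries the axis, with a warning.
#'   \item Association scan: impediment ~ learning rate, reactive ~ fGCM,
#'     adaptiveness ~ reactive, adaptiveness ~ fGCM, cross-phase trials to
#'     criterion ~ fGCM, learning rate ~ fGCM; assembled into a signed
#'     network.
#' }
#'
#' @param bundle A `study_bundle` with captive tables (`individuals`,
#'   `hormones`, `mab`, `rdt`, `sp`).
#' @param alpha Significance level for the repeatability gate and the
#'   network (default 0.05).
#' @param threshold Collinearity gate (default 0.7).
#' @param n_boot Bootstrap replicates for ICC intervals in the screen
#'   (default 0 = none).
#' @param seed Seed for the bootstrap.
#' @return An object of class `captive_run`: `scores` (one row per
#'   individual: metrics, axes, baseline fGCM), `repeatability` (screen
#'   tables), `axes` (named `axis_fit` list), `associations`, `network`.
#' @export
run_captive <- function(bundle, alpha = 0.05, threshold = 0.7, n_boot = 0,
                        seed = 1) {
  for (part in c("individuals", "mab", "rdt", "sp")) {
    if (is.null(bundle[[part]])) {
      abort(paste0("bundle lacks captive component '", part, "'"),
            class = "behavsyn_validation_error")
    }
  }
  mab <- .captive_mab_stage(bundle, alpha, n_boot, seed)
  rdt <- .captive_rdt_stage(bundle, alpha, n_boot, seed)
  sp <- .captive_sp_stage(bundle)

  scores <- bundle$individuals["individual_id"] |>
    dplyr::left_join(mab$scores, by = "individual_id") |>
    dplyr::left_join(rdt$scores, by = "individual_id") |>
    dplyr::left_join(sp, by = "individual_id")

  if (!is.null(bundle$hormones)) {
    base <- baseline_fgcm(bundle$hormones)
    scores <- dplyr::left_join(
      scores, dplyr::rename(base[c("individual_id", "baseline_fgcm")],
                            fgcm_ng_g = "baseline_fgcm"),
      by = "individual_id")
  }

  axes <- list()
  scores <- .attach_axis(scores, axes, mab$gate_vars, "neophobia",
                         "reactive", threshold)
  axes <- attr(scores, "axes")
  scores <- .attach_axis(scores, axes, rdt$learning_vars, "trials_to_learn",
                         "learning_impediment", threshold)
  axes <- attr(scores, "axes")
  scores <- .attach_axis(scores, axes, rdt$personality_vars, "accuracy",
                         "exploratory_adaptiveness", threshold)
  axes <- attr(scores, "axes")
  attr(scores, "axes") <- NULL

  associations <- NULL
  network <- NULL
  if (!is.null(bundle$hormones)) {
    plan <- tibble::tibble(
      response = c("learning_impediment", "reactive",
                   "exploratory_adaptiveness", "exploratory_adaptiveness",
                   "drs_cross", "learning_rate"),
      predictor = c("learning_rate", "fgcm_ng_g", "reactive", "fgcm_ng_g",
                    "fgcm_ng_g", "fgcm_ng_g")
    )
    associations <- assoc_scan(scores, plan)
    network <- association_network(associations, alpha = alpha)
  } else {
    warn("bundle has no hormone samples; association stage skipped")
  }

  structure(list(
    scores = scores,
    repeatability = list(mab = mab$screen, rdt = rdt$screen),
    axes = axes, associations = associations, network = network,
    alpha = alpha, threshold = threshold, seed = seed
  ), class = "captive_run")
}

.captive_mab_stage <- function(bundle, alpha, n_boot, seed) {
  events <- bundle$mab$events
  trials <- bundle$mab$trials
  blocked <- bundle$mab$blocked
  test_phases <- blocked$phase[lengths(blocked$blocked) > 0]

  blocked_map <- setNames(blocked$blocked, blocked$phase)
  # single grouped pass over the events; same arithmetic as the per-trial
  # operations (held together by a consistency test)
  per_trial <- events |>
    dplyr::filter(.data$phase != "familiarization") |>
    dplyr::group_by(.data$individual_id, .data$phase, .data$trial_index) |>
    dplyr::summarise(
      interact_s = {
        i <- .data$behaviour_code == "interact"
        interval_union_length(.data$start_s[i], .data$end_s[i])
      },
      explore_s = {
        i <- .data$behaviour_code == "explore"
        interval_union_length(.data$start_s[i], .data$end_s[i])
      },
      blocked_s = {
        bl <- blocked_map[[dplyr::cur_group()$phase]]
        i <- .data$behaviour_code == "explore" & .data$target %in% bl
        if (length(bl) == 0) NA_real_
        else interval_union_length(.data$start_s[i], .data$end_s[i])
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(trials, by = c("individual_id", "phase",
                                    "trial_index")) |>
    dplyr::mutate(
      persistence = pmin(1, .data$interact_s / .data$duration_s),
      inhibitory = dplyr::if_else(
        is.na(.data$blocked_s), NA_real_,
        dplyr::if_else(.data$explore_s > 0,
                       pmin(1, .data$blocked_s / .data$explore_s), 0)),
      trial_seq = .data$trial_index
    )

  screen <- repeatability_filter(
    per_trial, c("persistence", "inhibitory"), fixed = ~trial_seq,
    alpha = alpha, n_boot = n_boot, seed = seed)

  first_fam <- events |>
    dplyr::filter(.data$phase == "familiarization", .data$trial_index == 1)
  fam_dur <- trials |>
    dplyr::filter(.data$phase == "familiarization", .data$trial_index == 1)
  one_shot <- first_fam |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      dur <- fam_dur$duration_s[fam_dur$individual_id == key$individual_id][1]
      tibble::tibble(
        neophobia = as.numeric(
          mab_neophobia(d, dur, contact_codes = "contact")),
        exploratory_diversity = mab_exploratory_diversity(
          d[d$behaviour_code != "contact", ])
      )
    }) |>
    dplyr::ungroup()

  lr <- mab_learning_rate(
    dplyr::filter(trials, .data$phase != "familiarization"))
  completed <- trials |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(trials_completed = dplyr::n(), .groups = "drop")

  scores <- screen$scores |>
    dplyr::full_join(one_shot, by = "individual_id") |>
    dplyr::left_join(lr[c("individual_id", "learning_rate")],
                     by = "individual_id") |>
    dplyr::left_join(completed, by = "individual_id")
  list(scores = scores, screen = screen,
       gate_vars = intersect(
         c("neophobia", "persistence", "inhibitory",
           "exploratory_diversity"), names(scores)))
}

.captive_rdt_stage <- function(bundle, alpha, n_boot, seed) {
  scored <- rdt_score_table(bundle$rdt$visits,
                            bundle$rdt$learned_location %||% 3)
  per_trial <- scored$trials |>
    dplyr::mutate(trial_seq = .data$trial_index)
  fixed_trials <- dplyr::filter(per_trial, .data$phase == "fixed")
  depl_trials <- dplyr::filter(per_trial, .data$phase == "depletion")

  screen_fixed <- repeatability_filter(
    fixed_trials, "pick_count", fixed = ~trial_seq, alpha = alpha,
    n_boot = n_boot, seed = seed)
  screen_depl <- repeatability_filter(
    depl_trials, c("wme", "llvr", "llsd", "accuracy", "tlv"),
    fixed = ~trial_seq, alpha = alpha, n_boot = n_boot, seed = seed)
  screen <- list(fixed = screen_fixed, depletion = screen_depl)

  n_depl <- max(depl_trials$trial_index)
  learning <- scored$individuals |>
    dplyr::mutate(
      # censored learners/disengagers score the phase length + 1 / length
      trials_to_learn = ifelse(is.na(.data$trials_to_learn), 21L,
                               .data$trials_to_learn),
      dft = ifelse(is.na(.data$dft), n_depl, .data$dft)
    )

  scores <- screen_fixed$scores |>
    dplyr::full_join(screen_depl$scores, by = "individual_id") |>
    dplyr::full_join(learning[c("individual_id", "trials_to_learn", "dft")],
                     by = "individual_id")
  list(
    scores = scores, screen = screen,
    learning_vars = intersect(c("pick_count", "trials_to_learn", "dft",
                                "wme"), names(scores)),
    personality_vars = intersect(c("llvr", "llsd", "accuracy", "tlv"),
                                 names(scores))
  )
}

.captive_sp_stage <- function(bundle) {
  drs <- bundle$sp$trials |>
    dplyr::group_by(.data$individual_id, .data$phase) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::summarise(drs = sp_drs(.data$success), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "drs",
                       names_prefix = "drs_")
  hand <- bundle$sp$pulls |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(~ handedness(.x$forelimb)) |>
    dplyr::ungroup() |>
    dplyr::select("individual_id", "hi", "hi_z", "hand_label")
  dplyr::full_join(drs, hand, by = "individual_id")
}

# gate the candidate variables and extract the axis anchored at anchor_var
.attach_axis <- function(scores, axes, vars, anchor_var, axis_name,
                         threshold) {
  vars <- vars[vapply(scores[vars], function(x) sum(!is.na(x)) >= 3 &&
                        sd(x, na.rm = TRUE) > 0, logical(1))]
  if (!anchor_var %in% vars) {
    abort(paste0("anchor variable ", anchor_var, " unavailable for axis ",
                 axis_name), class = "behavsyn_validation_error")
  }
  gate <- collinearity_gate(spearman_matrix(scores, vars), threshold)
  cluster_vars <- gate$variable[gate$cluster ==
                                  gate$cluster[gate$variable == anchor_var]]
  if (length(cluster_vars) >= 2) {
    ax <- pca_axis(scores, cluster_vars, orient_var = anchor_var,
                   axis_name = axis_name)
    axes[[axis_name]] <- ax
    scores <- dplyr::left_join(scores, ax$scores, by = "individual_id")
  } else {
    warn(paste0("collinearity gate leaves ", anchor_var,
                " unclustered; using standardized ", anchor_var, " as ",
                axis_name))
    scores[[axis_name]] <- as.numeric(scale(scores[[anchor_var]]))
    axes[[axis_name]] <- NULL
  }
  attr(scores, "axes") <- axes
  scores
}

#' @export
print.captive_run <- function(x, ...) {
  cat("Captive syndrome pipeline:", nrow(x$scores), "individuals\n")
  if (!is.null(x$associations)) {
    cat("associations:\n")
    print(x$associations[c("response", "predictor", "beta", "p", "n")])
  }
  invisible(x)
}

#' Run the field pipeline
#'
#' Genetics to hormones: per-locus diversity and identification statistics,
#' PIC-ranked panel selection to the target sibling probability of
#' identity, multilocus sample-to-individual matching, shortest surface
#' distances over the DEM, and the within-/between-individual fGCM-distance
#' models.
#'
#' @param bundle A `study_bundle` with field tables (`genotypes`,
#'   `samples` with coordinates and `fgcm_ng_g`, `dem`, `disturbance`).
#'   When `samples` already carries `ssd_km` and no DEM is supplied the
#'   precomputed distances are used.
#' @param target_pid_sib Panel target (default 0.01).
#' @param max_mismatch_loci Matching tolerance (default 0).
#' @param min_samples Repeated-sample threshold for within-individual
#'   models (default 3).
#' @param step Profile sampling step in metres (default: DEM cell size).
#' @return An object of class `field_run`: `locus_stats`, `panel`,
#'   `matches`, `samples` (with individual assignment and SSD), `intra`,
#'   `inter`.
#' @export
run_field <- function(bundle, target_pid_sib = 0.01, max_mismatch_loci = 0,
                      min_samples = 3, step = NULL) {
  if (is.null(bundle$genotypes) || nrow(bundle$genotypes) == 0) {
    abort("field bundle has no genotypes; aborting at the genetics stage",
          class = "behavsyn_validation_error")
  }
  stats_tab <- locus_stats(bundle$genotypes)
  panel <- select_panel(stats_tab, target_pid_sib)
  matches <- match_individuals(bundle$genotypes, panel = panel$loci,
                               max_mismatch_loci = max_mismatch_loci)
  samples <- dplyr::left_join(bundle$samples, matches, by = "sample_id")
  if (!is.null(bundle$dem)) {
    step <- step %||% bundle$dem$cell_size
    ssd_tab <- ssd(bundle$dem, samples, bundle$disturbance, step = step)
    samples$ssd_km <- ssd_tab$ssd_km
  } else if (!"ssd_km" %in% names(samples)) {
    abort("no DEM and no precomputed ssd_km; cannot run distance models",
          class = "behavsyn_validation_error")
  }
  intra <- intra_individual_assoc(samples, id = "individual",
                                  min_samples = min_samples)
  inter <- inter_individual_assoc(samples, id = "individual")
  structure(list(locus_stats = stats_tab, panel = panel, matches = matches,
                 samples = samples, intra = intra, inter = inter),
            class = "field_run")
}

#' @export
print.field_run <- function(x, ...) {
  cat("Field pipeline:", nrow(x$matches), "samples ->",
      attr(x$matches, "n_individuals"), "individuals;",
      length(x$panel$loci), "panel loci (PIDsib",
      format(x$panel$pid_sib, digits = 3), ")\n")
  cat("inter-individual slope:", format(x$inter$beta, digits = 4),
      " (n =", x$inter$n, ")\n")
  invisible(x)
}

#' Reanalyse the packaged panda study tables
#'
#' Recomputes, from the packaged captive and wild tables alone, the
#' headline statistics of the study the package ships: the six captive
#' ordinary-least-squares slopes among composite axes, learning rate,
#' cross-phase trials-to-criterion and baseline fGCM; the signed-rank
#' comparison of the two string-pulling phases; the within-individual and
#' between-individual fGCM-distance slopes for the wild cohort; and the
#' collinearity-gate partitions of the three published correlation
#' matrices.
#'
#' @param alpha Network significance level (default 0.05).
#' @return An object of class `study_reanalysis`: `associations` (seven
#'   captive rows including the Wilcoxon entry), `wilcoxon`, `intra`,
#'   `inter`, `gates` (named list of partition tibbles), `network`.
#' @examples
#' reproduce_study()
#' @export
reproduce_study <- function(alpha = 0.05) {
  cap <- panda_captive()
  plan <- tibble::tibble(
    response = c("learning_impediment", "reactive",
                 "exploratory_adaptiveness", "exploratory_adaptiveness",
                 "drs_cross", "learning_rate"),
    predictor = c("learning_rate", "fgcm_ng_g", "reactive", "fgcm_ng_g",
                  "fgcm_ng_g", "fgcm_ng_g")
  )
  associations <- assoc_scan(cap, plan)
  wil <- wilcoxon_signed_rank(cap$drs_cross, cap$drs_parallel)
  wild <- panda_wild()
  intra <- intra_individual_assoc(wild)
  inter <- inter_individual_assoc(wild)
  gates <- purrr::map(panda_cor_matrices(), collinearity_gate)
  structure(list(associations = associations, wilcoxon = wil,
                 intra = intra, inter = inter, gates = gates,
                 network = association_network(associations, alpha)),
            class = "study_reanalysis")
}

#' @export
print.study_reanalysis <- function(x, ...) {
  cat("Captive association scan (packaged tables):\n")
  print(as.data.frame(
    x$associations[c("response", "predictor", "beta", "p", "n")]),
    digits = 4)
  cat("\nString-pulling phases, signed-rank: W =", x$wilcoxon$w,
      " p =", format(x$wilcoxon$p, digits = 3), "\n")
  cat("\nWild fGCM ~ surface distance:\n")
  cat("  within-individual:", paste0(
    x$intra$individual_id, ": beta = ",
    format(x$intra$beta, digits = 4), " (n = ", x$intra$n, ")",
    collapse = "; "), "\n")
  cat("  between-individual: beta =", format(x$inter$beta, digits = 4),
      " (n =", x$inter$n, ")\n")
  cat("\nCollinearity-gate partitions:\n")
  for (nm in names(x$gates)) {
    g <- x$gates[[nm]]
    cl <- split(g$variable, g$cluster)
    cat("  ", nm, ": ",
        paste(vapply(cl, function(v) paste0("{", paste(v, collapse = ", "),
                                            "}"), character(1)),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname reproduce_study
#' @param x A `study_reanalysis` object.
#' @param ... Unused.
#' @export
tidy.study_reanalysis <- function(x, ...) {
  dplyr::bind_rows(
    x$associations[c("response", "predictor", "beta", "p", "n")],
    tibble::tibble(response = "drs_cross", predictor = "drs_parallel",
                   beta = NA_real_, p = x$wilcoxon$p, n = x$wilcoxon$n,
                   statistic = x$wilcoxon$w, test = "wilcoxon"),
    dplyr::mutate(x$intra[c("beta", "p", "n")],
                  response = "fgcm_ng_g", predictor = "ssd_km",
                  test = paste0("intra:", x$intra$individual_id)),
    dplyr::mutate(x$inter[c("beta", "p", "n")],
                  response = "mean_fgcm", predictor = "mean_ssd",
                  test = "inter")
  )
}
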