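#' Parameters for the captive-study generator
#'
#' Defaults mirror the captive study design the package analyses: 12
#' subjects, a five-sample baseline hormone window, a familiarization
#' stage plus four sequentially blocked problem-solving phases, a 12-20
#' trial fixed-reward spatial phase followed by 15 depletion trials, and
#' two 150-trial string-pulling phases. Two standard-normal latent traits
#' drive the between-individual structure: a coping-style trait `c`
#' (reactive pole = high baseline fGCM, high neophobia, low persistence,
#' poor inhibition, dwelling on the learned location, inefficient search,
#' left-forelimb bias) and a learning trait `l` (steeper decline of
#' exploration time, faster spatial rule acquisition, quicker
#' disengagement from a depleted location).
#'
#' Gaussian trial-level metrics are parameterized by residual SD, a target
#' intraclass correlation and a loading on `c`; the loading consumes part
#' of the among-individual variance implied by the ICC, and an infeasible
#' combination (loading^2 exceeding that variance) is an error.
#'
#' @param n_individuals Cohort size (default 12).
#' @param latent_sd SD of both latent traits (default 1).
#' @param fgcm_intercept,fgcm_slope_on_c Baseline fGCM mean structure in
#'   ng/g: per-individual mean `intercept + slope * c`, spanning roughly
#'   165-490 ng/g at the defaults (330, 80).
#' @param fgcm_sample_sd Within-individual SD of the five baseline samples
#'   (default 20 ng/g).
#' @param n_hormone_samples Samples per individual in the baseline window
#'   (default 5, one per day).
#' @param handedness_link Logit shift of P(left forelimb) per unit `c`
#'   (default 1.2).
#' @param trials_per_phase Cap on problem-solving trials per phase
#'   (default 10).
#' @param trial_duration_s Problem-solving trial length (default 300 s).
#' @param n_depletion_trials Depletion-phase trials (default 15).
#' @param pulls_per_phase Scored forelimb uses per string-pulling phase
#'   (default 30).
#' @param sp_max_trials String-pulling phase cap (default 150).
#' @param couple Set `FALSE` to zero every latent loading and link (null
#'   structure for type-I-error checks).
#' @param persistence,inhibitory Gaussian trial-metric specs:
#'   `list(mu, sd_res, icc, load)`.
#' @return A parameter list for [sim_captive_study()].
#' @export
sim_captive_params <- function(n_individuals = 12, latent_sd = 1,
                               fgcm_intercept = 330, fgcm_slope_on_c = 80,
                               fgcm_sample_sd = 20, n_hormone_samples = 5,
                               handedness_link = 1.2, trials_per_phase = 10,
                               trial_duration_s = 300,
                               n_depletion_trials = 15,
                               pulls_per_phase = 30, sp_max_trials = 150,
                               couple = TRUE,
                               persistence = list(mu = 0.5, sd_res = 0.1,
                                                  icc = 0.4, load = -0.075),
                               inhibitory = list(mu = 0.35, sd_res = 0.1,
                                                 icc = 0.4, load = 0.075)) {
  as.list(environment())
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# among-individual intercept SD left after the latent loading claims its
# share of the ICC-implied variance; infeasible combinations error
.residual_intercept_sd <- function(spec, latent_sd, what) {
  v_ind <- spec$icc / (1 - spec$icc) * spec$sd_res^2
  v_u <- v_ind - spec$load^2 * latent_sd^2
  if (v_u < 0) {
    abort(paste0("infeasible icc/loading for ", what,
                 ": implied intercept variance ", format(v_u, digits = 3)),
          class = "behavsyn_validation_error")
  }
  sqrt(v_u)
}

#' Generate a complete captive study bundle
#'
#' Draws latent traits per individual, then emits every input table the
#' captive pipeline consumes, in the exact event-table formats the readers
#' validate: individual profiles, baseline hormone samples, problem-solving
#' (MAB) events with per-trial durations and phase-wise blocked solutions,
#' resource-depletion bowl-visit events, and string-pulling success and
#' forelimb sequences. The latent truth (`c`, `l` per individual) is
#' returned alongside for recovery checks.
#'
#' @param params A [sim_captive_params()] list.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @return A `study_bundle` list: `individuals`, `hormones`, `mab`
#'   (`events`, `trials`, `blocked`), `rdt` (`visits`), `sp` (`trials`,
#'   `pulls`), `latent`, `params`, `seed`.
#' @export
sim_captive_study <- function(params = sim_captive_params(), seed = 1) {
  p <- params
  k <- if (p$couple) 1 else 0
  withr::with_seed(seed, {
    n <- p$n_individuals
    ids <- sprintf("P%02d", seq_len(n))
    cc <- rnorm(n, 0, p$latent_sd)
    ll <- rnorm(n, 0, p$latent_sd)

    individuals <- tibble::tibble(
      individual_id = ids,
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
      age_years = round(runif(n, 2, 16)),
      body_mass_kg = round(runif(n, 60, 135))
    )

    # baseline hormone window: one sample per day
    mean_fgcm <- p$fgcm_intercept + k * p$fgcm_slope_on_c * cc +
      rnorm(n, 0, 25)
    mean_fgcm <- .clip(mean_fgcm, 20, Inf)
    hormones <- purrr::map(seq_len(n), function(i) {
      vals <- rnorm(p$n_hormone_samples, mean_fgcm[i], p$fgcm_sample_sd)
      while (any(vals <= 0)) {           # positive truncation by resampling
        vals[vals <= 0] <- rnorm(sum(vals <= 0), mean_fgcm[i],
                                 p$fgcm_sample_sd)
      }
      tibble::tibble(
        sample_id = sprintf("%s-H%d", ids[i], seq_len(p$n_hormone_samples)),
        individual_id = ids[i],
        collection_date = as.Date("2023-07-26") +
          seq_len(p$n_hormone_samples) - 1,
        fgcm_ng_g = vals, context = "captive"
      )
    }) |> purrr::list_rbind()

    mab <- .sim_mab(ids, cc, ll, p, k)
    rdt <- .sim_rdt(ids, cc, ll, p, k)
    sp <- .sim_sp(ids, cc, ll, p, k)

    structure(list(
      individuals = individuals, hormones = hormones,
      mab = mab, rdt = rdt, sp = sp,
      latent = tibble::tibble(individual_id = ids, c = cc, l = ll),
      params = p, seed = seed
    ), class = "study_bundle")
  })
}

.sim_mab <- function(ids, cc, ll, p, k) {
  n <- length(ids)
  D <- p$trial_duration_s
  solutions <- c("push", "pull", "slide", "drawer")
  sd_u_pers <- .residual_intercept_sd(p$persistence, p$latent_sd,
                                      "persistence")
  sd_u_inh <- .residual_intercept_sd(p$inhibitory, p$latent_sd, "inhibitory")
  u_pers <- rnorm(n, 0, sd_u_pers)
  u_inh <- rnorm(n, 0, sd_u_inh)
  u_expl <- rnorm(n, 0, 25)
  slope_expl <- -(7 + k * 3.5 * ll + rnorm(n, 0, 0.8))
  neo <- .clip(60 + k * 25 * cc + rnorm(n, 0, 8), 1, D - 10)
  diversity <- 1 + stats::rpois(n, exp(1.3 - k * 0.15 * cc))
  codes_pool <- c("sniff", "paw", "bite", "lick", "push_at", "climb",
                  "nose", "pull_at")

  events <- list()
  trials <- list()
  for (i in seq_len(n)) {
    # familiarization: one scored first-exposure trial
    kdiv <- min(diversity[i], length(codes_pool))
    contact <- neo[i]
    ev_fam <- tibble::tibble(
      individual_id = ids[i], paradigm = "MAB", phase = "familiarization",
      trial_index = 1L,
      behaviour_code = c("contact", sample(codes_pool, kdiv)),
      target = "box",
      start_s = c(contact, sort(runif(kdiv, contact, D - 5))),
      forelimb = "none", success = NA
    )
    ev_fam$end_s <- .clip(ev_fam$start_s + runif(kdiv + 1, 1, 8), 0, D)
    events[[length(events) + 1]] <- ev_fam
    trials[[length(trials) + 1]] <- tibble::tibble(
      individual_id = ids[i], phase = "familiarization", trial_index = 1L,
      duration_s = D, success = NA, exploration_s = NA_real_
    )

    for (ph in seq_along(solutions)) {
      phase <- paste0("phase", ph)
      blocked <- if (ph == 1) character() else solutions[seq_len(ph - 1)]
      ok <- logical(0)
      succ <- 0L
      fails <- 0L
      while (length(ok) < p$trials_per_phase && succ < 3 && fails < 3) {
        t <- length(ok) + 1L
        hit <- runif(1) < stats::plogis(-0.3 + 0.6 * t + k * 0.4 * ll[i])
        if (hit) { succ <- succ + 1L; fails <- 0L } else fails <- fails + 1L
        ok <- c(ok, hit)
      }
      nt <- length(ok)
      tt <- seq_len(nt)
      pers <- .clip(p$persistence$mu + k * p$persistence$load * cc[i] +
                      u_pers[i] + rnorm(nt, 0, p$persistence$sd_res),
                    0.02, 0.98)
      expl <- .clip(150 + u_expl[i] + slope_expl[i] * (tt - 1) +
                      rnorm(nt, 0, 10), 5, D)
      if (length(blocked) > 0) {
        inh <- .clip(p$inhibitory$mu + k * p$inhibitory$load * cc[i] +
                       u_inh[i] + rnorm(nt, 0, p$inhibitory$sd_res),
                     0.02, 0.98)
        ev <- tibble::tibble(
          individual_id = ids[i], paradigm = "MAB", phase = phase,
          trial_index = rep(tt, 3),
          behaviour_code = rep(c("interact", "explore", "explore"),
                               each = nt),
          target = rep(c("box", blocked[1], solutions[ph]), each = nt),
          start_s = c(rep(0, 2 * nt), inh * expl),
          end_s = c(pers * D, inh * expl, expl),
          forelimb = "none",
          success = c(ok, rep(NA, 2 * nt))
        )
      } else {
        ev <- tibble::tibble(
          individual_id = ids[i], paradigm = "MAB", phase = phase,
          trial_index = rep(tt, 2),
          behaviour_code = rep(c("interact", "explore"), each = nt),
          target = rep(c("box", solutions[ph]), each = nt),
          start_s = 0,
          end_s = c(pers * D, expl),
          forelimb = "none",
          success = c(ok, rep(NA, nt))
        )
      }
      events[[length(events) + 1]] <- ev
      trials[[length(trials) + 1]] <- tibble::tibble(
        individual_id = ids[i], phase = phase, trial_index = tt,
        duration_s = D, success = ok, exploration_s = expl
      )
    }
  }
  list(
    events = validate_trial_events(
      purrr::list_rbind(events)[.event_columns]
    ),
    trials = purrr::list_rbind(trials),
    blocked = tibble::tibble(
      phase = paste0("phase", seq_along(solutions)),
      blocked = purrr::map(seq_along(solutions),
                           ~ solutions[seq_len(.x - 1)])
    )
  )
}

.sim_rdt <- function(ids, cc, ll, p, k) {
  n <- length(ids)
  learned_loc <- 3L
  others <- setdiff(1:6, learned_loc)
  m <- stats::plogis(-1.2 + k * 1.2 * ll)      # spatial rule strength
  w <- stats::plogis(-0.2 + k * 0.8 * cc)      # learned-location dwelling
  acc <- stats::plogis(0.8 - k * 1.4 * cc)     # search efficiency
  fade <- pmax(0.45 + k * 0.3 * ll, 0.05)      # disengagement speed
  visits <- list()
  for (i in seq_len(n)) {
    acc_phase <- character(0)
    acc_trial <- integer(0)
    acc_bowl <- integer(0)
    acc_dur <- numeric(0)
    acc_rew <- logical(0)
    add <- function(phase, t, bowls, durs, rew) {
      acc_phase <<- c(acc_phase, rep(phase, length(bowls)))
      acc_trial <<- c(acc_trial, rep(t, length(bowls)))
      acc_bowl <<- c(acc_bowl, as.integer(bowls))
      acc_dur <<- c(acc_dur, durs)
      acc_rew <<- c(acc_rew, rew)
    }
    # fixed-reward phase: run to the learning criterion, 12-20 trials
    picks_hist <- integer()
    t <- 0L
    repeat {
      t <- t + 1L
      p_hit <- stats::plogis(stats::qlogis(m[i]) + 0.35 * (t - 1))
      if (runif(1) < p_hit) {
        bowls <- learned_loc
      } else {
        extra <- min(1 + stats::rgeom(1, 0.35 + 0.45 * m[i]), 5)
        wrong <- sample(others, extra, replace = extra > length(others))
        if (extra >= 2 && runif(1) < 0.25) wrong[extra] <- wrong[1] # revisit
        bowls <- c(wrong, learned_loc)
      }
      nb <- length(bowls)
      durs <- runif(nb, 2, 8)
      durs[nb] <- 4 + 10 * w[i] + runif(1, 0, 2)
      add("fixed", t, bowls, durs, c(rep(FALSE, nb - 1), TRUE))
      picks_hist <- c(picks_hist, nb)
      crit <- !is.na(.first_run_end(picks_hist <= 2, 3))
      if ((crit && t >= 12) || t >= 20) break
    }
    # depletion phase
    for (t in seq_len(p$n_depletion_trials)) {
      pi_learned <- stats::plogis(1.2 - fade[i] * (t - 1))
      bowls <- integer()
      durs <- numeric()
      if (runif(1) < pi_learned) {
        bowls <- learned_loc
        durs <- 3 + 10 * w[i] + runif(1, 0, 2)
      }
      baited <- sample(others, 3)
      unbaited <- setdiff(others, baited)
      # wasted picks before the first baited bowl scale with inefficiency
      waste <- stats::rbinom(1, 4, 0.8 * (1 - acc[i]))
      seq_bowls <- c(if (waste > 0) sample(unbaited, waste, replace = TRUE),
                     sample(baited, 1))
      bowls <- c(bowls, seq_bowls)
      durs <- c(durs, runif(length(seq_bowls), 2, 6))
      rew <- bowls %in% baited & !duplicated(bowls)
      rew[bowls == learned_loc] <- FALSE
      add("depletion", t, bowls, durs, rew)
    }
    visits[[i]] <- tibble::tibble(
      individual_id = ids[i], phase = acc_phase, trial_index = acc_trial,
      bowl = acc_bowl, duration_s = acc_dur, rewarded = acc_rew
    )
  }
  list(visits = purrr::list_rbind(visits), learned_location = learned_loc)
}

.sim_sp <- function(ids, cc, ll, p, k) {
  n <- length(ids)
  p_par <- stats::plogis(1.5 + k * (0.3 * ll - 0.15 * cc))
  p_cross <- stats::plogis(1.1 - k * 0.5 * cc)
  p_left <- stats::plogis(0.4 + k * p$handedness_link * cc)
  trials <- purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      individual_id = ids[i],
      phase = rep(c("parallel", "cross"), each = p$sp_max_trials),
      trial_index = rep(seq_len(p$sp_max_trials), 2),
      success = c(runif(p$sp_max_trials) < p_par[i],
                  runif(p$sp_max_trials) < p_cross[i])
    )
  }) |> purrr::list_rbind()
  pulls <- purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      individual_id = ids[i],
      phase = rep(c("parallel", "cross"), each = p$pulls_per_phase),
      pull_index = rep(seq_len(p$pulls_per_phase), 2),
      forelimb = ifelse(runif(2 * p$pulls_per_phase) < p_left[i], "L", "R")
    )
  }) |> purrr::list_rbind()
  list(trials = trials, pulls = pulls)
}

#' Gaussian trial-level trait with a known intraclass correlation
#'
#' Minimal generator for repeatability calibration: `y_ij = mu + b_i +
#' e_ij` with `b_i ~ N(0, v_ind)`, `e_ij ~ N(0, v_res)` and
#' `v_ind / (v_ind + v_res) = icc`.
#'
#' @param n_individuals,n_trials Design size.
#' @param icc Target intraclass correlation in `[0, 1)`.
#' @param mu Grand mean.
#' @param total_var Total variance `v_ind + v_res` (default 1).
#' @param trend Linear fixed effect of trial index (default 0).
#' @param seed Integer seed.
#' @return Tibble `individual_id`, `trial_index`, `value`.
#' @export
sim_trait_trials <- function(n_individuals, n_trials, icc, mu = 0,
                             total_var = 1, trend = 0, seed = 1) {
  stopifnot(icc >= 0, icc < 1)
  withr::with_seed(seed, {
    b <- rnorm(n_individuals, 0, sqrt(icc * total_var))
    tidyr::expand_grid(individual_id = sprintf("I%03d",
                                               seq_len(n_individuals)),
                       trial_index = seq_len(n_trials)) |>
      dplyr::mutate(value = mu + b[as.integer(factor(.data$individual_id))] +
                      trend * .data$trial_index +
                      rnorm(dplyr::n(), 0, sqrt((1 - icc) * total_var)))
  })
}

#' Parameters for the field-study generator
#'
#' Defaults mirror the wild component: nine individuals behind 18 faecal
#' samples (one individual sampled seven times), eight microsatellite loci
#' under Hardy-Weinberg equilibrium, a 30 m smoothed random terrain, a
#' linear disturbance feature, and opposing hormone-disturbance structure:
#' a positive between-individual slope of mean fGCM on mean surface
#' distance with a negative within-individual slope around each
#' individual's own baseline.
#'
#' @param n_individuals Number of wild individuals (default 9).
#' @param samples_per_individual Integer vector of per-individual sample
#'   counts (default `c(7, 2, 2, 2, 1, 1, 1, 1, 1)`, 18 samples).
#' @param n_loci,alleles_per_locus Microsatellite panel shape (8, 6).
#' @param allele_conc Dirichlet concentration for allele frequencies
#'   (default 1).
#' @param dem_cells,cell_size,dem_relief Terrain: grid side (cells), cell
#'   size (m), relief amplitude (m SD). The synthetic terrain is coarser
#'   (250 m cells over a 30 km extent) than a native 30 m DEM so that
#'   surface distances span the home-range kilometres over which the
#'   per-km hormone slopes act, at negligible cost.
#' @param sample_jitter_frac Within-individual scatter of sample
#'   locations, as a fraction of the grid extent (default 0.15, i.e. a
#'   few km of home-range spread).
#' @param inter_slope,intra_slope fGCM change per km of surface distance
#'   between individuals (+5) and within an individual (-4).
#' @param fgcm_intercept Wild fGCM level at zero distance (default 30
#'   ng/g).
#' @param fgcm_noise_sd Residual sample noise (default 8 ng/g).
#' @return A parameter list for [sim_field_study()].
#' @export
sim_field_params <- function(n_individuals = 9,
                             samples_per_individual = c(7, 2, 2, 2, 1, 1,
                                                        1, 1, 1),
                             n_loci = 8, alleles_per_locus = 6,
                             allele_conc = 1, dem_cells = 120,
                             cell_size = 250, dem_relief = 200,
                             sample_jitter_frac = 0.15,
                             inter_slope = 5, intra_slope = -4,
                             fgcm_intercept = 30, fgcm_noise_sd = 8) {
  stopifnot(length(samples_per_individual) == n_individuals)
  as.list(environment())
}

#' Generate a complete field study bundle
#'
#' Emits genotypes (Hardy-Weinberg draws from Dirichlet allele
#' frequencies, identical across each individual's samples), a smoothed
#' Gaussian random DEM, a disturbance point line, sample coordinates, the
#' realized shortest surface distances, and fGCM values built on those
#' realized distances with the configured between- and within-individual
#' slopes.
#'
#' @param params A [sim_field_params()] list.
#' @param seed Integer seed.
#' @return A `study_bundle` list: `genotypes` (long tibble over all
#'   samples), `samples` (coordinates + `ssd_km` + `fgcm_ng_g` +
#'   `true_individual`), `dem`, `disturbance`, `freqs` (true allele
#'   frequencies), `params`, `seed`.
#' @export
sim_field_study <- function(params = sim_field_params(), seed = 1) {
  p <- params
  withr::with_seed(seed, {
    inds <- LETTERS[seq_len(p$n_individuals)]
    # true allele frequencies and HWE genotypes per individual
    freqs <- purrr::map(seq_len(p$n_loci), function(l) {
      g <- stats::rgamma(p$alleles_per_locus, p$allele_conc)
      tibble::tibble(locus = sprintf("L%02d", l),
                     allele = 100 + 4 * seq_len(p$alleles_per_locus),
                     freq = g / sum(g))
    }) |> purrr::list_rbind()
    ind_geno <- tidyr::expand_grid(individual = inds,
                                   locus = unique(freqs$locus)) |>
      dplyr::rowwise() |>
      dplyr::mutate(pair = list(sort(sample(
        freqs$allele[freqs$locus == .data$locus], 2, replace = TRUE,
        prob = freqs$freq[freqs$locus == .data$locus]
      )))) |>
      dplyr::ungroup() |>
      dplyr::mutate(allele_1 = purrr::map_dbl(.data$pair, 1),
                    allele_2 = purrr::map_dbl(.data$pair, 2)) |>
      dplyr::select(-"pair")

    dem <- sim_dem(p$dem_cells, cell_size = p$cell_size,
                   relief = p$dem_relief,
                   seed = sample.int(2^31 - 1, 1))
    extent <- p$dem_cells * p$cell_size
    # disturbance: a "road" along the western margin
    road_x <- 2 * p$cell_size
    disturbance <- tibble::tibble(
      x = road_x,
      y = seq(p$cell_size, extent - p$cell_size, by = p$cell_size)
    )

    n_samp <- sum(p$samples_per_individual)
    ind_of_sample <- rep(inds, p$samples_per_individual)
    # individual centres at staggered distances from the road
    centre_d <- seq(0.15, 0.8, length.out = p$n_individuals) * extent
    centre_d <- sample(centre_d)
    xy <- purrr::map(seq_len(p$n_individuals), function(i) {
      m <- p$samples_per_individual[i]
      x <- .clip(road_x + centre_d[i] +
                   runif(m, -p$sample_jitter_frac,
                         p$sample_jitter_frac) * extent,
                 3 * p$cell_size, extent - 3 * p$cell_size)
      y <- runif(m, 0.15, 0.85) * extent
      tibble::tibble(x = x, y = y)
    }) |> purrr::list_rbind()
    samples <- tibble::tibble(
      sample_id = sprintf("W-%02d", seq_len(n_samp)),
      true_individual = ind_of_sample, x = xy$x, y = xy$y
    )
    ssd_tab <- ssd(dem, samples, disturbance, step = p$cell_size)
    samples$ssd_km <- ssd_tab$ssd_km
    samples <- samples |>
      dplyr::group_by(.data$true_individual) |>
      dplyr::mutate(mean_ssd = mean(.data$ssd_km)) |>
      dplyr::ungroup() |>
      dplyr::mutate(fgcm_ng_g = .clip(
        p$fgcm_intercept + p$inter_slope * .data$mean_ssd +
          p$intra_slope * (.data$ssd_km - .data$mean_ssd) +
          rnorm(n_samp, 0, p$fgcm_noise_sd), 0.5, Inf))
    genotypes <- samples |>
      dplyr::select("sample_id", individual = "true_individual") |>
      dplyr::left_join(ind_geno, by = "individual",
                       relationship = "many-to-many") |>
      dplyr::select("sample_id", "locus", "allele_1", "allele_2")
    structure(list(genotypes = genotypes, samples = samples, dem = dem,
                   disturbance = disturbance, freqs = freqs, params = p,
                   seed = seed),
              class = "study_bundle")
  })
}

#' Smoothed Gaussian random terrain
#'
#' White noise smoothed with a separable moving-average kernel, rescaled to
#' the requested relief SD and offset to a mountainous base elevation.
#' Smoothness guarantees well-behaved bilinear interpolation.
#'
#' @param n_cells Grid side length in cells.
#' @param cell_size Cell size in metres (default 30).
#' @param relief SD of the final elevation field (default 80 m).
#' @param base Mean elevation (default 2600 m).
#' @param smooth Kernel half-width in cells (default 6).
#' @param seed Integer seed.
#' @return A [dem_grid()].
#' @export
sim_dem <- function(n_cells, cell_size = 30, relief = 80, base = 2600,
                    smooth = 6, seed = 1) {
  withr::with_seed(seed, {
    pad <- 2 * smooth + 1
    z <- matrix(rnorm((n_cells + 2 * pad)^2), n_cells + 2 * pad)
    kern <- dnorm(seq(-smooth, smooth) / (smooth / 2))
    kern <- kern / sum(kern)
    z <- apply(z, 2, function(col) as.numeric(stats::filter(col, kern,
                                                            sides = 2)))
    z <- t(apply(z, 1, function(row) as.numeric(stats::filter(row, kern,
                                                              sides = 2))))
    z <- z[pad + seq_len(n_cells), pad + seq_len(n_cells)]
    z <- (z - mean(z)) / sd(z) * relief + base
    dem_grid(z, origin_x = 0, origin_y = 0, cell_size = cell_size)
  })
}
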