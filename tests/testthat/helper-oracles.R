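# Independent brute-force oracles used across the suite. Each is written
# as differently as possible from the implementation it checks.

# interval union by indicator on a fine grid (endpoints on a 0.01 lattice)
oracle_union_length <- function(start, end, step = 0.005) {
  if (length(start) == 0) return(0)
  grid <- seq(min(start), max(end), by = step)
  mids <- grid[-1] - step / 2
  covered <- rep(FALSE, length(mids))
  for (i in seq_along(start)) {
    covered <- covered | (mids > start[i] & mids < end[i])
  }
  sum(covered) * step
}

# step-through simulator for problem-solving phase termination
oracle_phase_outcome <- function(success) {
  successes <- 0
  consec_fail <- 0
  for (t in seq_along(success)) {
    if (success[t]) {
      successes <- successes + 1
      consec_fail <- 0
    } else {
      consec_fail <- consec_fail + 1
    }
    if (successes == 3) return(list(learned = TRUE, stop_at = t))
    if (consec_fail == 3) return(list(learned = FALSE, stop_at = t))
  }
  list(learned = FALSE, stop_at = length(success))
}

# exhaustive window scan for the string-pulling criterion
oracle_drs <- function(success, max_trials = 150) {
  s <- as.integer(success)[seq_len(min(length(success), max_trials))]
  for (t in 12:length(s)) {
    ok <- TRUE
    for (e in (t - 2):t) {
      if (sum(s[(e - 9):e]) < 8) { ok <- FALSE; break }
    }
    if (ok) return(t)
  }
  151L
}

# direct recount of the six spatial-task trial metrics
oracle_rdt <- function(bowl, rewarded, duration, learned) {
  n <- length(bowl)
  first_rew <- Inf
  for (i in seq_len(n)) if (rewarded[i]) { first_rew <- i; break }
  seen <- c()
  wme <- 0
  for (b in bowl) {
    if (b %in% seen) wme <- wme + 1
    seen <- c(seen, b)
  }
  list(
    pick_count = if (is.finite(first_rew)) first_rew else n,
    wme = wme,
    llvr = sum(bowl == learned) / n,
    llsd = sum(duration[bowl == learned]) / sum(duration),
    accuracy = 1 - sum(!rewarded) / n,
    tlv = length(unique(bowl))
  )
}

# balanced one-way ANOVA moment estimators (= REML on balanced designs)
oracle_anova_vc <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n0 <- length(y) / k
  gm <- tapply(y, g, mean)
  msb <- n0 * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - k)
  list(v_ind = max(0, (msb - msw) / n0), v_res = msw)
}

# genotype-sharing probability by exhaustive enumeration under HWE
oracle_pid_enum <- function(p) {
  k <- length(p)
  total <- 0
  for (i in 1:k) for (j in i:k) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + pg^2
  }
  total
}

# signed-rank exact two-sided p by full enumeration of sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# mean-matched synthetic per-sample hormone table for the packaged cohort
# (raw per-sample values are unpublished; only the means are constrained)
synthetic_hormone_samples <- function(captive = panda_captive()) {
  offsets <- c(-2, -1, 0, 1, 2) * 3.5
  purrr::map(seq_len(nrow(captive)), function(i) {
    tibble::tibble(
      sample_id = sprintf("C%02d-%d", i, 1:5),
      individual_id = captive$individual_id[i],
      collection_date = as.Date("2023-07-26") + 0:4,
      fgcm_ng_g = captive$fgcm_ng_g[i] + offsets,
      context = "captive"
    )
  }) |> purrr::list_rbind()
}
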