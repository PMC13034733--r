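#' Ordinary least-squares association between two traits
#'
#' Identity-link Gaussian GLM of `response` on `predictor`, optionally
#' adjusting for covariates. Complete cases only; the reported `n` is the
#' number of rows actually modelled, so printed sample sizes track
#' missingness in either trait.
#'
#' @param data Individual-level data frame.
#' @param response,predictor Column names (strings).
#' @param covariates Optional character vector of adjustment columns.
#' @return One-row tibble: `response`, `predictor`, `beta`, `se`, `t_stat`,
#'   `p`, `n`, `covariates`.
#' @examples
#' assoc_ols(panda_captive(), "learning_impediment", "learning_rate")
#' @export
assoc_ols <- function(data, response, predictor, covariates = NULL) {
  cols <- c(response, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "behavsyn_format_error")
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n <= length(cols)) {
    abort("too few complete cases for the requested model",
          class = "behavsyn_validation_error")
  }
  rhs <- paste(c(sprintf("`%s`", predictor),
                 sprintf("`%s`", covariates)), collapse = " + ")
  f <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
  fit <- lm(f, data = d)
  sm <- summary(fit)$coefficients
  if (qr(fit)$rank < length(coef(fit))) {
    abort("rank-deficient design in association model",
          class = "behavsyn_validation_error")
  }
  row <- sm[2, ]
  tibble::tibble(
    response = response, predictor = predictor,
    beta = row[["Estimate"]], se = row[["Std. Error"]],
    t_stat = row[["t value"]], p = row[["Pr(>|t|)"]], n = n,
    covariates = paste(covariates %||% character(), collapse = "+")
  )
}

#' Run a plan of pairwise associations
#'
#' @param data Individual-level data frame.
#' @param plan Tibble with columns `response`, `predictor` and optionally
#'   `covariates` (a `"+"`-separated string per row, `""`/`NA` for none).
#' @param adjust_p When `TRUE`, a Benjamini-Hochberg adjusted column
#'   `p_adj` is appended; raw p-values are never altered.
#' @return Tibble of [assoc_ols()] rows, one per plan entry.
#' @export
assoc_scan <- function(data, plan, adjust_p = FALSE) {
  out <- purrr::pmap(plan, function(response, predictor, covariates = NULL,
                                    ...) {
    covs <- if (is.null(covariates) || is.na(covariates) ||
                  !nzchar(covariates)) NULL
            else strsplit(covariates, "+", fixed = TRUE)[[1]]
    assoc_ols(data, response, predictor, covs)
  }) |> purrr::list_rbind()
  if (adjust_p) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Reports the statistic as `W = min(W+, W-)` over signed mid-ranks of the
#' non-zero paired differences. The p-value is exact (full null
#' distribution of the positive-rank sum, by convolution) for `n <= 25`
#' without ties in `|differences|`; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null is enumerated
#'   (default 25).
#' @return One-row tibble: `w`, `w_plus`, `w_minus`, `n` (non-zero pairs),
#'   `p`, `method`.
#' @examples
#' cap <- panda_captive()
#' wilcoxon_signed_rank(cap$drs_cross, cap$drs_parallel) # W = 23
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero; test undefined",
                    class = "behavsyn_validation_error")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_max) {
    # exact null of W+ by convolution over rank inclusion
    f <- 1
    for (k in seq_len(n)) {
      g <- c(f, numeric(k)) + c(numeric(k), f)
      f <- g / 2
    }
    cdf <- cumsum(f)
    lower <- cdf[w_plus + 1]
    upper <- 1 - if (w_plus == 0) 0 else cdf[w_plus]
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- w_plus - mu
    z <- (z - sign(z) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- if (ties) "normal (tie-corrected)" else "normal"
  }
  tibble::tibble(w = w, w_plus = w_plus, w_minus = w_minus, n = n, p = p,
                 method = method)
}

#' Two-sample t test between trait groups
#'
#' @param data Data frame.
#' @param response Numeric column name.
#' @param group Grouping column name; must have exactly two non-missing
#'   levels in the modelled rows.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return One-row tibble: `t_stat`, `df`, `p`, `mean_1`, `mean_2`,
#'   `group_1`, `group_2`, `n_1`, `n_2`.
#' @export
two_sample_t <- function(data, response, group,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  d <- data[c(response, group)]
  d <- d[stats::complete.cases(d), ]
  levs <- unique(d[[group]])
  if (length(levs) != 2) abort("group must have exactly two levels",
                               class = "behavsyn_validation_error")
  x <- d[[response]][d[[group]] == levs[1]]
  y <- d[[response]][d[[group]] == levs[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs n >= 2", class = "behavsyn_validation_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("zero variance in both groups; t undefined",
          class = "behavsyn_validation_error")
  }
  tt <- t.test(x, y, var.equal = variant == "pooled")
  tibble::tibble(
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_1 = mean(x), mean_2 = mean(y),
    group_1 = as.character(levs[1]), group_2 = as.character(levs[2]),
    n_1 = length(x), n_2 = length(y)
  )
}

#' Within-individual hormone-disturbance models
#'
#' For each individual with at least `min_samples` repeated samples, fits
#' the sample-level OLS of fGCM concentration on shortest surface distance
#' (SSD), capturing short-term within-individual covariation with
#' disturbance proximity.
#'
#' @param samples Sample-level tibble with individual ids, fGCM and SSD.
#' @param response,predictor,id Column names (defaults `fgcm_ng_g`,
#'   `ssd_km`, `individual_id`).
#' @param min_samples Minimum repeated samples per individual (default 3).
#' @return Tibble of per-individual [assoc_ols()] rows with an
#'   `individual_id` column; empty (with a message) when no individual
#'   qualifies. Individuals with constant SSD are skipped with a warning.
#' @examples
#' intra_individual_assoc(panda_wild()) # individual A: beta ~ -3.92
#' @export
intra_individual_assoc <- function(samples, response = "fgcm_ng_g",
                                   predictor = "ssd_km",
                                   id = "individual_id", min_samples = 3) {
  counts <- table(samples[[id]])
  eligible <- names(counts)[counts >= min_samples]
  if (length(eligible) == 0) {
    inform("no individual has enough repeated samples")
    return(tibble::tibble())
  }
  purrr::map(eligible, function(ind) {
    d <- samples[samples[[id]] == ind, ]
    if (sd(d[[predictor]], na.rm = TRUE) == 0) {
      warn(paste0("constant ", predictor, " for individual ", ind,
                  "; skipped"))
      return(NULL)
    }
    dplyr::mutate(assoc_ols(d, response, predictor),
                  individual_id = ind, .before = 1)
  }) |> purrr::list_rbind()
}

#' Between-individual hormone-disturbance model
#'
#' OLS of per-individual mean fGCM on per-individual mean SSD across all
#' identified individuals.
#'
#' @inheritParams intra_individual_assoc
#' @return One-row [assoc_ols()] tibble where `n` is the number of
#'   individuals.
#' @examples
#' inter_individual_assoc(panda_wild()) # beta ~ 5.035 across 9 individuals
#' @export
inter_individual_assoc <- function(samples, response = "fgcm_ng_g",
                                   predictor = "ssd_km",
                                   id = "individual_id") {
  means <- samples |>
    dplyr::group_by(.data[[id]]) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(response, predictor)),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  if (nrow(means) < 3) abort("need at least 3 individuals",
                             class = "behavsyn_validation_error")
  assoc_ols(means, response, predictor)
}

#' Assemble an association network
#'
#' Converts a completed association scan into an edge list: one edge per
#' tested pair, signed by the slope and flagged significant at `alpha`.
#'
#' @param results Tibble of [assoc_ols()] rows (e.g. from [assoc_scan()]).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `assoc_network`: a tibble with `from`
#'   (predictor), `to` (response), `beta`, `p`, `significant`, `direction`.
#' @export
association_network <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            beta = numeric(), p = numeric(),
                            significant = logical(), direction = character())
  } else {
    edges <- tibble::tibble(
      from = results$predictor, to = results$response,
      beta = results$beta, p = results$p,
      significant = results$p < alpha,
      direction = ifelse(results$beta >= 0, "positive", "negative")
    )
  }
  structure(edges, class = c("assoc_network", class(edges)), alpha = alpha)
}

#' Plot an association network
#'
#' Trait-network diagram in the style of cross-experiment syndrome
#' summaries: red edges are significant positive associations, blue edges
#' significant negative ones, dashed grey edges non-significant.
#'
#' @param object An `assoc_network` edge list.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_network <- function(object, ...) {
  nodes <- unique(c(object$from, object$to))
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes, x = cos(ang), y = sin(ang))
  edges <- tibble::as_tibble(object) |>
    dplyr::left_join(pos, by = c("from" = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c("to" = "node"))
  edges$edge_col <- ifelse(!edges$significant, "n.s.",
                           ifelse(edges$beta >= 0, "positive", "negative"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$edge_col,
                   linetype = .data$significant)
    ) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(.data$x, .data$y, label = .data$node)) +
    ggplot2::scale_colour_manual(
      values = c(positive = "firebrick", negative = "steelblue",
                 n.s. = "grey60")
    ) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = 1, `FALSE` = 2),
                                   guide = "none") +
    ggplot2::labs(colour = "association") +
    ggplot2::theme_void()
}
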