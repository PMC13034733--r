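#' Fit a Gaussian random-intercept model by profiled ML/REML
#'
#' Fits `y = X beta + b_group + e` with `b_group ~ N(0, v_individual)` and
#' `e ~ N(0, v_residual)` by maximizing the (restricted) likelihood profiled
#' over the variance ratio `lambda = v_individual / v_residual`. For a
#' single random intercept the generalized least-squares step has a closed
#' group-wise form, so the optimization is one-dimensional, deterministic
#' and fast. Boundary solutions (`v_individual = 0`) are returned, not
#' errors, and flagged.
#'
#' @param data A data frame holding the response, grouping factor and any
#'   fixed-effect covariates.
#' @param response Name of the response column (string).
#' @param group Name of the grouping column (string), e.g. individual id.
#' @param fixed One-sided formula of fixed effects (e.g. `~ trial_index`),
#'   or `NULL` for an intercept-only model.
#' @param method `"REML"` (default, for reported variance components) or
#'   `"ML"` (for likelihood-ratio tests).
#' @return An object of class `ranint_fit`: variance components
#'   (`v_individual`, `v_residual`), `lambda`, fixed-effect `beta`,
#'   `logLik` of the chosen criterion, `n_obs`, `n_groups`, `boundary`
#'   flag, and the model frame needed for simulation.
#' @seealso [icc()], [lrt_random_intercept()], [bootstrap_icc()]
#' @export
fit_random_intercept <- function(data, response, group, fixed = NULL,
                                 method = c("REML", "ML")) {
  method <- match.arg(method)
  y <- data[[response]]
  if (is.null(y)) abort(paste0("no column '", response, "'"),
                        class = "behavsyn_format_error")
  if (is.null(fixed)) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- model.matrix(fixed, stats::model.frame(fixed, data,
                                                na.action = stats::na.pass))
  }
  g <- as.character(data[[group]])
  keep <- !is.na(y) & stats::complete.cases(X) & !is.na(g)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; g <- g[keep]
  fit <- .ranint_fit(y, X, g, method)
  fit$response <- response
  fit$group <- group
  fit$fixed <- fixed
  fit
}

.ranint_fit <- function(y, X, g, method = "REML") {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("fixed-effect design is rank deficient",
          class = "behavsyn_validation_error")
  }
  gf <- factor(g)
  G <- nlevels(gf)
  if (G < 2) abort("need at least 2 groups",
                   class = "behavsyn_validation_error")
  ni <- as.numeric(table(gf))
  if (max(ni) < 2) abort("need at least one group with >= 2 observations",
                         class = "behavsyn_validation_error")
  # sufficient statistics
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  Sx <- rowsum(X, gf)                       # G x p group sums of X
  Sy <- as.numeric(rowsum(y, gf))           # group sums of y
  profile <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(Sx * sqrt(ci))
    b <- Xty - crossprod(Sx, ci * Sy)
    beta <- solve(A, b)
    rss <- yty - sum(ci * Sy^2) - sum(b * beta)
    rss <- max(rss, 1e-12)
    ldet_v <- sum(log1p(lambda * ni))
    list(beta = beta, rss = rss, ldet_v = ldet_v,
         ldet_a = determinant(A, logarithm = TRUE)$modulus[[1]])
  }
  dev <- function(lambda) {
    pr <- profile(lambda)
    if (method == "ML") {
      n * log(2 * pi * pr$rss / n) + pr$ldet_v + n
    } else {
      (n - p) * log(2 * pi * pr$rss / (n - p)) + pr$ldet_v + pr$ldet_a +
        (n - p)
    }
  }
  # coarse deterministic grid, then golden-section refinement on log scale
  us <- seq(-12, 8, by = 0.5)
  dvals <- vapply(exp(us), dev, numeric(1))
  i0 <- which.min(dvals)
  lo <- us[max(1, i0 - 1)]; hi <- us[min(length(us), i0 + 1)]
  opt <- optimize(function(u) dev(exp(u)), c(lo, hi), tol = 1e-8)
  lambda <- exp(opt$minimum)
  if (dev(0) <= opt$objective) lambda <- 0   # boundary beats interior
  pr <- profile(lambda)
  sigma2 <- pr$rss / if (method == "ML") n else n - p
  ll <- -0.5 * dev(lambda)
  structure(list(
    v_individual = lambda * sigma2, v_residual = sigma2, lambda = lambda,
    beta = setNames(as.numeric(pr$beta), colnames(X)),
    logLik = ll, method = method, n_obs = n, n_groups = G,
    boundary = lambda <= 1e-8,
    y = y, X = X, g = as.character(gf)
  ), class = "ranint_fit")
}

#' @export
print.ranint_fit <- function(x, ...) {
  cat("Random-intercept Gaussian model (", x$method, ")\n", sep = "")
  cat("  groups:", x$n_groups, " obs:", x$n_obs, "\n")
  cat("  v_individual:", format(x$v_individual, digits = 4),
      " v_residual:", format(x$v_residual, digits = 4),
      " ICC:", format(icc(x), digits = 4),
      if (x$boundary) " [boundary]" else "", "\n")
  invisible(x)
}

#' @export
logLik.ranint_fit <- function(object, ...) object$logLik

#' Intraclass correlation coefficient from a fitted model
#'
#' The repeatability of a trait: among-individual variance divided by total
#' variance, `v_individual / (v_individual + v_residual)`.
#'
#' @param fit A [fit_random_intercept()] result.
#' @return ICC in `[0, 1]`.
#' @export
icc <- function(fit) {
  tot <- fit$v_individual + fit$v_residual
  if (tot <= 0) abort("both variance components are zero; ICC undefined",
                      class = "behavsyn_validation_error")
  fit$v_individual / tot
}

#' Likelihood-ratio test for the random intercept
#'
#' Compares the ML fit with the random intercept against the fixed-only
#' linear model on the same data. Because the null (`v_individual = 0`)
#' lies on the boundary of the parameter space, the reference distribution
#' is the 50:50 mixture of a point mass at 0 and a chi-squared with 1 df;
#' the naive chi-squared-1 p-value is also reported since conventions vary.
#'
#' @inheritParams fit_random_intercept
#' @return One-row tibble: `chi2`, `p_mixture`, `p_naive`.
#' @export
lrt_random_intercept <- function(data, response, group, fixed = NULL) {
  full <- fit_random_intercept(data, response, group, fixed, method = "ML")
  null_ll <- .ols_loglik(full$y, full$X)
  chi2 <- max(0, 2 * (full$logLik - null_ll))
  tibble::tibble(
    chi2 = chi2,
    p_mixture = if (chi2 <= 0) 1 else 0.5 * pchisq(chi2, 1, lower.tail = FALSE),
    p_naive = pchisq(chi2, 1, lower.tail = FALSE)
  )
}

.ols_loglik <- function(y, X) {
  n <- length(y)
  res <- stats::lm.fit(X, y)$residuals
  s2 <- sum(res^2) / n
  -0.5 * (n * log(2 * pi * s2) + n)
}

#' Parametric bootstrap confidence interval for the ICC
#'
#' Simulates new responses from the fitted variance components
#' (`y* = X beta + b_group + e`), refits by REML, and takes percentile
#' bounds of the bootstrap ICC distribution. Replicates that fail to fit
#' are dropped and counted. Reproducible given `seed`.
#'
#' @param fit A REML [fit_random_intercept()] result.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n_boot_ok`,
#'   `n_boot_failed`.
#' @export
bootstrap_icc <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  if (n_boot < 100) abort("n_boot must be >= 100",
                          class = "behavsyn_validation_error")
  mu <- as.numeric(fit$X %*% fit$beta)
  gf <- factor(fit$g)
  G <- nlevels(gf)
  idx <- as.integer(gf)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      b <- rnorm(G, 0, sqrt(fit$v_individual))
      ystar <- mu + b[idx] + rnorm(length(mu), 0, sqrt(fit$v_residual))
      out <- tryCatch(icc(.ranint_fit(ystar, fit$X, fit$g, "REML")),
                      error = function(e) NA_real_)
      out
    }, numeric(1))
  })
  ok <- boots[!is.na(boots)]
  if (length(ok) < n_boot) {
    inform(paste0(n_boot - length(ok), " bootstrap replicate(s) dropped"))
  }
  qs <- quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(icc = icc(fit), ci_low = qs[1], ci_high = qs[2],
                 n_boot_ok = length(ok), n_boot_failed = n_boot - length(ok))
}

#' Repeatability analysis of one trial-level metric
#'
#' Convenience wrapper bundling the REML variance components, the ICC, the
#' boundary-corrected likelihood-ratio test and (optionally) a parametric
#' bootstrap confidence interval for one metric.
#'
#' @inheritParams fit_random_intercept
#' @param n_boot Bootstrap replicates for the ICC interval; 0 skips the
#'   bootstrap.
#' @param seed Seed for the bootstrap.
#' @return An object of class `rpt_fit` with `tidy()` and `glance()`
#'   methods.
#' @export
repeatability <- function(data, response, group = "individual_id",
                          fixed = ~trial_index, n_boot = 0, seed = 1) {
  reml <- fit_random_intercept(data, response, group, fixed, "REML")
  lrt <- lrt_random_intercept(data, response, group, fixed)
  ci <- if (n_boot > 0) bootstrap_icc(reml, n_boot, seed) else NULL
  structure(list(metric = response, fit = reml, icc = icc(reml), lrt = lrt,
                 ci = ci), class = "rpt_fit")
}

#' @export
print.rpt_fit <- function(x, ...) {
  cat("Repeatability of", x$metric, "\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname repeatability
#' @param x,object An `rpt_fit` object.
#' @param ... Unused.
#' @export
tidy.rpt_fit <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    icc = x$icc,
    ci_low = if (is.null(x$ci)) NA_real_ else x$ci$ci_low,
    ci_high = if (is.null(x$ci)) NA_real_ else x$ci$ci_high,
    chi2 = x$lrt$chi2,
    p_mixture = x$lrt$p_mixture,
    p_naive = x$lrt$p_naive,
    v_individual = x$fit$v_individual,
    v_residual = x$fit$v_residual,
    boundary = x$fit$boundary
  )
}

#' @rdname repeatability
#' @export
glance.rpt_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$fit$n_obs, n_groups = x$fit$n_groups,
                 logLik_reml = x$fit$logLik, icc = x$icc,
                 p_mixture = x$lrt$p_mixture)
}

#' Repeatability gate: from trial-level metrics to individual mean scores
#'
#' Screens each candidate trial-level metric for significant repeatability
#' and averages only the metrics that pass into per-individual mean scores,
#' the inputs of all downstream composite-axis and association analyses.
#' Metrics failing the gate are dropped with their reason retained.
#'
#' @param data Per-trial table: one row per (individual, trial) with metric
#'   columns.
#' @param metrics Character vector of metric column names to screen.
#' @param group,fixed,n_boot,seed Passed to [repeatability()].
#' @param alpha Significance level of the gate on the boundary-corrected
#'   LRT p-value (default 0.05).
#' @return An object of class `rpt_screen`: `repeatability` (per-metric
#'   tidy table with `retained` flag), `scores` (individual x retained
#'   metric means) and `dropped` (metric names).
#' @export
repeatability_filter <- function(data, metrics, group = "individual_id",
                                 fixed = ~trial_index, alpha = 0.05,
                                 n_boot = 0, seed = 1) {
  rpt <- purrr::map(metrics, function(m) {
    tidy(repeatability(data, m, group, fixed, n_boot = n_boot, seed = seed))
  }) |> purrr::list_rbind()
  rpt$retained <- rpt$p_mixture < alpha
  kept <- rpt$metric[rpt$retained]
  scores <- data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(kept),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  structure(list(repeatability = rpt, scores = scores,
                 dropped = setdiff(metrics, kept), alpha = alpha),
            class = "rpt_screen")
}

#' @export
print.rpt_screen <- function(x, ...) {
  cat("Repeatability screen (alpha =", x$alpha, ")\n")
  print(x$repeatability[c("metric", "icc", "chi2", "p_mixture", "retained")])
  if (length(x$dropped)) {
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname repeatability_filter
#' @param x An `rpt_screen` object.
#' @param ... Unused.
#' @export
tidy.rpt_screen <- function(x, ...) x$repeatability

#' Forest plot of screened repeatabilities
#'
#' @param object An `rpt_screen` object.
#' @param ... Unused.
#' @return A ggplot: ICC point estimates (with bootstrap intervals when
#'   available) per metric, coloured by gate outcome.
#' @export
autoplot.rpt_screen <- function(object, ...) {
  d <- object$repeatability
  ggplot2::ggplot(d, ggplot2::aes(x = .data$icc, y = .data$metric,
                                  colour = .data$retained)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "ICC (repeatability)", y = NULL,
                  colour = paste0("p < ", object$alpha)) +
    ggplot2::theme_minimal()
}
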