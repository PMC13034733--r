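#' Spearman correlation matrix of individual scores
#'
#' Rank-based pairwise correlations among per-individual metric columns,
#' using pairwise-complete observations so that individuals missing one
#' assay still contribute elsewhere. Constant columns yield undefined
#' entries and a warning.
#'
#' @param scores Individual-by-metric data frame; non-numeric columns
#'   (ids) are dropped.
#' @param variables Optional character vector selecting/ordering columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(scores, variables = NULL) {
  num <- scores[vapply(scores, is.numeric, logical(1))]
  if (!is.null(variables)) num <- num[variables]
  if (nrow(num) < 3) abort("need at least 3 individuals",
                           class = "behavsyn_validation_error")
  const <- vapply(num, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(const, na.rm = TRUE)) {
    warn(paste0("constant column(s): ",
                paste(names(num)[which(const)], collapse = ", ")))
  }
  suppressWarnings(
    cor(as.matrix(num), method = "spearman", use = "pairwise.complete.obs")
  )
}

#' Collinearity gate: cluster variables by strong correlation
#'
#' Builds a graph with an edge wherever `|rho| > threshold` and returns its
#' connected components. Components of two or more variables are destined
#' for a composite PCA axis; singletons are analysed independently. Using
#' connected components (rather than requiring all pairs to exceed the
#' threshold) lets a cluster contain a sub-threshold pair bridged by a
#' shared strong correlate.
#'
#' @param corr Square symmetric correlation matrix with named dimensions.
#' @param threshold Absolute-correlation gate (default 0.7, strict
#'   inequality).
#' @return Tibble with `variable`, `cluster` (integer label), and `in_pca`
#'   (TRUE when the cluster has two or more members). Clusters are numbered
#'   by first appearance in the matrix ordering.
#' @examples
#' R <- panda_cor_matrices()$mab
#' collinearity_gate(R)
#' @export
collinearity_gate <- function(corr, threshold = 0.7) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  vars <- rownames(corr) %||% paste0("V", seq_len(nrow(corr)))
  adj <- abs(corr) > threshold
  diag(adj) <- FALSE
  adj[is.na(adj)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  cluster <- as.integer(factor(comp, levels = unique(comp)))
  sizes <- table(cluster)
  tibble::tibble(variable = vars, cluster = cluster,
                 in_pca = as.integer(sizes[as.character(cluster)]) >= 2)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the sum of squared off-diagonal correlations divided by that
#' sum plus the sum of squared anti-image partial correlations.
#'
#' @param corr Invertible correlation matrix.
#' @param ridge Ridge added to the diagonal when inversion fails
#'   (default 0; suggest `1e-6` for singular matrices).
#' @return List with `kmo` (overall, in `[0, 1]`) and `msa` (per-variable
#'   measures).
#' @export
kmo <- function(corr, ridge = 0) {
  R <- corr
  if (ridge > 0) R <- R + diag(ridge, nrow(R))
  inv <- tryCatch(solve(R), error = function(e) {
    abort("singular correlation matrix; retry with ridge = 1e-6",
          class = "behavsyn_validation_error")
  })
  d <- 1 / sqrt(diag(inv))
  Q <- -inv * tcrossprod(d)   # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  list(kmo = sum(R0^2) / (sum(R0^2) + sum(Q^2)), msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from identity:
#' `chi2 = -[(n - 1) - (2p + 5) / 6] * ln det(R)` on `p (p - 1) / 2` df.
#'
#' @param corr Correlation matrix (p x p).
#' @param n Number of observations behind `corr` (must exceed p).
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(corr, n) {
  p <- ncol(corr)
  if (n <= p) abort("n must exceed the number of variables",
                    class = "behavsyn_validation_error")
  ld <- determinant(corr, logarithm = TRUE)
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  chi2 <- max(0, chi2)
  df <- p * (p - 1) / 2
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Composite behavioural axis by correlation-matrix PCA
#'
#' Eigen-decomposes the correlation matrix of z-standardized variables,
#' retains components by the Kaiser criterion (eigenvalue > 1), and
#' extracts per-individual scores. The leading component's sign is oriented
#' by a named rule variable (its loading is made positive), so that e.g. a
#' "reactive" axis always points toward higher neophobia regardless of the
#' arbitrary eigenvector sign.
#'
#' @param scores Individual-by-metric data frame; must contain an id column
#'   (`id_col`) and the axis `variables`. Rows with any missing variable
#'   are dropped from score extraction.
#' @param variables Character vector (length >= 2) of metric columns
#'   entering the axis.
#' @param orient_var Variable whose PC1 loading is forced positive
#'   (default: first of `variables`).
#' @param axis_name Label for the axis (e.g. `"reactive"`).
#' @param id_col Name of the individual id column (default
#'   `"individual_id"`).
#' @param cor_method `"pearson"` (conventional PCA on z-scores, default) or
#'   `"spearman"`.
#' @param ridge Passed to [kmo()] for near-singular matrices.
#' @return An object of class `axis_fit`: loadings, eigenvalues, variance
#'   explained, per-individual scores (zero mean), KMO and Bartlett
#'   adequacy statistics, and the Kaiser retention count. `tidy()` returns
#'   loadings, `glance()` the axis summary, `autoplot()` a scree/loadings
#'   panel.
#' @export
pca_axis <- function(scores, variables, orient_var = variables[1],
                     axis_name = "axis", id_col = "individual_id",
                     cor_method = c("pearson", "spearman"), ridge = 0) {
  cor_method <- match.arg(cor_method)
  if (length(variables) < 2) abort("need at least 2 variables",
                                   class = "behavsyn_validation_error")
  stopifnot(orient_var %in% variables)
  dat <- scores[c(id_col, variables)]
  dat <- dat[stats::complete.cases(dat[variables]), ]
  Xz <- scale(as.matrix(dat[variables]))
  R <- cor(Xz, method = cor_method)
  eig <- eigen(R, symmetric = TRUE)
  k <- sum(eig$values > 1)
  loadings <- eig$vectors
  rownames(loadings) <- variables
  # orientation rule on the leading component
  if (loadings[orient_var, 1] < 0) loadings[, 1] <- -loadings[, 1]
  scr <- Xz %*% loadings
  adequacy <- tryCatch(kmo(R, ridge = ridge), error = function(e) {
    # degenerate (e.g. perfectly collinear) matrices: fall back to a
    # tiny ridge so adequacy is still reported
    kmo(R, ridge = 1e-6)
  })
  bart <- bartlett_sphericity(R, n = nrow(dat))
  if (k != 1) {
    warn(paste0("Kaiser criterion retains ", k,
                " component(s); the leading component is used for '",
                axis_name, "'"))
  }
  structure(list(
    axis_name = axis_name, variables = variables,
    loadings = loadings, eigenvalues = eig$values,
    variance_explained = eig$values / sum(eig$values),
    n_retained = k,
    scores = tibble::tibble(!!id_col := dat[[id_col]],
                            !!axis_name := as.numeric(scr[, 1])),
    kmo = adequacy$kmo, msa = adequacy$msa,
    bartlett = bart, cor_method = cor_method, n_individuals = nrow(dat)
  ), class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat("Composite axis '", x$axis_name, "' (", x$n_individuals,
      " individuals)\n", sep = "")
  cat("  PC1 variance explained:",
      format(100 * x$variance_explained[1], digits = 3), "%\n")
  cat("  KMO:", format(x$kmo, digits = 3),
      " Bartlett p:", format(x$bartlett$p_value, digits = 3), "\n")
  cat("  loadings:\n")
  print(round(x$loadings[, 1], 3))
  invisible(x)
}

#' @rdname pca_axis
#' @param x,object An `axis_fit` object.
#' @param ... Unused.
#' @export
tidy.axis_fit <- function(x, ...) {
  tibble::tibble(
    axis = x$axis_name,
    variable = rownames(x$loadings),
    loading = x$loadings[, 1],
    component = 1L
  )
}

#' @rdname pca_axis
#' @export
glance.axis_fit <- function(x, ...) {
  tibble::tibble(
    axis = x$axis_name,
    n_variables = length(x$variables),
    n_individuals = x$n_individuals,
    n_retained = x$n_retained,
    pc1_eigenvalue = x$eigenvalues[1],
    pc1_variance = x$variance_explained[1],
    kmo = x$kmo,
    bartlett_chi2 = x$bartlett$chi2,
    bartlett_p = x$bartlett$p_value
  )
}

#' @rdname pca_axis
#' @export
autoplot.axis_fit <- function(object, ...) {
  scree <- tibble::tibble(component = seq_along(object$eigenvalues),
                          eigenvalue = object$eigenvalues)
  p1 <- ggplot2::ggplot(scree,
                        ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(title = paste0("Scree: ", object$axis_name),
                  x = "Component", y = "Eigenvalue") +
    ggplot2::theme_minimal()
  load1 <- tidy(object)
  p2 <- ggplot2::ggplot(load1,
                        ggplot2::aes(.data$loading, .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PC1 loading", y = NULL) +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) p1 + p2 else p1
}
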