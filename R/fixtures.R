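#' Packaged giant-panda study tables
#'
#' The package ships a small published-style dataset from a giant panda
#' (*Ailuropoda melanoleuca*) behavioural-syndrome study: per-individual
#' composite behavioural scores, hormone baselines and string-pulling
#' outcomes for 12 captive subjects (`panda_captive()`); 18 wild faecal
#' samples with fGCM concentration, genotyped individual identity and
#' shortest surface distance to human disturbance (`panda_wild()`); the
#' three Spearman correlation matrices among trial-derived behavioural
#' metrics that feed the collinearity gate (`panda_cor_matrices()`); and a
#' per-locus microsatellite diversity summary for the wild cohort
#' (`panda_loci()`).
#'
#' Empty cells in the captive table are genuine missingness (one individual
#' left the multi-access box assay early) and are kept as `NA`, never
#' imputed. Trial-level raw data behind these summaries are not published;
#' the synthetic generator ([sim_captive_study()]) stands in for them.
#'
#' @return A tibble (`panda_captive()`, `panda_wild()`, `panda_loci()`) or a
#'   named list of three numeric correlation matrices
#'   (`panda_cor_matrices()`: `mab`, `rdt_learning`, `rdt_personality`).
#' @examples
#' head(panda_captive())
#' panda_cor_matrices()$mab
#' @export
panda_captive <- function() {
  readr::read_tsv(.extdata("captive_pandas.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

.extdata <- function(file) {
  system.file("extdata", file, package = "behavsyn", mustWork = TRUE)
}

#' @rdname panda_captive
#' @export
panda_wild <- function() {
  readr::read_tsv(.extdata("wild_samples.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname panda_captive
#' @export
panda_cor_matrices <- function() {
  read_mat <- function(file) {
    d <- readr::read_tsv(.extdata(file), show_col_types = FALSE,
                         progress = FALSE)
    m <- as.matrix(d[-1])
    rownames(m) <- d$variable
    m
  }
  list(
    mab = read_mat("mab_spearman.tsv"),
    rdt_learning = read_mat("rdt_learning_spearman.tsv"),
    rdt_personality = read_mat("rdt_personality_spearman.tsv")
  )
}

#' @rdname panda_captive
#' @export
panda_loci <- function() {
  readr::read_tsv(.extdata("wild_loci.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
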