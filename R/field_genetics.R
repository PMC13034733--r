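#' Read and write microsatellite genotype tables
#'
#' Genotypes travel as wide tab-delimited text: a `sample_id` column plus a
#' pair of columns `<locus>_a` / `<locus>_b` per locus holding integer
#' allele sizes (empty = missing). Internally the package uses a long
#' tibble `sample_id, locus, allele_1, allele_2` with the allele pair
#' stored in sorted order (genotypes are unordered).
#'
#' @param path File path.
#' @return `read_genotypes()`: a long genotype tibble.
#' @export
read_genotypes <- function(path) {
  wide <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                          progress = FALSE)
  if (!"sample_id" %in% names(wide)) {
    abort("genotype table needs a sample_id column",
          class = "behavsyn_format_error")
  }
  acols <- grep("_a$", names(wide), value = TRUE)
  loci <- sub("_a$", "", acols)
  missing_b <- setdiff(paste0(loci, "_b"), names(wide))
  if (length(missing_b) > 0) {
    abort(paste0("missing allele column(s): ",
                 paste(missing_b, collapse = ", ")),
          class = "behavsyn_format_error")
  }
  purrr::map(loci, function(l) {
    tibble::tibble(sample_id = as.character(wide$sample_id), locus = l,
                   allele_1 = wide[[paste0(l, "_a")]],
                   allele_2 = wide[[paste0(l, "_b")]])
  }) |>
    purrr::list_rbind() |>
    normalize_genotypes()
}

#' @rdname read_genotypes
#' @param genotypes A long genotype tibble.
#' @export
write_genotypes <- function(genotypes, path) {
  genotypes <- normalize_genotypes(genotypes)
  wide <- genotypes |>
    tidyr::pivot_wider(names_from = "locus",
                       values_from = c("allele_1", "allele_2"),
                       names_glue = "{locus}_{ifelse(.value == 'allele_1', 'a', 'b')}")
  loci <- unique(genotypes$locus)
  wide <- wide[c("sample_id", as.vector(rbind(paste0(loci, "_a"),
                                              paste0(loci, "_b"))))]
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

#' @rdname read_genotypes
#' @export
normalize_genotypes <- function(genotypes) {
  g <- tibble::as_tibble(genotypes)
  needed <- c("sample_id", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(needed, names(g))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "behavsyn_format_error")
  }
  half <- xor(is.na(g$allele_1), is.na(g$allele_2))
  if (any(half)) {
    abort(paste0("half-missing genotype at row(s): ",
                 paste(which(half), collapse = ", ")),
          class = "behavsyn_validation_error")
  }
  a1 <- pmin(g$allele_1, g$allele_2)
  a2 <- pmax(g$allele_1, g$allele_2)
  g$allele_1 <- a1
  g$allele_2 <- a2
  g
}

#' Allele frequencies at each locus
#'
#' Counts allele copies over the `2n` gene copies of the non-missing
#' genotypes and normalizes.
#'
#' @param genotypes Long genotype tibble.
#' @return Tibble with `locus`, `allele`, `count`, `freq`.
#' @export
allele_freqs <- function(genotypes, locus = NULL) {
  g <- normalize_genotypes(genotypes)
  if (!is.null(locus)) g <- g[g$locus %in% locus, ]
  g <- g[!is.na(g$allele_1), ]
  if (nrow(g) == 0) {
    abort("no non-missing genotypes at the requested locus",
          class = "behavsyn_empty_data_error")
  }
  long <- tibble::tibble(locus = rep(g$locus, 2),
                         allele = c(g$allele_1, g$allele_2))
  long |>
    dplyr::count(.data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Probability of identity for one locus
#'
#' `pid()` is the probability that two unrelated individuals drawn from a
#' Hardy-Weinberg population share a genotype at the locus:
#' `2 (sum p_i^2)^2 - sum p_i^4`. `pid_sib()` is the (more conservative)
#' full-sibling version:
#' `0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' Multi-locus values multiply across independent loci.
#'
#' @param freqs Numeric allele-frequency vector summing to 1.
#' @return A probability in `(0, 1]`.
#' @examples
#' pid(c(0.5, 0.5)) # 0.375
#' pid_sib(c(0.5, 0.5)) # 0.59375
#' @export
pid <- function(freqs) {
  .check_freqs(freqs)
  2 * sum(freqs^2)^2 - sum(freqs^4)
}

#' @rdname pid
#' @export
pid_sib <- function(freqs) {
  .check_freqs(freqs)
  0.25 + 0.5 * sum(freqs^2) + 0.5 * sum(freqs^2)^2 - 0.25 * sum(freqs^4)
}

.check_freqs <- function(freqs) {
  if (length(freqs) == 0 || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-8) {
    abort("freqs must be a non-negative vector summing to 1",
          class = "behavsyn_validation_error")
  }
}

#' Per-locus diversity and identification statistics
#'
#' Observed heterozygosity (fraction of typed genotypes that are
#' heterozygous), expected heterozygosity (Nei's gene diversity
#' `1 - sum p_i^2`, or its small-sample unbiased `2n/(2n-1)` correction),
#' polymorphic information content
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`, and the
#' probability-of-identity measures [pid()] and [pid_sib()].
#'
#' @param genotypes Long genotype tibble.
#' @param unbiased_he Apply the `2n/(2n-1)` correction to He
#'   (default `FALSE`).
#' @return Tibble with one row per locus: `locus`, `n_typed`, `n_alleles`,
#'   `ho`, `he`, `pic`, `pid`, `pid_sib`.
#' @export
locus_stats <- function(genotypes, unbiased_he = FALSE) {
  g <- normalize_genotypes(genotypes)
  freqs <- allele_freqs(g)
  g <- g[!is.na(g$allele_1), ]
  purrr::map(unique(g$locus), function(l) {
    gl <- g[g$locus == l, ]
    p <- freqs$freq[freqs$locus == l]
    sp2 <- sum(p^2)
    he <- 1 - sp2
    if (unbiased_he) he <- he * 2 * nrow(gl) / (2 * nrow(gl) - 1)
    # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
    pic_val <- 1 - sp2 - (sp2^2 - sum(p^4))
    tibble::tibble(
      locus = l, n_typed = nrow(gl), n_alleles = length(p),
      ho = mean(gl$allele_1 != gl$allele_2),
      he = he, pic = pic_val, pid = pid(p), pid_sib = pid_sib(p)
    )
  }) |> purrr::list_rbind()
}

#' Cumulative identification power of a marker panel
#'
#' Products of per-locus PID and PID(sib) over the listed loci, under the
#' standard locus-independence assumption.
#'
#' @param stats A [locus_stats()] tibble.
#' @param loci Character vector of locus names (non-empty).
#' @return One-row tibble: `n_loci`, `pid`, `pid_sib`.
#' @export
panel_pid <- function(stats, loci) {
  if (length(loci) == 0) abort("empty locus subset",
                               class = "behavsyn_validation_error")
  missing_loci <- setdiff(loci, stats$locus)
  if (length(missing_loci) > 0) {
    abort(paste0("unknown locus: ", paste(missing_loci, collapse = ", ")),
          class = "behavsyn_validation_error")
  }
  sub <- stats[match(loci, stats$locus), ]
  tibble::tibble(n_loci = length(loci), pid = prod(sub$pid),
                 pid_sib = prod(sub$pid_sib))
}

#' Select a marker panel to a target sibling probability of identity
#'
#' Ranks loci by descending polymorphic information content and returns the
#' smallest prefix whose cumulative PID(sib) falls below the target
#' discriminatory power. When even the full set cannot attain the target,
#' all loci are returned with a warning.
#'
#' @param stats A [locus_stats()] tibble (or any tibble with `locus`,
#'   `pic`, `pid`, `pid_sib`).
#' @param target_pid_sib Target (default 0.01, strict `<`).
#' @return List with `loci` (selected names, PIC order), `pid`, `pid_sib`
#'   (cumulative over the selection) and `attained` (logical).
#' @export
select_panel <- function(stats, target_pid_sib = 0.01) {
  if (nrow(stats) == 0) abort("no loci", class = "behavsyn_validation_error")
  ord <- stats[order(-stats$pic), ]
  cum <- cumprod(ord$pid_sib)
  k <- which(cum < target_pid_sib)[1]
  if (is.na(k)) {
    warn(paste0("target PID(sib) < ", target_pid_sib,
                " unattainable; returning all ", nrow(ord), " loci"))
    k <- nrow(ord)
  }
  list(loci = ord$locus[seq_len(k)],
       pid = prod(ord$pid[seq_len(k)]),
       pid_sib = cum[k],
       attained = cum[k] < target_pid_sib)
}

#' Multi-tube consensus genotyping
#'
#' Collapses replicate PCR calls per sample-locus into a consensus under
#' standard multi-tube rules: a heterozygote is accepted when each of its
#' two alleles is observed in at least two replicates; a homozygote when
#' its allele is observed in at least three replicates with no second
#' allele ever seen; anything else is missing. Observing three or more
#' alleles each in two or more replicates is ambiguous, hence missing.
#'
#' @param replicates Long tibble with `sample_id`, `locus`, `allele_1`,
#'   `allele_2`, one row per replicate call (missing replicate calls as
#'   `NA` pairs).
#' @param min_het,min_hom Replicate-support thresholds (defaults 2 and 3).
#' @return Long consensus genotype tibble with a `confidence` column
#'   (`"het"`, `"hom"`, `"missing"`) and `n_replicates`.
#' @export
consensus_genotypes <- function(replicates, min_het = 2, min_hom = 3) {
  reps <- normalize_genotypes(replicates)
  reps |>
    dplyr::group_by(.data$sample_id, .data$locus) |>
    dplyr::group_modify(function(d, key) {
      d <- d[!is.na(d$allele_1), ]
      n_rep <- nrow(d)
      # per-replicate allele presence
      pres <- purrr::map(seq_len(n_rep),
                         ~ unique(c(d$allele_1[.x], d$allele_2[.x])))
      counts <- table(unlist(pres))
      alleles <- as.numeric(names(counts))
      supported <- alleles[counts >= min_het]
      call <- tibble::tibble(allele_1 = NA_real_, allele_2 = NA_real_,
                             confidence = "missing", n_replicates = n_rep)
      if (length(alleles) == 1 && counts[1] >= min_hom) {
        call$allele_1 <- alleles
        call$allele_2 <- alleles
        call$confidence <- "hom"
      } else if (length(supported) == 2 && length(alleles) >= 2) {
        call$allele_1 <- min(supported)
        call$allele_2 <- max(supported)
        call$confidence <- "het"
      }
      call
    }) |>
    dplyr::ungroup()
}

#' Cluster samples into individuals by multilocus genotype matching
#'
#' Samples whose consensus genotypes agree (allowing up to
#' `max_mismatch_loci` disagreeing loci; loci missing in either sample are
#' ignored) are clustered into putative individuals via graph connected
#' components. Non-clique components (A matches B, B matches C, but A does
#' not match C) are merged transitively with a warning, as they need manual
#' review. Labels are assigned in first-seen sample order.
#'
#' @param genotypes Long consensus genotype tibble.
#' @param panel Optional character vector of loci to compare (default: all
#'   loci present).
#' @param max_mismatch_loci Allowed disagreeing loci (default 0).
#' @param min_shared_loci Minimum co-typed loci for a comparison to count
#'   (default 1).
#' @return Tibble `sample_id`, `individual` (labels `IND01`, `IND02`, ...),
#'   with attribute `n_individuals`.
#' @export
match_individuals <- function(genotypes, panel = NULL,
                              max_mismatch_loci = 0, min_shared_loci = 1) {
  g <- normalize_genotypes(genotypes)
  if (!is.null(panel)) g <- g[g$locus %in% panel, ]
  samples <- unique(g$sample_id)
  n <- length(samples)
  key <- paste(g$sample_id, g$locus)
  gt <- setNames(paste(g$allele_1, g$allele_2), key)
  loci <- unique(g$locus)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      gi <- gt[paste(samples[i], loci)]
      gj <- gt[paste(samples[j], loci)]
      ok <- !is.na(gi) & !is.na(gj) & gi != "NA NA" & gj != "NA NA"
      if (sum(ok) >= min_shared_loci &&
            sum(gi[ok] != gj[ok]) <= max_mismatch_loci) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  # flag non-clique components (transitive chains)
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (length(members) >= 3) {
      sub <- adj[members, members]
      if (any(!sub[upper.tri(sub)])) {
        warn(paste0("samples ", paste(samples[members], collapse = ", "),
                    " form a non-clique match chain; merged transitively"))
      }
    }
  }
  labels <- as.integer(factor(comp, levels = unique(comp)))
  out <- tibble::tibble(sample_id = samples,
                        individual = sprintf("IND%02d", labels))
  attr(out, "n_individuals") <- max(labels)
  out
}
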