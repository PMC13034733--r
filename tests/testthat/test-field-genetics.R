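geno <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, "", 1),
    locus = vapply(rows, `[[`, "", 2),
    allele_1 = as.numeric(vapply(rows, `[[`, "", 3)),
    allele_2 = as.numeric(vapply(rows, `[[`, "", 4))
  )
}

test_that("allele frequencies count gene copies", {
  g <- geno(c("s1", "L1", "1", "1"), c("s2", "L1", "1", "2"))
  f <- allele_freqs(g)
  expect_equal(f$freq, c(0.75, 0.25))
  g2 <- geno(c("s1", "L1", "5", "5"))
  expect_equal(allele_freqs(g2)$freq, 1)
  withr::with_seed(91, {
    alleles <- sample(1:6, 40, replace = TRUE)
    g3 <- tibble::tibble(sample_id = paste0("s", 1:20), locus = "L1",
                         allele_1 = alleles[1:20], allele_2 = alleles[21:40])
    f3 <- allele_freqs(g3)
    tall <- table(c(pmin(g3$allele_1, g3$allele_2),
                    pmax(g3$allele_1, g3$allele_2)))
    expect_equal(f3$count, as.integer(tall))
    expect_equal(sum(f3$freq), 1)
  })
})

test_that("diversity statistics match direct substitution", {
  g <- geno(c("s1", "L1", "1", "2"), c("s2", "L1", "1", "2"),
            c("s3", "L1", "1", "1"), c("s4", "L1", "2", "2"))
  st <- locus_stats(g)  # p = q = 0.5
  expect_equal(st$he, 0.5)
  expect_equal(st$pic, 0.375)
  expect_equal(st$ho, 0.5)
  mono <- locus_stats(geno(c("s1", "L1", "3", "3")))
  expect_equal(mono$he, 0)
  expect_equal(mono$pic, 0)
  # four equal alleles: He 0.75; PIC against a double-sum oracle
  p <- rep(0.25, 4)
  double_sum <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    double_sum <- double_sum + 2 * p[i]^2 * p[j]^2
  }
  g4 <- geno(c("a", "L1", "1", "2"), c("b", "L1", "3", "4"))
  st4 <- locus_stats(g4)
  expect_equal(st4$he, 0.75)
  expect_equal(st4$pic, 1 - sum(p^2) - double_sum)
  # unbiased He variant applies 2n/(2n-1)
  expect_equal(locus_stats(g4, unbiased_he = TRUE)$he, 0.75 * 4 / 3)
})

test_that("PID formulas match the worked values and the enumeration oracle", {
  expect_equal(pid(c(0.5, 0.5)), 0.375)
  expect_equal(pid_sib(c(0.5, 0.5)), 0.59375)
  expect_equal(pid(1), 1)
  expect_equal(pid_sib(1), 1)
  withr::with_seed(12, {
    for (rep in 1:12) {
      k <- sample(2:6, 1)
      p <- rgamma(k, 1)
      p <- p / sum(p)
      expect_equal(pid(p), oracle_pid_enum(p), tolerance = 1e-12)
      # invariants: pid <= pid_sib, splitting an allele reduces both
      expect_lte(pid(p), pid_sib(p))
      split_p <- c(p[-1], p[1] / 2, p[1] / 2)
      expect_lt(pid(split_p), pid(p))
      expect_lt(pid_sib(split_p), pid_sib(p))
    }
  })
})

test_that("panel selection takes the smallest PIC-ranked prefix", {
  st <- tibble::tibble(locus = paste0("L", 1:5), pic = 5:1 / 10,
                       pid = rep(0.2, 5), pid_sib = rep(0.3, 5))
  sel <- select_panel(st, target_pid_sib = 0.01)
  expect_equal(sel$loci, paste0("L", 1:4))  # 0.3^4 = 0.0081 < 0.01
  expect_equal(sel$pid_sib, 0.3^4)
  one <- tibble::tibble(locus = "L1", pic = 0.9, pid = 1e-4,
                        pid_sib = 5e-3)
  expect_equal(select_panel(one)$loci, "L1")
  hopeless <- tibble::tibble(locus = c("A", "B"), pic = c(0.2, 0.1),
                             pid = c(0.9, 0.9), pid_sib = c(0.95, 0.95))
  expect_warning(sel2 <- select_panel(hopeless), "unattainable")
  expect_equal(length(sel2$loci), 2)
  # brute force over all PIC-ordered prefixes agrees
  withr::with_seed(19, {
    st2 <- tibble::tibble(locus = paste0("M", 1:8), pic = runif(8),
                          pid = runif(8, 0.05, 0.5),
                          pid_sib = runif(8, 0.2, 0.7))
    sel3 <- select_panel(st2, 0.01)
    ord <- st2[order(-st2$pic), ]
    sizes <- which(cumprod(ord$pid_sib) < 0.01)
    expect_equal(length(sel3$loci), min(sizes))
  })
  # multi-locus PID(sib) is monotone non-increasing in panel size
  stats_tab <- locus_stats(sim_field_study(seed = 3)$genotypes)
  cums <- vapply(seq_len(nrow(stats_tab)), function(k) {
    panel_pid(stats_tab, stats_tab$locus[seq_len(k)])$pid_sib
  }, numeric(1))
  expect_true(all(diff(cums) <= 1e-12))
})

test_that("multi-tube consensus follows the replicate-support rules", {
  reps <- geno(c("s1", "L1", "1", "2"), c("s1", "L1", "1", "2"),
               c("s1", "L1", "1", "1"))
  out <- consensus_genotypes(reps)
  expect_equal(out$allele_1, 1)
  expect_equal(out$allele_2, 2)
  expect_equal(out$confidence, "het")
  single <- consensus_genotypes(geno(c("s1", "L1", "1", "1")))
  expect_equal(single$confidence, "missing")
  hom <- consensus_genotypes(geno(c("s1", "L1", "4", "4"),
                                  c("s1", "L1", "4", "4"),
                                  c("s1", "L1", "4", "4")))
  expect_equal(hom$confidence, "hom")
  # a stray second allele blocks the homozygote call
  tainted <- consensus_genotypes(geno(c("s1", "L1", "4", "4"),
                                      c("s1", "L1", "4", "4"),
                                      c("s1", "L1", "4", "5")))
  expect_equal(tainted$confidence, "missing")
})

test_that("replication suppresses false homozygotes under allelic dropout", {
  sim_false_hom <- function(n_rep, n_sim = 400, drop = 0.4, seed = 1) {
    withr::with_seed(seed, {
      wrong <- 0
      called <- 0
      for (i in seq_len(n_sim)) {
        reps <- purrr::map(seq_len(n_rep), function(r) {
          # true genotype (1,2); each allele drops independently
          seen <- c(1, 2)[runif(2) > drop]
          if (length(seen) == 0) seen <- sample(1:2, 1)
          c(min(seen), max(seen))
        })
        tab <- tibble::tibble(
          sample_id = "s", locus = "L",
          allele_1 = vapply(reps, `[`, 0, 1),
          allele_2 = vapply(reps, function(x) x[length(x)], 0))
        out <- consensus_genotypes(tab)
        if (out$confidence != "missing") {
          called <- called + 1
          if (out$confidence == "hom") wrong <- wrong + 1
        }
      }
      wrong / max(called, 1)
    })
  }
  # a homozygote call needs >= 3 replicates at all, so start at 3
  expect_gte(sim_false_hom(3), sim_false_hom(6))
  expect_gte(sim_false_hom(6), sim_false_hom(9))
  expect_gt(sim_false_hom(3), 0)
})

test_that("genotype matching clusters identical multilocus profiles", {
  two_same <- geno(c("s1", "L1", "1", "2"), c("s1", "L2", "3", "3"),
                   c("s2", "L1", "2", "1"), c("s2", "L2", "3", "3"))
  m <- match_individuals(two_same)
  expect_equal(attr(m, "n_individuals"), 1)
  one_off <- geno(c("s1", "L1", "1", "2"), c("s1", "L2", "3", "3"),
                  c("s2", "L1", "1", "2"), c("s2", "L2", "3", "4"))
  m2 <- match_individuals(one_off, max_mismatch_loci = 0)
  expect_equal(attr(m2, "n_individuals"), 2)
  expect_equal(attr(match_individuals(one_off, max_mismatch_loci = 1),
                    "n_individuals"), 1)
  # generator truth: error-free genotypes recover all nine individuals
  bundle <- sim_field_study(seed = 8)
  m3 <- match_individuals(bundle$genotypes)
  expect_equal(attr(m3, "n_individuals"), 9)
  truth <- bundle$samples$true_individual
  expect_equal(length(unique(paste(truth, m3$individual))), 9)
})

test_that("genotype tables round-trip through the wide text format", {
  bundle <- sim_field_study(seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(bundle$genotypes, path)
  back <- read_genotypes(path)
  orig <- dplyr::arrange(normalize_genotypes(bundle$genotypes),
                         sample_id, locus)
  back <- dplyr::arrange(back, sample_id, locus)
  expect_equal(as.data.frame(back), as.data.frame(orig))
})
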