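# A synthetic effect matrix with known entries, built directly.
synthetic_matrix <- function(region, deltas, wt_value = -8.92) {
  wt <- strsplit(region$wt_aa, "")[[1]]
  aa_seqs <- character(0); values <- numeric(0)
  for (i in seq_along(wt)) {
    for (a in setdiff(titeseq:::AA_ALPHABET, wt[i])) {
      v <- wt; v[i] <- a
      aa_seqs <- c(aa_seqs, paste(v, collapse = ""))
      values <- c(values, wt_value + deltas[i, a])
    }
  }
  build_effect_matrix(aa_seqs, values, region, wt_value = wt_value)
}

random_deltas <- function(region, seed, sd = 1) {
  wt <- strsplit(region$wt_aa, "")[[1]]
  withr::with_seed(seed, {
    d <- matrix(rnorm(length(wt) * 20, 1, sd), length(wt), 20,
                dimnames = list(region$residue_numbers, titeseq:::AA_ALPHABET))
    d[cbind(seq_along(wt), match(wt, titeseq:::AA_ALPHABET))] <- 0
    d
  })
}

test_that("effect matrices average synonymous variants and fix WT entries at zero", {
  r1 <- variable_region("1H")
  # all variants measured equal to WT -> zero matrix
  m0 <- build_effect_matrix(rep(r1$wt_aa, 3), rep(-8.92, 3), r1,
                            wt_value = NULL)
  expect_true(all(m0[!is.na(m0)] == 0))
  # boundary arithmetic: a variant censored at the upper limit vs WT -8.92
  m <- build_effect_matrix(c(r1$wt_aa, "AFSDYWMNWV"), c(-8.92, -5.0), r1)
  expect_equal(m["28", "A"], 3.92)
  expect_equal(m["28", "T"], 0)  # WT residue
  # synonymous codon variants of one substitution are averaged
  m2 <- build_effect_matrix(c(r1$wt_aa, "AFSDYWMNWV", "AFSDYWMNWV"),
                            c(-8.92, -7.0, -7.5), r1)
  expect_equal(m2["28", "A"], mean(c(-7.0, -7.5)) + 8.92)
  expect_equal(attr(m2, "n")["28", "A"], 2L)
})

test_that("sensitivity equals the brute-force mean over the 19 non-WT amino acids", {
  r1 <- variable_region("1H")
  wt <- strsplit(r1$wt_aa, "")[[1]]
  zero <- synthetic_matrix(r1, matrix(0, 10, 20,
    dimnames = list(NULL, titeseq:::AA_ALPHABET)))
  expect_equal(sensitivity_profile(zero)$s_k, rep(0, 10))
  # a uniform +2 shift at one position gives S_K = 4 there
  d <- matrix(0, 10, 20, dimnames = list(NULL, titeseq:::AA_ALPHABET))
  d[4, ] <- 2; d[4, wt[4]] <- 0
  m4 <- synthetic_matrix(r1, d)
  expect_equal(sensitivity_profile(m4)$s_k[4], 4)
  # random matrix vs term-by-term evaluation
  dm <- random_deltas(r1, seed = 50)
  mr <- synthetic_matrix(r1, dm)
  prof <- sensitivity_profile(mr, mr)
  brute <- vapply(seq_len(10), function(i)
    mean(dm[i, setdiff(titeseq:::AA_ALPHABET, wt[i])]^2), numeric(1))
  expect_equal(prof$s_k, brute)
  expect_equal(prof$s_e, brute)
  # consistent relabeling of the non-WT amino acids leaves S_K unchanged
  dperm <- dm
  for (i in seq_len(10)) {
    nonwt <- setdiff(titeseq:::AA_ALPHABET, wt[i])
    dperm[i, nonwt] <- dm[i, sample(nonwt)]
  }
  expect_equal(sensitivity_profile(synthetic_matrix(r1, dperm))$s_k, brute)
})

test_that("the additive model reproduces single mutants exactly and sums multi-mutants", {
  r1 <- variable_region("1H"); r3 <- variable_region("3H")
  d1 <- random_deltas(r1, seed = 60); d3 <- random_deltas(r3, seed = 61)
  m1 <- synthetic_matrix(r1, d1); m3 <- synthetic_matrix(r3, d3)
  wt_kd <- -8.92
  expect_equal(predict_log10_kd(list(m1, m3), list(r1$wt_aa, r3$wt_aa), wt_kd),
               wt_kd)
  single <- "TFSDYWINWV"
  expect_equal(predict_log10_kd(list(m1, m3), list(single, r3$wt_aa), wt_kd),
               wt_kd + m1["34", "I"])
  double3 <- "GAYYGMDYCG"  # S101A, W108C against GSYYGMDYWG
  manual <- wt_kd + d3[2, "A"] + d3[9, "C"]
  expect_equal(predict_log10_kd(list(m1, m3), list(r1$wt_aa, double3), wt_kd),
               manual)
  expect_error(predict_log10_kd(list(m1), list("TFSDYWMNWB"), wt_kd),
               "unknown amino acid")
})

test_that("random multi-mutant fractions agree with exhaustive enumeration", {
  r1 <- variable_region("1H")
  d <- random_deltas(r1, seed = 70)
  m <- synthetic_matrix(r1, d)
  wt <- strsplit(r1$wt_aa, "")[[1]]
  wt_kd <- -8.92
  expect_equal(random_multimutant_fraction(m, wt_kd, 2, 500, Inf, seed = 1), 1)
  zero <- synthetic_matrix(r1, matrix(0, 10, 20,
    dimnames = list(NULL, titeseq:::AA_ALPHABET)))
  expect_equal(random_multimutant_fraction(zero, wt_kd, 2, 500, wt_kd - 1,
                                           seed = 1), 0)
  # exhaustive double-mutant distribution
  nonwt <- lapply(seq_len(10), function(i)
    d[i, setdiff(titeseq:::AA_ALPHABET, wt[i])])
  sums <- c()
  for (i in 1:9) for (j in (i + 1):10)
    sums <- c(sums, as.vector(outer(nonwt[[i]], nonwt[[j]], "+")))
  thr <- wt_kd + stats::quantile(sums, 0.2)
  exact <- mean(wt_kd + sums <= thr)
  n_mc <- 2e4
  mc <- random_multimutant_fraction(m, wt_kd, 2, n_mc, thr, seed = 7)
  se <- sqrt(exact * (1 - exact) / n_mc)
  expect_lt(abs(mc - exact), 3 * se)
  # law of large numbers: standard error halves when samples quadruple
  reps <- function(ns) vapply(1:40, function(s)
    random_multimutant_fraction(m, wt_kd, 2, ns, thr, seed = 100 + s),
    numeric(1))
  expect_equal(sd(reps(4000)) / sd(reps(1000)), 0.5, tolerance = 0.3)
})

test_that("full-pipeline effect matrices recover simulated ground truth", {
  r1 <- variable_region("1H")
  singles <- enumerate_single_codon_variants(r1)
  aa_nonwt <- singles[singles$aa != r1$wt_aa, ]
  pick <- aa_nonwt[!duplicated(aa_nonwt$aa), ]       # one codon per substitution
  syn <- utils::head(singles[singles$aa == r1$wt_aa, ], 5)
  wt_kd <- -8.92
  d <- random_deltas(r1, seed = 81, sd = 1.2)
  wt <- strsplit(r1$wt_aa, "")[[1]]
  true_of <- function(aa_seq) {
    v <- strsplit(aa_seq, "")[[1]]
    i <- which(v != wt)
    min(max(wt_kd + d[i, v[i]], -9.5), -5)
  }
  truth <- vapply(pick$aa, true_of, numeric(1))
  lib <- ground_truth_library(
    kd = 10^c(truth, rep(wt_kd, nrow(syn))),
    id = c(pick$id, syn$id))
  sim <- simulate_titeseq(lib, desk_design(), seed = 82)
  est <- fit_titeseq(sim)
  m <- build_effect_matrix(c(pick$aa, syn$aa), est$log10_kd, r1)
  truth_m <- build_effect_matrix(c(pick$aa, syn$aa), c(truth, rep(wt_kd, 5)),
                                 r1, wt_value = wt_kd)
  interior <- !is.na(truth_m) & truth_m + wt_kd > -9.2 & truth_m + wt_kd < -5.3
  rmse <- sqrt(mean((m[interior] - truth_m[interior])^2))
  expect_lte(rmse, 0.3)
})

test_that("enrichment ratios match hand arithmetic on a toy count table", {
  des <- sort_design(concentrations = c(0, 1e-7), cells_per_sort = 400,
                     reads_per_bin = 100)
  des$gates <- c(1, 2, 3)
  reads <- array(0, c(2, 2, 4))
  reads[1, 1, ] <- c(40, 20, 30, 10)
  reads[2, 1, ] <- c(10, 30, 20, 40)
  reads[1, 2, ] <- c(5, 5, 45, 45)
  reads[2, 2, ] <- c(45, 45, 5, 5)
  cellt <- matrix(100, 2, 4)
  readt <- apply(reads, c(2, 3), sum)
  sim <- structure(list(
    library = ground_truth_library(kd = c(1e-8, 1e-6), id = c("a", "b")),
    design = des, affinity_reads = reads,
    cell_totals = cellt, read_totals = readt), class = "titeseq_sim")
  rho <- enrichment_diagnostic(sim, log10_kd = c(-8, -6))
  enr <- attr(rho, "enrichment")
  # re-weighted count = reads * cells_in_bin / reads_in_bin; bin totals are
  # equal here, so ratios reduce to raw (bins 2+3)/(bins 0+1)
  expect_equal(unname(enr[1, 1]), (30 + 10) / (40 + 20))
  expect_equal(unname(enr[2, 1]), (20 + 40) / (10 + 30))
  expect_equal(unname(enr[1, 2]), (45 + 45) / (5 + 5))
})

test_that("region comparison tests match exact and simulation oracles", {
  x <- rnorm(20)
  # ties force the normal approximation; p is 1 up to continuity correction
  expect_gt(suppressWarnings(compare_regions(x, x, test = "rank-location")),
            0.95)
  # completely separated groups: one-sided exact tail = 1 / choose(20, 10)
  p_sep <- compare_regions(1:10, 11:20, test = "rank-location",
                           alternative = "less")
  expect_equal(p_sep, 1 / choose(20, 10))
  expect_error(compare_regions(1, 2, test = "variance-homogeneity"), ">= 2")
  # Levene against a hand-rolled anova on absolute deviations from group means
  withr::with_seed(91, {
    a <- rnorm(30, sd = 1); b <- rnorm(25, sd = 2)
  })
  p_lev <- compare_regions(a, b, test = "variance-homogeneity")
  dev <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(c("a", "b"), c(30, 25)))
  p_manual <- stats::anova(stats::lm(dev ~ g))[1, "Pr(>F)"]
  expect_equal(p_lev, p_manual)
  # null calibration: p-values uniform under equal variances
  withr::with_seed(92, {
    ps <- vapply(1:1000, function(i)
      compare_regions(rnorm(25), rnorm(25), test = "variance-homogeneity"),
      numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
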