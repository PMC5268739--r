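test_that("the default design accounts for 48 sorted bins", {
  des <- sort_design()
  expect_equal(length(des$concentrations), 11L)
  expect_equal(des$concentrations[1], 0)
  expect_equal(des$concentrations[-1], 10^seq(-9.5, -5, by = 0.5))
  expect_equal(n_sorted_bins(des), 48L)
})

test_that("quantile gate calibration matches analytic quantiles", {
  withr::with_seed(21, {
    u <- runif(2e5)
    g <- gates_from_fluorescence(u)
    expect_equal(g, c(0.25, 0.5, 0.75), tolerance = 0.01)
    expect_length(gates_from_fluorescence(u, probs = 0.5), 1L)
    # log-normal population: quantiles are 10^(mu + sd * z_p)
    ln <- 10^rnorm(2e5, mean = 2, sd = 0.4)
    g2 <- gates_from_fluorescence(ln)
    expect_equal(log10(g2), 2 + 0.4 * qnorm(c(0.25, 0.5, 0.75)),
                 tolerance = 0.01)
    expect_error(gates_from_fluorescence(rep(1, 100)), "degenerate")
  })
})

test_that("sorting conserves cells exactly and is seed-deterministic", {
  lib <- random_library(20, seed = 5)
  des <- desk_design()
  des$gates <- default_gates(lib, des, seed = 9)
  cc <- simulate_sort(lib, des, conc = 1e-7, seed = 33)
  expect_equal(sum(cc), des$cells_per_sort)
  expect_identical(cc, simulate_sort(lib, des, conc = 1e-7, seed = 33))
  expect_error(simulate_sort(lib[0, ], des, 1e-7), "empty")
})

test_that("a noiseless single-variant sort lands every cell in the median's bin", {
  lib <- ground_truth_library(kd = 1e-7, amplitude = 100, background = 10)
  des <- desk_design()
  des$gates <- c(30, 90, 200)  # median at c = KD is 60: strictly inside bin 1
  cc <- simulate_sort(lib, des, conc = 1e-7, noise = noise_model(1e-5),
                      seed = 2)
  expect_equal(unname(cc[1, 2]), sum(cc))
})

test_that("cells split between equally abundant variants as a fair binomial", {
  lib <- ground_truth_library(kd = c(1e-8, 1e-6))
  des <- desk_design(depth = 0.25)  # 1e6 cells
  des$gates <- c(30, 90, 200)
  cc <- simulate_sort(lib, des, conc = 0, seed = 8)
  n <- sum(cc)
  expect_true(abs(sum(cc[1, ]) - n / 2) <= 4 * sqrt(n * 0.25))
})

test_that("empirical mean bin number tracks the forward model across the ladder", {
  p <- binding_params(10^-8.9, 100, 10)
  lib <- ground_truth_library(kd = p$kd, amplitude = p$amplitude,
                              background = p$background)
  des <- desk_design(depth = 0.25)
  des$gates <- c(25, 60, 140)
  nm <- noise_model(0.5)
  for (cc in c(0, 10^c(-9.5, -8.5, -7.5, -6.5, -5))) {
    counts <- simulate_sort(lib, des, cc, nm, seed = round(1e6 * (cc + 1)))
    n <- sum(counts)
    emp <- sum((seq_len(ncol(counts)) - 1) * counts[1, ]) / n
    pr <- bin_probabilities(p, nm, cc, des$gates)
    mu <- mean_bin_number(pr)
    se <- sqrt(max(sum((seq_along(pr) - 1)^2 * pr) - mu^2, 1e-12) / n)
    expect_true(abs(emp - mu) <= 4 * se)
  }
})

test_that("sequencing with perfect recovery and reads = cells reproduces totals exactly", {
  withr::with_seed(3, {
    cells <- matrix(rpois(8, 500), 2, 4)
  })
  des <- sort_design(recovery_efficiency = 1)
  reads <- simulate_sequencing(cells, des, seed = 4,
                               reads_per_bin = colSums(cells))
  expect_equal(colSums(reads), colSums(cells))
  # zero recovery yields an all-zero table
  des0 <- sort_design()
  des0$recovery_efficiency <- 0
  expect_true(all(simulate_sequencing(cells, des0, seed = 4) == 0))
})

test_that("the recovery bottleneck inflates read-count variance like a two-stage draw", {
  # two variants, equal cells per bin; read share of variant 1 fluctuates
  # with the binomially thinned clone counts, not just multinomial sampling
  cells <- matrix(c(10000, 10000), 1, 2)
  cells2 <- rbind(c(10000, 0), c(10000, 0))  # one bin, two variants
  des <- sort_design(recovery_efficiency = 0.1)
  n_reads <- 1e4
  reps <- 300
  ours <- withr::with_seed(11, vapply(seq_len(reps), function(i)
    simulate_sequencing(cells2, des, reads_per_bin = c(n_reads, 0))[1, 1],
    numeric(1)))
  oracle <- withr::with_seed(12, vapply(seq_len(reps), function(i) {
    rec <- rbinom(2, 10000, 0.1)           # stage 1: recovery bottleneck
    rmultinom(1, n_reads, rec / sum(rec))[1]  # stage 2: sequencing
  }, numeric(1)))
  v_multinomial <- n_reads * 0.5 * 0.5
  expect_gt(var(ours), 3 * v_multinomial)
  expect_lt(abs(var(ours) - var(oracle)) / var(oracle), 0.5)
  expect_equal(mean(ours) / n_reads, 0.5, tolerance = 0.02)
})

test_that("the expression sort orders variants by their expression multiplier", {
  lib <- ground_truth_library(kd = rep(1e-7, 4),
                              expression = c(0, 0.5, 1, 2))
  des <- desk_design(depth = 0.25)
  cc <- simulate_expression_sort(lib, des, noise_model(0.3), seed = 6)
  mb <- sapply(seq_len(4), function(v)
    sum((seq_len(ncol(cc)) - 1) * cc[v, ]) / sum(cc[v, ]))
  expect_true(all(diff(mb) > 0))
  # a null clone falls entirely in bin 0 for gates above zero signal
  expect_equal(unname(cc[1, 1]), sum(cc[1, ]))
  # identical multipliers share one expected bin distribution
  lib2 <- ground_truth_library(kd = c(1e-8, 1e-6), expression = 1)
  cc2 <- simulate_expression_sort(lib2, des, noise_model(0.3), seed = 7)
  p1 <- cc2[1, ] / sum(cc2[1, ]); p2 <- cc2[2, ] / sum(cc2[2, ])
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("a full simulated dataset is reproducible and self-consistent", {
  lib <- random_library(15, seed = 44, is_wt_syn = c(TRUE, rep(FALSE, 14)))
  des <- desk_design(depth = 0.002)
  s1 <- simulate_titeseq(lib, des, seed = 100)
  s2 <- simulate_titeseq(lib, des, seed = 100)
  expect_identical(s1$affinity_reads, s2$affinity_reads)
  expect_identical(s1$expression_reads, s2$expression_reads)
  # conservation: every concentration sort holds exactly cells_per_sort cells
  expect_true(all(rowSums(s1$cell_totals) == des$cells_per_sort))
  df <- as.data.frame(s1)
  expect_equal(sum(df$reads), sum(s1$affinity_reads) + sum(s1$expression_reads))
})
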