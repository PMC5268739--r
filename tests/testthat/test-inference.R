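test_that("the ML fitter inverts noiseless expected counts to within 0.01 decades", {
  des <- sort_design()
  des$gates <- c(25, 60, 140)
  nm <- noise_model(0.5)
  for (lkd in c(-8.5, -7.0, -6.0)) {
    p <- binding_params(10^lkd, 100, 10)
    counts <- t(vapply(des$concentrations, function(cc)
      1e6 * bin_probabilities(p, nm, cc, des$gates),
      numeric(4)))
    fit <- fit_titration_ml(counts, des, nm)
    expect_equal(fit$log10_kd, lkd, tolerance = 0.01)
    expect_equal(fit$censored, "none")
  }
})

test_that("an affinity beyond the lower detection limit is censored there", {
  des <- sort_design()
  des$gates <- c(25, 60, 140)
  nm <- noise_model(0.5)
  p <- binding_params(1e-11, 100, 10)
  counts <- t(vapply(des$concentrations, function(cc)
    1e6 * bin_probabilities(p, nm, cc, des$gates), numeric(4)))
  fit <- fit_titration_ml(counts, des, nm)
  expect_equal(fit$censored, "low")
  expect_equal(fit$log10_kd, -9.5, tolerance = 2e-3)
  expect_error(fit_titration_ml(matrix(0, 11, 4), des, nm), "insufficient")
})

test_that("the mean-signal fitter inverts an exact isotherm to three decimals", {
  des <- sort_design()
  p <- binding_params(10^-8.61, amplitude = 2.4, background = 0.3)
  signal <- mean_fluorescence(p, des$concentrations)
  fit <- fit_titration_meanbin(signal, des)
  expect_equal(fit$log10_kd, -8.61, tolerance = 1e-3)
  expect_equal(fit$amplitude, 2.4, tolerance = 1e-3)
  expect_equal(fit$censored, "none")
  # a flat curve carries no binding signal
  flat <- fit_titration_meanbin(rep(1.7, 11), des)
  expect_equal(flat$censored, "high")
  expect_lt(flat$amplitude, 1e-6)
  expect_error(fit_titration_meanbin(c(1, 2, NA, rep(NA, 8)), des), ">= 3")
})

test_that("the classed fit exposes the standard modelling methods", {
  des <- sort_design()
  p <- binding_params(10^-7.2, amplitude = 2.1, background = 0.4)
  signal <- mean_fluorescence(p, des$concentrations)
  fit <- fit_titration_meanbin(signal, des)
  expect_s3_class(fit, "titration_fit")
  expect_named(coef(fit), c("log10_kd", "amplitude", "background"))
  expect_equal(unname(coef(fit)["log10_kd"]), -7.2, tolerance = 1e-3)
  expect_equal(predict(fit), signal, tolerance = 1e-3)
  expect_equal(residuals(fit), signal - predict(fit))
  expect_output(print(fit), "log10 KD")
  expect_output(print(summary(fit)), "concentration")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("ML and mean-bin estimates agree on interior affinities from simulated data", {
  lib <- random_library(60, seed = 202, lo = -9, hi = -5.5)
  sim <- simulate_titeseq(lib, desk_design(), seed = 203)
  ml <- fit_titeseq(sim, method = "ml")
  mb <- fit_titeseq(sim, method = "meanbin")
  ok <- ml$censored == "none" & mb$censored == "none"
  expect_gt(sum(ok), 30)
  expect_gt(cor(ml$log10_kd[ok], mb$log10_kd[ok]), 0.9)
})

test_that("expression scores normalize the synonymous-WT pool to 1 and track multipliers", {
  wt_pool <- rbind(c(5, 10, 40, 45), c(4, 11, 39, 46), c(6, 9, 41, 44))
  pooled_mb <- mean(apply(wt_pool, 1, function(x)
    sum((seq_along(x) - 1) * x) / sum(x)))
  same <- expression_score(c(10, 20, 80, 90), wt_pool)
  expect_equal(same$e_value * pooled_mb,
               sum(0:3 * c(10, 20, 80, 90)) / 200)
  # identical distribution to the pool mean: E = 1
  avg <- colMeans(wt_pool / rowSums(wt_pool))
  expect_equal(expression_score(1000 * avg, rbind(avg, avg))$e_value, 1,
               tolerance = 1e-12)
  expect_equal(expression_score(c(100, 0, 0, 0), wt_pool)$e_value, 0)
  expect_error(expression_score(c(0, 0, 0, 0), wt_pool), "no reads")
  expect_error(expression_score(c(1, 0, 0, 0), wt_pool * 0), "pool")
})

test_that("simulated expression multipliers are recovered in rank order", {
  withr::with_seed(301, {
    mult <- c(rep(1, 5), runif(25, 0.2, 2))
  })
  lib <- random_library(30, seed = 302, expression = mult,
                        is_wt_syn = c(rep(TRUE, 5), rep(FALSE, 25)))
  sim <- simulate_titeseq(lib, desk_design(depth = 0.02), seed = 303)
  est <- fit_titeseq(sim, variants = lib$id, min_reads = 1e9)  # scores only
  rho <- cor(est$e_value, mult, method = "spearman", use = "complete.obs")
  expect_gte(rho, 0.95)
  expect_equal(mean(est$e_value[lib$is_wt_syn]), 1, tolerance = 1e-9)
})

test_that("replicate aggregation reproduces hand-checked replicate arithmetic", {
  agg <- aggregate_replicates(c(-9.18, -9.18, -9.18))
  expect_equal(agg$log10_kd, -9.18)
  expect_equal(agg$stderr, 0)
  one <- aggregate_replicates(-9.28)
  expect_equal(one$log10_kd, -9.28)
  expect_true(is.na(one$stderr))
  # replicate scatter quoted as the across-replicate SD
  wtlike <- aggregate_replicates(c(-8.8, -9.0, -8.96))
  expect_equal(wtlike$log10_kd, -8.92)
  expect_equal(wtlike$stderr, sd(c(-8.8, -9.0, -8.96)))
  expect_equal(wtlike$stderr, 0.106, tolerance = 0.005)
  cens <- aggregate_replicates(c(-9.5, -9.4), censored = c("low", "none"))
  expect_equal(cens$censored, "low")
  expect_error(aggregate_replicates(numeric(0)), "no estimates")
})

test_that("fitted KD shifts decade-for-decade with a horizontal shift of the curve", {
  des <- sort_design()
  base <- binding_params(10^-7.5, amplitude = 2, background = 0.2)
  s0 <- mean_fluorescence(base, des$concentrations)
  f0 <- fit_titration_meanbin(s0, des)
  shifted <- binding_params(10^-6.5, amplitude = 2, background = 0.2)
  f1 <- fit_titration_meanbin(mean_fluorescence(shifted, des$concentrations),
                              des)
  expect_equal(f1$log10_kd - f0$log10_kd, 1, tolerance = 0.02)
})
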