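# Inverse problem: per-variant dissociation constants from binned read
# counts across the concentration ladder, and per-variant expression scores
# from the expression sort. The likelihood is a product over concentrations
# of multinomial bin-count likelihoods with probabilities from the gated
# log-normal forward model; optimization is a deterministic coarse grid over
# log10 KD with the amplitude and background profiled out, followed by local
# refinement. No random restarts, so fits are exactly reproducible.

# Re-weight read counts so read proportions reflect cell proportions:
# each (concentration, bin) cell count is scaled by
# (cells sorted into that bin) / (reads obtained from that bin).
reweight_counts <- function(counts, cell_totals, read_totals) {
  w <- counts * ifelse(read_totals > 0, cell_totals / read_totals, 0)
  # keep the effective evidence comparable to the raw read counts per
  # concentration so that likelihood sharpness is not inflated
  rs_raw <- rowSums(counts)
  rs_w <- rowSums(w)
  scale <- ifelse(rs_w > 0, rs_raw / rs_w, 0)
  w * scale
}

# Rough log10-fluorescence "center" of each bin, used only to initialize the
# amplitude/background profile.
bin_log10_centers <- function(gates) {
  lg <- log10(gates)
  gap <- if (length(lg) > 1) mean(diff(lg)) else 1
  c(lg[1] - gap / 2,
    if (length(lg) > 1) (lg[-1] + lg[-length(lg)]) / 2,
    lg[length(lg)] + gap / 2)
}

ml_negloglik <- function(theta, conc, w, gates, log_sd) {
  kd <- 10^theta[1]; a <- 10^theta[2]; b <- 10^theta[3]
  f <- a * conc / (conc + kd) + b
  p <- bin_prob_matrix(log10(f), log_sd, gates)
  -sum(w * log(pmax(p, 1e-300)))
}

#' Maximum-likelihood titration fit for one variant
#'
#' Fits \eqn{(\log_{10} K_D, A, B)} to the per-(concentration, bin) read
#' counts of a single variant by maximizing the summed multinomial
#' log-likelihood under the gated log-normal forward model.
#' \eqn{\log_{10} K_D} is box-constrained to the sensitivity window; an
#' estimate at a window edge is flagged censored (`"low"` / `"high"`). When
#' per-bin cell and read totals are supplied, counts are re-weighted so read
#' proportions reflect cell proportions.
#'
#' @param counts Numeric matrix of reads, concentrations x bins (rows in the
#'   order of `design$concentrations`).
#' @param design A [sort_design()] with `gates` set.
#' @param noise A [noise_model()]; `log_sd` is treated as known (shared
#'   across variants).
#' @param window A [sensitivity_window()].
#' @param cell_totals,read_totals Optional concentration x bin totals used
#'   for cell-fraction re-weighting.
#' @param grid_step Coarse grid step over log10 KD (default 0.25).
#' @return An object of class `titration_fit`.
#' @seealso [fit_titration_meanbin()], [fit_titeseq()]
#' @export
fit_titration_ml <- function(counts, design, noise = noise_model(),
                             window = sensitivity_window(),
                             cell_totals = NULL, read_totals = NULL,
                             grid_step = 0.25) {
  stopifnot(inherits(design, "sort_design"), inherits(noise, "fluor_noise"))
  counts <- as.matrix(counts)
  conc <- design$concentrations
  if (nrow(counts) != length(conc))
    stop("counts must have one row per concentration")
  gates <- design$gates
  if (is.null(gates)) stop("design gates are not set")
  w <- if (!is.null(cell_totals) && !is.null(read_totals))
    reweight_counts(counts, cell_totals, read_totals) else counts
  if (sum(rowSums(w) > 0) < 2L)
    stop("insufficient reads: need nonzero counts at >= 2 concentrations")

  log_sd <- noise$log_sd
  lo <- log10(window$kd_min); hi <- log10(window$kd_max)
  centers <- bin_log10_centers(gates)
  rs <- rowSums(w)
  l10f_obs <- as.vector(w %*% centers) / ifelse(rs > 0, rs, NA_real_)
  lb0 <- min(l10f_obs, na.rm = TRUE)
  la0 <- log10(max(10^max(l10f_obs, na.rm = TRUE) - 10^lb0, 10^lb0 / 10))

  grid <- seq(lo, hi, by = grid_step)
  best <- NULL
  for (lk in grid) {
    opt <- stats::optim(c(la0, lb0), function(ab)
      ml_negloglik(c(lk, ab), conc, w, gates, log_sd),
      method = "Nelder-Mead", control = list(maxit = 120, reltol = 1e-7))
    if (is.null(best) || opt$value < best$value)
      best <- list(value = opt$value, par = c(lk, opt$par))
  }
  ref <- stats::optim(best$par, ml_negloglik, conc = conc, w = w,
                      gates = gates, log_sd = log_sd,
                      method = "L-BFGS-B",
                      lower = c(lo, -6, -6), upper = c(hi, 8, 8),
                      control = list(maxit = 200))
  par <- if (ref$value <= best$value) ref$par else best$par
  val <- min(ref$value, best$value)
  censored <- if (par[1] <= lo + 1e-3) "low"
              else if (par[1] >= hi - 1e-3) "high" else "none"
  new_titration_fit(
    log10_kd = unname(par[1]), amplitude = unname(10^par[2]),
    background = unname(10^par[3]), censored = censored,
    loglik = -val, method = "ml", design = design, noise = noise,
    window = window, counts = counts, weights = w,
    signal = mean_bin_rows(w), n_reads = sum(counts))
}

# Weighted least-squares profile of (A, B) at fixed KD; the model is linear
# in (A, B) given KD. A is constrained nonnegative.
meanbin_profile <- function(lk, conc, s, wts) {
  x <- conc / (conc + 10^lk)
  fit <- stats::lm.wfit(cbind(1, x), s, wts)
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  if (is.na(a) || a < 0) {
    b <- sum(wts * s) / sum(wts); a <- 0
  }
  rss <- sum(wts * (s - (a * x + b))^2)
  list(a = a, b = b, rss = rss)
}

#' Least-squares titration fit to a mean-signal curve
#'
#' Fits the binding isotherm `signal = A * c / (c + KD) + B` to one mean
#' signal per concentration by (weighted) least squares, profiling the
#' linear parameters (A, B) over a deterministic log10 KD grid with local
#' refinement. The signal may be a sequencing-derived mean bin number or a
#' median fluorescence from clonal flow cytometry; the same fitter serves
#' both. A fit with no concentration dependence (A ~ 0) is flagged censored
#' `"high"` (no detectable binding).
#'
#' @param signal Numeric vector, one value per concentration (`NA` allowed).
#' @param design A [sort_design()] (only `concentrations` is used).
#' @param window A [sensitivity_window()].
#' @param weights Optional nonnegative weights per concentration.
#' @param grid_step Profile grid step over log10 KD (default 0.1).
#' @return An object of class `titration_fit`.
#' @export
fit_titration_meanbin <- function(signal, design,
                                  window = sensitivity_window(),
                                  weights = NULL, grid_step = 0.1) {
  stopifnot(inherits(design, "sort_design"))
  conc <- design$concentrations
  if (length(signal) != length(conc))
    stop("signal must have one value per concentration")
  weights <- weights %||% rep(1, length(signal))
  keep <- is.finite(signal) & weights > 0
  if (sum(keep) < 3L) stop("need >= 3 concentrations with usable signal")
  conc_k <- conc[keep]; s_k <- signal[keep]; w_k <- weights[keep]

  lo <- log10(window$kd_min); hi <- log10(window$kd_max)
  grid <- seq(lo, hi, by = grid_step)
  rss <- vapply(grid, function(lk) meanbin_profile(lk, conc_k, s_k, w_k)$rss,
                numeric(1))
  i <- which.min(rss)
  bracket <- c(max(lo, grid[i] - grid_step), min(hi, grid[i] + grid_step))
  opt <- stats::optimize(function(lk)
    meanbin_profile(lk, conc_k, s_k, w_k)$rss,
    interval = bracket, tol = 1e-6)
  lk <- if (opt$objective <= rss[i]) opt$minimum else grid[i]
  prof <- meanbin_profile(lk, conc_k, s_k, w_k)
  censored <- if (prof$a < 1e-6) "high"
              else if (lk <= lo + 1e-3) "low"
              else if (lk >= hi - 1e-3) "high" else "none"
  if (prof$a < 1e-6) lk <- hi
  new_titration_fit(
    log10_kd = unname(lk), amplitude = unname(prof$a),
    background = unname(prof$b), censored = censored,
    loglik = NA_real_, method = "meanbin", design = design, noise = NULL,
    window = window, counts = NULL, weights = weights,
    signal = signal, n_reads = NA_real_, rss = prof$rss)
}

new_titration_fit <- function(...) {
  structure(list(...), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  tag <- switch(x$censored, low = " (censored: lower limit)",
                high = " (censored: upper limit)", "")
  cat(sprintf("Titration fit (%s): log10 KD = %.3f%s, A = %.3g, B = %.3g\n",
              x$method, x$log10_kd, tag, x$amplitude, x$background))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  c(log10_kd = object$log10_kd, amplitude = object$amplitude,
    background = object$background)
}

#' @export
logLik.titration_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, class = "logLik")
}

#' Predicted signal of a titration fit
#'
#' @param object A `titration_fit`.
#' @param conc Concentrations at which to predict (default the design
#'   ladder).
#' @param type `"signal"` (mean bin number for ML and mean-bin fits),
#'   `"fluorescence"` (isotherm median fluorescence; ML fits only) or
#'   `"probabilities"` (bin probability matrix; ML fits only).
#' @param ... Unused.
#' @return Numeric vector (or matrix for `"probabilities"`).
#' @export
predict.titration_fit <- function(object,
                                  conc = object$design$concentrations,
                                  type = c("signal", "fluorescence",
                                           "probabilities"), ...) {
  type <- match.arg(type)
  kd <- 10^object$log10_kd
  if (object$method == "meanbin") {
    if (type != "signal")
      stop("mean-signal fits predict only type = 'signal'")
    return(object$amplitude * conc / (conc + kd) + object$background)
  }
  f <- object$amplitude * conc / (conc + kd) + object$background
  if (type == "fluorescence") return(f)
  p <- bin_prob_matrix(log10(f), object$noise$log_sd, object$design$gates)
  if (type == "probabilities") return(p)
  as.vector(p %*% (seq_len(ncol(p)) - 1L))
}

#' @export
residuals.titration_fit <- function(object, ...) {
  object$signal - predict(object)
}

#' @export
summary.titration_fit <- function(object, ...) {
  out <- list(fit = object,
              table = data.frame(
                concentration = object$design$concentrations,
                observed = object$signal,
                fitted = predict(object)))
  class(out) <- "summary.titration_fit"
  out
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  print(x$fit)
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a titration fit
#'
#' Observed signal against antigen concentration (log axis; the 0 M point is
#' drawn at the left edge), with the fitted binding curve and a vertical line
#' at the inferred KD.
#'
#' @param x A `titration_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.titration_fit <- function(x, ...) {
  conc <- x$design$concentrations
  pos <- conc > 0
  edge <- min(conc[pos]) / 10
  xs <- ifelse(pos, conc, edge)
  graphics::plot(xs, x$signal, log = "x", xlab = "antigen concentration [M]",
                 ylab = "mean bin number", ...)
  cg <- 10^seq(log10(edge), log10(max(conc)), length.out = 120)
  graphics::lines(cg, predict(x, conc = cg))
  if (x$censored == "none")
    graphics::abline(v = 10^x$log10_kd, lty = 2)
  invisible(x)
}

#' Expression score of one variant
#'
#' The variant's expression-sort mean bin number divided by the mean of the
#' same quantity over the synonymous-WT pool, so that the WT-synonymous mean
#' is exactly 1.
#'
#' @param variant_counts Read-count vector over expression bins for the
#'   variant.
#' @param wt_counts Matrix of expression-bin counts for the synonymous-WT
#'   variants (one row each), or a single count vector.
#' @return A list with `e_value`, a delta-method `stderr`, and `n_reads`.
#' @export
expression_score <- function(variant_counts, wt_counts) {
  n <- sum(variant_counts)
  if (n <= 0) stop("no reads for this variant in the expression sort")
  if (is.null(dim(wt_counts))) wt_counts <- matrix(wt_counts, nrow = 1)
  wt_ok <- rowSums(wt_counts) > 0
  if (!any(wt_ok)) stop("no reads in the WT-synonymous pool")
  m_wt <- mean(mean_bin_rows(wt_counts[wt_ok, , drop = FALSE]))
  if (m_wt <= 0) stop("WT-synonymous pool has zero mean bin number")
  p <- variant_counts / n
  b <- seq_along(variant_counts) - 1
  m <- sum(b * p)
  v <- (sum(b^2 * p) - m^2) / n
  list(e_value = m / m_wt, stderr = sqrt(max(v, 0)) / m_wt, n_reads = n)
}

#' Aggregate replicate affinity estimates
#'
#' Mean and replicate error of log10 KD across replicate fits. The error is
#' the across-replicate standard deviation (the scatter quoted alongside
#' replicate-averaged KD values). Censored replicates enter at their
#' boundary value; the aggregate is flagged censored if any replicate is.
#'
#' @param estimates A list of `titration_fit` objects, or a numeric vector of
#'   log10 KD values.
#' @param censored Optional character vector of per-replicate censoring flags
#'   (used with a numeric `estimates`).
#' @return A list with `log10_kd` (mean), `stderr` (across-replicate SD;
#'   `NA` for a single replicate), `censored`, `n`.
#' @export
aggregate_replicates <- function(estimates, censored = NULL) {
  if (length(estimates) == 0L) stop("no estimates to aggregate")
  if (is.list(estimates) && inherits(estimates[[1]], "titration_fit")) {
    censored <- vapply(estimates, `[[`, character(1), "censored")
    estimates <- vapply(estimates, `[[`, numeric(1), "log10_kd")
  }
  censored <- censored %||% rep("none", length(estimates))
  flags <- setdiff(unique(censored), "none")
  list(log10_kd = mean(estimates),
       stderr = if (length(estimates) > 1) stats::sd(estimates) else NA_real_,
       censored = if (length(flags)) flags[1] else "none",
       n = length(estimates))
}

# Profile a shared log_sd over a subset of high-count variants by maximizing
# the summed ML log-likelihood on a coarse grid.
fit_global_log_sd <- function(sim, window, grid = seq(0.2, 0.8, by = 0.1),
                              n_variants = 20L) {
  tot <- apply(sim$affinity_reads, 1, sum)
  idx <- order(tot, decreasing = TRUE)[seq_len(min(n_variants, length(tot)))]
  ll <- vapply(grid, function(sd) {
    sum(vapply(idx, function(v) {
      fit <- try(fit_titration_ml(sim$affinity_reads[v, , ], sim$design,
                                  noise_model(sd), window,
                                  sim$cell_totals, sim$read_totals,
                                  grid_step = 0.5), silent = TRUE)
      if (inherits(fit, "try-error")) 0 else fit$loglik
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

#' Fit every variant of a simulated (or assembled) titration dataset
#'
#' Runs [fit_titration_ml()] (or the mean-bin least-squares path) on each
#' variant's read counts and, when expression-sort counts and a
#' synonymous-WT pool are available, computes expression scores normalized to
#' that pool.
#'
#' @param sim A `titeseq_sim` object (see [simulate_titeseq()]).
#' @param method `"ml"` or `"meanbin"`.
#' @param noise A [noise_model()] giving the (shared) log10 fluorescence
#'   spread, or `NULL` with `fit_log_sd = TRUE` to profile it globally from
#'   the data.
#' @param window A [sensitivity_window()].
#' @param fit_log_sd Profile a single shared `log_sd` from high-count
#'   variants before fitting (ML path only).
#' @param variants Optional subset of variant ids to fit.
#' @param min_reads Variants with fewer total affinity reads are skipped
#'   (`NA` estimates).
#' @return A data frame with one row per variant: `variant_id`, `log10_kd`,
#'   `censored`, `amplitude`, `background`, `loglik`, `n_reads`, and
#'   `e_value` / `e_stderr` when computable.
#' @export
fit_titeseq <- function(sim, method = c("ml", "meanbin"),
                        noise = noise_model(), window = sensitivity_window(),
                        fit_log_sd = FALSE, variants = NULL, min_reads = 10) {
  stopifnot(inherits(sim, "titeseq_sim"))
  method <- match.arg(method)
  ids <- variants %||% sim$library$id
  if (fit_log_sd && method == "ml")
    noise <- noise_model(fit_global_log_sd(sim, window))
  rows <- lapply(ids, function(id) {
    v <- match(id, sim$library$id)
    counts <- sim$affinity_reads[v, , , drop = TRUE]
    out <- data.frame(variant_id = id, log10_kd = NA_real_,
                      censored = NA_character_, amplitude = NA_real_,
                      background = NA_real_, loglik = NA_real_,
                      n_reads = sum(counts), stringsAsFactors = FALSE)
    if (sum(counts) < min_reads) return(out)
    fit <- try(switch(method,
      ml = fit_titration_ml(counts, sim$design, noise, window,
                            sim$cell_totals, sim$read_totals),
      meanbin = fit_titration_meanbin(
        mean_bin_rows(reweight_counts(counts, sim$cell_totals,
                                      sim$read_totals)),
        sim$design, window,
        weights = as.numeric(rowSums(counts) > 0))), silent = TRUE)
    if (inherits(fit, "try-error")) return(out)
    out$log10_kd <- fit$log10_kd
    out$censored <- fit$censored
    out$amplitude <- fit$amplitude
    out$background <- fit$background
    out$loglik <- fit$loglik
    out
  })
  est <- do.call(rbind, rows)
  wt_rows <- which(sim$library$is_wt_syn)
  if (length(wt_rows) > 0 && !is.null(sim$expression_reads)) {
    wt_counts <- sim$expression_reads[wt_rows, , drop = FALSE]
    es <- lapply(match(ids, sim$library$id), function(v) {
      tryCatch(expression_score(sim$expression_reads[v, ], wt_counts),
               error = function(e) list(e_value = NA_real_,
                                        stderr = NA_real_))
    })
    est$e_value <- vapply(es, `[[`, numeric(1), "e_value")
    est$e_stderr <- vapply(es, `[[`, numeric(1), "stderr")
  }
  est
}
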