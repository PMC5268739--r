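# Sequence-affinity landscape analyses built on per-variant estimates:
# single-substitution effect matrices (position-specific affinity matrices),
# per-position sensitivity statistics, the additive multi-mutant model,
# enrichment diagnostics, and the two between-region hypothesis tests.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Single-substitution effect matrix (position-specific affinity matrix)
#'
#' Builds the positions x 20 amino acid matrix of measured effects from
#' per-variant estimates: entry (i, a) is the mean, over synonymous codon
#' variants encoding that substitution, of `value - wt_value`. WT-residue
#' entries are exactly 0; unmeasured entries are `NA`. Censored estimates
#' are expected to enter at their boundary values (the fitter already clamps
#' them).
#'
#' @param aa_seqs Character vector of variant amino-acid sequences over the
#'   region window (single-substitution and synonymous-WT variants are used;
#'   others are ignored).
#' @param values Numeric estimate per variant (log10 KD, or expression
#'   score).
#' @param region A [variable_region()].
#' @param wt_value The WT value; when `NULL` it is taken as the mean value of
#'   the synonymous-WT variants present in the input.
#' @return A matrix of class `effect_matrix` (rows = antibody residue
#'   numbers, columns = amino acids), with attributes `wt_aa`, `wt_value`,
#'   `region` and `n` (per-entry variant counts).
#' @export
build_effect_matrix <- function(aa_seqs, values, region, wt_value = NULL) {
  stopifnot(inherits(region, "variable_region"),
            length(aa_seqs) == length(values))
  wt <- strsplit(region$wt_aa, "")[[1]]
  n_pos <- length(wt)
  if (is.null(wt_value)) {
    syn <- aa_seqs == region$wt_aa & is.finite(values)
    if (!any(syn)) stop("wt_value not given and no synonymous-WT variants present")
    wt_value <- mean(values[syn])
  }
  m <- matrix(NA_real_, n_pos, 20L,
              dimnames = list(region$residue_numbers, AA_ALPHABET))
  nmat <- matrix(0L, n_pos, 20L,
                 dimnames = dimnames(m))
  acc <- matrix(0, n_pos, 20L)
  for (k in seq_along(aa_seqs)) {
    if (!is.finite(values[k])) next
    v <- strsplit(aa_seqs[k], "")[[1]]
    if (length(v) != n_pos) next
    diffp <- which(v != wt)
    if (length(diffp) != 1L) next
    a <- match(v[diffp], AA_ALPHABET)
    if (is.na(a)) next
    acc[diffp, a] <- acc[diffp, a] + values[k]
    nmat[diffp, a] <- nmat[diffp, a] + 1L
  }
  m[nmat > 0] <- acc[nmat > 0] / nmat[nmat > 0] - wt_value
  m[cbind(seq_len(n_pos), match(wt, AA_ALPHABET))] <- 0
  structure(m, class = c("effect_matrix", "matrix"), wt_aa = region$wt_aa,
            wt_value = wt_value, region = region$name, n = nmat)
}

#' Per-position sensitivity profile
#'
#' For each position, the mean squared deviation from WT over the 19 non-WT
#' amino acids: \eqn{S_K(i) = \langle (\Delta \log_{10} K_D^{ia})^2
#' \rangle_{a|i}} and analogously \eqn{S_E(i)} for expression. `NA` entries
#' are excluded with the divisor reduced accordingly; a position with no
#' measured non-WT amino acid yields `NA` with a warning.
#'
#' @param kd_matrix An [build_effect_matrix()] result for log10 KD.
#' @param e_matrix Optional effect matrix for expression scores.
#' @return A data frame with `position` (residue numbers), `s_k`, and `s_e`
#'   (when `e_matrix` is given).
#' @export
sensitivity_profile <- function(kd_matrix, e_matrix = NULL) {
  stopifnot(inherits(kd_matrix, "effect_matrix"))
  one <- function(m) {
    wt <- strsplit(attr(m, "wt_aa"), "")[[1]]
    vapply(seq_len(nrow(m)), function(i) {
      vals <- m[i, setdiff(AA_ALPHABET, wt[i])]
      if (all(is.na(vals))) NA_real_ else mean(vals^2, na.rm = TRUE)
    }, numeric(1))
  }
  s_k <- one(kd_matrix)
  if (any(is.na(s_k)))
    warning("positions with no measured non-WT substitutions yield NA sensitivity")
  out <- data.frame(position = as.integer(rownames(kd_matrix)), s_k = s_k)
  if (!is.null(e_matrix)) {
    stopifnot(inherits(e_matrix, "effect_matrix"))
    out$s_e <- one(e_matrix)
  }
  out
}

#' Additive log10 KD prediction for arbitrary region sequences
#'
#' The WT log10 KD plus the sum of the matrix entries of every non-WT amino
#' acid in the supplied sequences; purely additive, no epistasis.
#'
#' @param matrices A list of effect matrices, one per region (e.g. CDR1H and
#'   CDR3H).
#' @param sequences A list of amino-acid sequences matched to `matrices`.
#' @param wt_log10_kd The WT log10 KD.
#' @return Predicted log10 KD (molar).
#' @export
predict_log10_kd <- function(matrices, sequences, wt_log10_kd) {
  if (inherits(matrices, "effect_matrix")) matrices <- list(matrices)
  if (is.character(sequences) && length(sequences) == length(matrices))
    sequences <- as.list(sequences)
  stopifnot(length(matrices) == length(sequences))
  total <- wt_log10_kd
  for (r in seq_along(matrices)) {
    m <- matrices[[r]]
    wt <- strsplit(attr(m, "wt_aa"), "")[[1]]
    v <- strsplit(sequences[[r]], "")[[1]]
    if (length(v) != nrow(m))
      stop("sequence length does not match the effect matrix")
    if (any(!v %in% AA_ALPHABET)) stop("unknown amino acid in sequence")
    for (i in which(v != wt)) {
      d <- m[i, v[i]]
      if (is.na(d)) stop("effect not measured for ", wt[i], i, v[i])
      total <- total + d
    }
  }
  unname(total)
}

#' Fraction of random multi-mutants at or below an affinity threshold
#'
#' Samples variants carrying `n_mutations` substitutions scattered uniformly
#' (positions without replacement across all regions, amino acids uniform
#' over the 19 non-WT residues), scores them with the additive model, and
#' returns the fraction with predicted log10 KD at or below `threshold`.
#'
#' @inheritParams predict_log10_kd
#' @param n_mutations Number of substitutions per sampled variant.
#' @param n_samples Number of variants to sample.
#' @param threshold log10 KD threshold (molar).
#' @param seed Integer seed or `NULL`.
#' @return The fraction in `[0, 1]`.
#' @export
random_multimutant_fraction <- function(matrices, wt_log10_kd, n_mutations,
                                        n_samples, threshold, seed = NULL) {
  if (inherits(matrices, "effect_matrix")) matrices <- list(matrices)
  # stack per-position vectors of non-WT effects across regions
  delta <- do.call(rbind, lapply(matrices, function(m) {
    wt <- strsplit(attr(m, "wt_aa"), "")[[1]]
    t(vapply(seq_len(nrow(m)), function(i)
      m[i, setdiff(AA_ALPHABET, wt[i])], numeric(19L)))
  }))
  if (anyNA(delta)) {
    warning("unmeasured effects treated as 0 in multi-mutant sampling")
    delta[is.na(delta)] <- 0
  }
  n_pos <- nrow(delta)
  if (n_mutations > n_pos)
    stop("n_mutations exceeds the number of positions")
  with_seed(seed, {
    sums <- vapply(seq_len(n_samples), function(k) {
      pos <- sample.int(n_pos, n_mutations)
      aa <- sample.int(19L, n_mutations, replace = TRUE)
      sum(delta[cbind(pos, aa)])
    }, numeric(1))
    mean(wt_log10_kd + sums <= threshold)
  })
}

#' Enrichment-versus-affinity diagnostic
#'
#' For each variant and concentration, the enrichment of re-weighted reads in
#' the high-fluorescence bins (2, 3) relative to the low bins (0, 1); then,
#' within groups of variants partitioned by measured log10 KD, the Spearman
#' rank correlation between enrichment and log10 KD at every concentration.
#' With informative data, correlations above the 0 M background band appear
#' only where the concentration is close to the group's KD (the diagonal
#' pattern); the 0 M row estimates the background.
#'
#' @param sim A `titeseq_sim` object (supplies reads and per-bin cell/read
#'   totals for the re-weighting).
#' @param log10_kd Per-variant measured log10 KD, aligned with
#'   `sim$library$id`.
#' @param group_breaks Interior group boundaries on log10 KD; the default
#'   half-decade marks give seven groups across the sensitivity window.
#' @return A matrix of Spearman rho, concentrations x groups, with attributes
#'   `groups` (cut labels), `enrichment` (the per-variant x concentration
#'   enrichment matrix) and `n_pseudocount` (number of zero-denominator
#'   enrichments padded with a pseudocount of 1).
#' @export
enrichment_diagnostic <- function(sim, log10_kd,
                                  group_breaks = seq(-9, -6.5, by = 0.5)) {
  stopifnot(inherits(sim, "titeseq_sim"))
  if (sim$design$n_bins != 4L)
    stop("the enrichment diagnostic is defined for a 4-bin design")
  nv <- nrow(sim$library); nc <- length(sim$design$concentrations)
  w <- array(0, dim(sim$affinity_reads))
  for (ci in seq_len(nc))
    w[, ci, ] <- reweight_counts(sim$affinity_reads[, ci, ],
                                 matrix(sim$cell_totals[ci, ], nv, 4,
                                        byrow = TRUE),
                                 matrix(sim$read_totals[ci, ], nv, 4,
                                        byrow = TRUE))
  hi <- w[, , 3] + w[, , 4]
  lo <- w[, , 1] + w[, , 2]
  n_pad <- sum(lo == 0 & hi > 0)
  lo[lo == 0] <- 1  # pseudocount for empty low bins
  enrich <- hi / lo
  grp <- cut(log10_kd, breaks = c(-Inf, group_breaks, Inf))
  rho <- matrix(NA_real_, nc, nlevels(grp),
                dimnames = list(
                  signif(sim$design$concentrations, 3), levels(grp)))
  for (g in seq_len(nlevels(grp))) {
    idx <- which(as.integer(grp) == g & is.finite(log10_kd))
    if (length(idx) < 3L) next
    for (ci in seq_len(nc)) {
      e <- enrich[idx, ci]
      if (stats::sd(e) == 0 || stats::sd(log10_kd[idx]) == 0) next
      rho[ci, g] <- stats::cor(e, log10_kd[idx], method = "spearman")
    }
  }
  structure(rho, groups = levels(grp),
            enrichment = structure(enrich,
                                   dimnames = list(sim$library$id, NULL)),
            n_pseudocount = n_pad)
}

#' Compare mutation-effect distributions between two regions
#'
#' Either a rank-location test (Mann-Whitney U / Wilcoxon rank-sum) or a
#' variance-homogeneity test (Levene's test, mean-centered). Censored KD
#' values are expected to enter at their boundary values.
#'
#' @param values_1,values_2 Numeric vectors of per-mutation effects for the
#'   two regions.
#' @param test `"rank-location"` or `"variance-homogeneity"`.
#' @param alternative Sidedness for the rank test (`"two.sided"`, `"less"`,
#'   `"greater"`; `values_1` vs `values_2`).
#' @return The p-value.
#' @export
compare_regions <- function(values_1, values_2,
                            test = c("rank-location",
                                     "variance-homogeneity"),
                            alternative = "two.sided") {
  test <- match.arg(test)
  if (length(values_1) == 0L || length(values_2) == 0L)
    stop("both groups must be nonempty")
  if (test == "rank-location") {
    stats::wilcox.test(values_1, values_2,
                       alternative = alternative)$p.value
  } else {
    if (length(values_1) < 2L || length(values_2) < 2L)
      stop("variance test needs >= 2 values per group")
    g <- factor(rep(c("r1", "r2"), c(length(values_1), length(values_2))))
    tab <- car::leveneTest(c(values_1, values_2), g, center = mean)
    tab[1, "Pr(>F)"]
  }
}
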