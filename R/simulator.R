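# Forward simulation of a sort-seq titration experiment: cells are allotted
# to variants by library abundance, each cell's fluorescence is log-normal
# around its variant's isotherm value, cells are gated into ordered bins,
# recovered with a post-sort bottleneck, and sequenced to a per-bin read
# budget. Per-variant bin counts are drawn multinomially with the gated
# log-normal bin probabilities, which is exactly equivalent to independent
# per-cell draws.

#' Sort experiment design
#'
#' Defaults describe one full titration experiment: eleven antigen
#' concentrations (0 M plus a half-decade ladder from 10^-9.5 to 10^-5 M),
#' four fluorescence bins per concentration sort plus a four-bin expression
#' sort (48 sorted bins in all), and sequencing of every bin.
#'
#' @param concentrations Molar antigen concentrations, ascending,
#'   nonnegative.
#' @param n_bins Number of sorting bins per sort (>= 2).
#' @param gates Fluorescence gate boundaries (length `n_bins - 1`), or `NULL`
#'   to calibrate from the simulated library (see [default_gates()]).
#' @param expression_gates Boundaries for the expression sort, or `NULL`.
#' @param cells_per_sort Cells sorted per concentration (and in the
#'   expression sort).
#' @param reads_per_bin Sequencing read budget per sorted bin.
#' @param recovery_efficiency Fraction of sorted cells whose sequence
#'   survives post-sort recovery (the dominant noise source), in (0, 1].
#' @return An object of class `sort_design`.
#' @export
sort_design <- function(concentrations = c(0, 10^seq(-9.5, -5, by = 0.5)),
                        n_bins = 4L,
                        gates = NULL,
                        expression_gates = NULL,
                        cells_per_sort = 4e6,
                        reads_per_bin = 2.6e6,
                        recovery_efficiency = 0.2) {
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (!is.null(gates)) {
    check_gates(gates)
    if (length(gates) != n_bins - 1L) stop("need n_bins - 1 gate boundaries")
  }
  if (!is.null(expression_gates)) check_gates(expression_gates)
  stopifnot_scalar(cells_per_sort, "cells_per_sort", positive = TRUE)
  stopifnot_scalar(reads_per_bin, "reads_per_bin", nonneg = TRUE)
  stopifnot_scalar(recovery_efficiency, "recovery_efficiency", positive = TRUE)
  if (recovery_efficiency > 1) stop("recovery_efficiency must be <= 1")
  structure(list(concentrations = concentrations, n_bins = as.integer(n_bins),
                 gates = gates, expression_gates = expression_gates,
                 cells_per_sort = cells_per_sort,
                 reads_per_bin = reads_per_bin,
                 recovery_efficiency = recovery_efficiency),
            class = "sort_design")
}

#' @export
print.sort_design <- function(x, ...) {
  cat(sprintf(paste0("Sort design: %d concentrations x %d bins + %d ",
                     "expression bins = %d sorted bins\n"),
              length(x$concentrations), x$n_bins, x$n_bins, n_sorted_bins(x)))
  cat(sprintf("  cells/sort %.3g, reads/bin %.3g, recovery %.2f\n",
              x$cells_per_sort, x$reads_per_bin, x$recovery_efficiency))
  invisible(x)
}

#' Total number of sorted bins in a design
#'
#' Concentration sorts times bins per sort, plus the expression-sort bins.
#'
#' @param design A [sort_design()].
#' @return Integer bin count (48 for the default design).
#' @export
n_sorted_bins <- function(design) {
  stopifnot(inherits(design, "sort_design"))
  length(design$concentrations) * design$n_bins + design$n_bins
}

#' Rescale a design's sequencing and sorting depth
#'
#' Multiplies cells per sort and reads per bin by `factor`, e.g. 0.01 for a
#' desk-scale run at 1/100 of full experimental depth.
#'
#' @param design A [sort_design()].
#' @param factor Positive scale factor (applied to cells and reads).
#' @param cells_factor,reads_factor Optional separate factors overriding
#'   `factor` for one of the two depths.
#' @return The rescaled `sort_design`.
#' @export
scale_design <- function(design, factor = 1, cells_factor = factor,
                         reads_factor = factor) {
  stopifnot(inherits(design, "sort_design"))
  design$cells_per_sort <- max(1, round(design$cells_per_sort * cells_factor))
  design$reads_per_bin <- round(design$reads_per_bin * reads_factor)
  design
}

#' Ground-truth variant library for simulation
#'
#' @param kd Per-variant dissociation constants, molar.
#' @param amplitude Saturating signal A (recycled).
#' @param background Background fluorescence B (recycled).
#' @param expression Expression multiplier; scales A and the expression-sort
#'   signal (recycled). 1 = WT-like.
#' @param abundance Library abundance weights (recycled; normalized to sum
#'   to 1).
#' @param id Variant identifiers (default `v0001`, ...).
#' @param dna,region Optional variant DNA and region label per variant
#'   (needed only for read emission).
#' @param is_wt_syn Logical: variant is a synonymous-WT clone (recycled);
#'   used to normalize expression scores.
#' @return A data frame of class `ground_truth`.
#' @export
ground_truth_library <- function(kd, amplitude = 100, background = 10,
                                 expression = 1, abundance = NULL, id = NULL,
                                 dna = NA_character_, region = NA_character_,
                                 is_wt_syn = FALSE) {
  n <- length(kd)
  if (n == 0L) stop("empty library")
  if (any(kd <= 0)) stop("kd must be > 0")
  abundance <- abundance %||% rep(1, n)
  if (any(abundance < 0) || sum(abundance) <= 0)
    stop("abundance weights must be nonnegative with positive sum")
  out <- data.frame(
    id = id %||% sprintf("v%04d", seq_len(n)),
    kd = kd,
    amplitude = rep_len(amplitude, n),
    background = rep_len(background, n),
    expression = rep_len(expression, n),
    abundance = rep_len(abundance, n) / sum(rep_len(abundance, n)),
    dna = rep_len(dna, n),
    region = rep_len(region, n),
    is_wt_syn = rep_len(is_wt_syn, n),
    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

# log10 median fluorescence of every library variant at concentration conc;
# the expression multiplier scales the functional amplitude.
library_log10_f <- function(library, conc) {
  a <- library$amplitude * library$expression
  f <- a * conc / (conc + library$kd) + library$background
  ifelse(f > 0, log10(f), -Inf)
}

#' Gate boundaries from a fluorescence sample
#'
#' Boundaries at the requested quantiles of a fluorescence sample; errors if
#' the resulting boundaries are not strictly increasing (degenerate sample).
#'
#' @param fluorescence Positive fluorescence values.
#' @param probs Quantile probabilities (default quartiles).
#' @return Strictly increasing gate boundaries.
#' @export
gates_from_fluorescence <- function(fluorescence, probs = c(0.25, 0.5, 0.75)) {
  g <- unname(stats::quantile(fluorescence, probs))
  if (any(diff(g) <= 0))
    stop("degenerate fluorescence distribution: gates are not strictly increasing")
  g
}

#' Calibrate default gates from the simulated library
#'
#' Simulates single-cell fluorescence for the whole library at a calibration
#' concentration and places gates at the requested quantiles. The default
#' calibration concentration is the highest antigen concentration, where the
#' library spans background to saturation so that quartile gates tile the
#' full dynamic range; one gate set is then used across all concentrations.
#'
#' @param library A [ground_truth_library()].
#' @param design A [sort_design()].
#' @param noise A [noise_model()].
#' @param conc Calibration concentration (default `max(concentrations)`).
#' @param probs Quantile probabilities; default splits the calibration
#'   population into `n_bins` equal parts.
#' @param n_cells Cells to simulate for calibration.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return Strictly increasing gate boundaries (length `n_bins - 1`).
#' @export
default_gates <- function(library, design, noise = noise_model(),
                          conc = max(design$concentrations),
                          probs = seq_len(design$n_bins - 1L) / design$n_bins,
                          n_cells = 2e5, seed = NULL) {
  stopifnot(inherits(library, "ground_truth"), inherits(design, "sort_design"))
  with_seed(seed, {
    v <- sample.int(nrow(library), n_cells, replace = TRUE,
                    prob = library$abundance)
    l10 <- library_log10_f(library, conc)[v] +
      stats::rnorm(n_cells, 0, noise$log_sd)
    gates_from_fluorescence(10^l10, probs)
  })
}

#' Simulate one concentration sort
#'
#' Cells are assigned to variants multinomially by abundance; each variant's
#' cells fall into bins with the gated log-normal probabilities of its
#' binding curve at `conc`.
#'
#' @param library A [ground_truth_library()].
#' @param design A [sort_design()] whose `gates` are set.
#' @param conc Antigen concentration, molar.
#' @param noise A [noise_model()].
#' @param seed Integer seed or `NULL`.
#' @param cells Number of cells sorted (default `design$cells_per_sort`).
#' @return Integer matrix of cell counts, variants x bins.
#' @export
simulate_sort <- function(library, design, conc, noise = noise_model(),
                          seed = NULL, cells = design$cells_per_sort) {
  stopifnot(inherits(library, "ground_truth"), inherits(design, "sort_design"))
  if (nrow(library) == 0L) stop("empty library")
  gates <- design$gates
  if (is.null(gates)) stop("design gates are not set; see default_gates()")
  with_seed(seed, {
    n_v <- as.vector(stats::rmultinom(1, cells, library$abundance))
    p <- bin_prob_matrix(library_log10_f(library, conc), noise$log_sd, gates)
    counts <- matrix(0L, nrow(library), design$n_bins,
                     dimnames = list(library$id, NULL))
    nz <- which(n_v > 0)
    for (v in nz) counts[v, ] <- stats::rmultinom(1, n_v[v], p[v, ])
    counts
  })
}

#' Simulate sequencing of sorted bins
#'
#' Per bin, sorted cells are thinned binomially by the recovery efficiency,
#' then reads are drawn multinomially over the recovered clones up to the
#' bin's read budget. Bins with no recovered cells yield zero reads.
#'
#' @param cell_counts Integer matrix, variants x bins (from
#'   [simulate_sort()]).
#' @param design A [sort_design()].
#' @param seed Integer seed or `NULL`.
#' @param reads_per_bin Read budget per bin (scalar or per-bin vector).
#' @return Integer matrix of read counts, variants x bins.
#' @export
simulate_sequencing <- function(cell_counts, design, seed = NULL,
                                reads_per_bin = design$reads_per_bin) {
  stopifnot(inherits(design, "sort_design"))
  reads_per_bin <- rep_len(round(reads_per_bin), ncol(cell_counts))
  with_seed(seed, {
    reads <- matrix(0L, nrow(cell_counts), ncol(cell_counts),
                    dimnames = dimnames(cell_counts))
    for (b in seq_len(ncol(cell_counts))) {
      recovered <- stats::rbinom(nrow(cell_counts), cell_counts[, b],
                                 design$recovery_efficiency)
      if (sum(recovered) > 0 && reads_per_bin[b] > 0)
        reads[, b] <- stats::rmultinom(1, reads_per_bin[b],
                                       recovered / sum(recovered))
    }
    reads
  })
}

#' Simulate the expression sort
#'
#' As [simulate_sort()], but cell fluorescence is the variant's expression
#' multiplier times a fixed reference signal, independent of antigen
#' concentration; a zero multiplier puts all cells in bin 0 for any gates
#' above zero.
#'
#' @inheritParams simulate_sort
#' @param reference_signal Fluorescence of a multiplier-1 (WT-like) variant.
#' @param gates Expression-sort boundaries; default
#'   `design$expression_gates`, or quantile gates calibrated on the simulated
#'   expression distribution when unset.
#' @return Integer matrix of cell counts, variants x bins.
#' @export
simulate_expression_sort <- function(library, design, noise = noise_model(),
                                     seed = NULL,
                                     cells = design$cells_per_sort,
                                     reference_signal = 100,
                                     gates = design$expression_gates) {
  stopifnot(inherits(library, "ground_truth"), inherits(design, "sort_design"))
  if (nrow(library) == 0L) stop("empty library")
  with_seed(seed, {
    l10 <- ifelse(library$expression > 0,
                  log10(library$expression * reference_signal), -Inf)
    if (is.null(gates)) {
      v <- sample.int(nrow(library), 2e5, replace = TRUE,
                      prob = library$abundance)
      draw <- l10[v] + stats::rnorm(length(v), 0, noise$log_sd)
      gates <- gates_from_fluorescence(
        10^draw[is.finite(draw)],
        seq_len(design$n_bins - 1L) / design$n_bins)
    }
    n_v <- as.vector(stats::rmultinom(1, cells, library$abundance))
    p <- bin_prob_matrix(l10, noise$log_sd, gates)
    counts <- matrix(0L, nrow(library), design$n_bins,
                     dimnames = list(library$id, NULL))
    for (v in which(n_v > 0)) counts[v, ] <- stats::rmultinom(1, n_v[v], p[v, ])
    attr(counts, "gates") <- gates
    counts
  })
}

#' Simulate a complete titration experiment
#'
#' Runs one concentration sort per ladder point plus the expression sort,
#' then sequencing of every bin, and returns cell and read counts alongside
#' the ground truth.
#'
#' @inheritParams simulate_sort
#' @param reference_signal Expression-sort reference signal.
#' @return An object of class `titeseq_sim`: a list with the ground-truth
#'   `library`, the `design` (gates filled in), `noise`, arrays
#'   `affinity_cells` and `affinity_reads` (variant x concentration x bin),
#'   matrices `expression_cells` / `expression_reads` (variant x bin),
#'   per-bin totals `cell_totals` / `read_totals` (concentration x bin), and
#'   the `seed` used.
#' @export
simulate_titeseq <- function(library, design, noise = noise_model(),
                             seed = NULL, reference_signal = 100) {
  stopifnot(inherits(library, "ground_truth"), inherits(design, "sort_design"))
  with_seed(seed, {
    if (is.null(design$gates))
      design$gates <- default_gates(library, design, noise, seed = NULL)
    nc <- length(design$concentrations)
    nb <- design$n_bins
    nv <- nrow(library)
    cells <- array(0L, c(nv, nc, nb),
                   dimnames = list(library$id, NULL, NULL))
    reads <- array(0L, c(nv, nc, nb),
                   dimnames = list(library$id, NULL, NULL))
    for (ci in seq_len(nc)) {
      cc <- simulate_sort(library, design, design$concentrations[ci], noise)
      cells[, ci, ] <- cc
      reads[, ci, ] <- simulate_sequencing(cc, design)
    }
    ec <- simulate_expression_sort(library, design, noise,
                                   reference_signal = reference_signal)
    design$expression_gates <- attr(ec, "gates")
    er <- simulate_sequencing(ec, design)
    structure(list(
      library = library, design = design, noise = noise,
      affinity_cells = cells, affinity_reads = reads,
      expression_cells = ec, expression_reads = er,
      cell_totals = apply(cells, c(2, 3), sum),
      read_totals = apply(reads, c(2, 3), sum),
      seed = seed), class = "titeseq_sim")
  })
}

#' @export
print.titeseq_sim <- function(x, ...) {
  cat(sprintf(paste0("Simulated titration dataset: %d variants, %d ",
                     "concentrations x %d bins + expression sort\n"),
              nrow(x$library), length(x$design$concentrations),
              x$design$n_bins))
  cat(sprintf("  total reads %.3g (affinity) + %.3g (expression)\n",
              sum(x$affinity_reads), sum(x$expression_reads)))
  invisible(x)
}

#' Tidy read counts of a simulated dataset
#'
#' @param x A `titeseq_sim` object.
#' @param ... Unused.
#' @return Data frame with columns `variant_id`, `concentration` (`NA` for
#'   the expression sort), `bin` (0-based), `cells`, `reads`.
#' @export
as.data.frame.titeseq_sim <- function(x, ...) {
  nv <- nrow(x$library); nc <- length(x$design$concentrations)
  nb <- x$design$n_bins
  aff <- expand.grid(variant_id = x$library$id,
                     concentration = x$design$concentrations,
                     bin = 0:(nb - 1L), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  aff$cells <- as.vector(x$affinity_cells)
  aff$reads <- as.vector(x$affinity_reads)
  expr <- expand.grid(variant_id = x$library$id, concentration = NA_real_,
                      bin = 0:(nb - 1L), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  expr$cells <- as.vector(x$expression_cells)
  expr$reads <- as.vector(x$expression_reads)
  rbind(aff, expr)
}
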