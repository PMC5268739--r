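# Codon-level variant library construction for the two mutagenized 10-codon
# windows (CDR1H and CDR3H) of the anti-fluorescein scFv.

GENETIC_CODE_TABLE <- NULL  # populated lazily from Biostrings

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]  # 61 codons; TAA/TAG/TGA excluded
}

#' Define a mutagenized variable region
#'
#' A variable region is a contiguous codon window of the scFv gene with an
#' associated antibody residue numbering. The two packaged regions are the
#' 10-codon CDR1H window (`"1H"`, residues 28-37, WT amino acids TFSDYWMNWV)
#' and the 10-codon CDR3H window (`"3H"`, residues 100-109, WT GSYYGMDYWG),
#' with coding-strand sequences taken from the library primer design.
#'
#' @param name Region label; `"1H"` or `"3H"` select the packaged defaults.
#'   Any other label requires `wt_dna`.
#' @param wt_dna WT coding-strand DNA of the window (length a multiple of 3,
#'   no stop codons). Ignored for the packaged regions.
#' @param residue_numbers Antibody numbering of the window's positions;
#'   defaults to the packaged numbering (28-37 / 100-109) or `1:n`.
#' @return An object of class `variable_region` with fields `name`, `wt_dna`,
#'   `wt_aa`, `residue_numbers`.
#' @examples
#' variable_region("1H")$wt_aa   # "TFSDYWMNWV"
#' @export
variable_region <- function(name, wt_dna = NULL, residue_numbers = NULL) {
  packaged <- list(
    "1H" = list(dna = "ACTTTTAGTGACTACTGGATGAACTGGGTC", res = 28:37),
    "3H" = list(dna = "GGTTCTTACTATGGTATGGACTACTGGGGT", res = 100:109)
  )
  if (is.null(wt_dna)) {
    if (!name %in% names(packaged))
      stop("no packaged region named '", name, "'; supply wt_dna")
    wt_dna <- packaged[[name]]$dna
    residue_numbers <- residue_numbers %||% packaged[[name]]$res
  }
  wt_dna <- toupper(wt_dna)
  if (nchar(wt_dna) %% 3L != 0L) stop("wt_dna length must be a multiple of 3")
  wt_aa <- translate_dna(wt_dna)
  if (grepl("\\*", wt_aa)) stop("WT region contains a stop codon")
  n_pos <- nchar(wt_dna) %/% 3L
  residue_numbers <- residue_numbers %||% seq_len(n_pos)
  if (length(residue_numbers) != n_pos)
    stop("residue_numbers must have one entry per codon")
  structure(list(name = name, wt_dna = wt_dna, wt_aa = wt_aa,
                 residue_numbers = as.integer(residue_numbers)),
            class = "variable_region")
}

#' @export
print.variable_region <- function(x, ...) {
  cat(sprintf("Variable region %s: %s (%s), residues %d-%d\n", x$name,
              x$wt_dna, x$wt_aa, min(x$residue_numbers), max(x$residue_numbers)))
  invisible(x)
}

region_codons <- function(dna) {
  substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
}

#' Apply codon substitutions to a region's WT sequence
#'
#' @param region A [variable_region()].
#' @param positions Codon indices (1-based within the window).
#' @param codons Replacement codons, same length as `positions`.
#' @return The mutated DNA sequence.
#' @export
apply_codon_mutations <- function(region, positions, codons) {
  stopifnot(inherits(region, "variable_region"),
            length(positions) == length(codons))
  cds <- region_codons(region$wt_dna)
  if (any(positions < 1L | positions > length(cds)))
    stop("codon position out of range")
  if (any(!codons %in% names(genetic_code()))) stop("invalid codon")
  cds[positions] <- codons
  paste(cds, collapse = "")
}

#' Enumerate all single-codon variants of a region
#'
#' Every sequence differing from WT at exactly one codon, excluding stop
#' codons and the WT codon itself: `n_positions * 60` variants (600 for a
#' 10-codon window).
#'
#' @param region A [variable_region()].
#' @return A data frame with one row per variant: `id`, `dna`, `aa`,
#'   `position` (codon index mutated), `codon` (replacement codon).
#' @export
enumerate_single_codon_variants <- function(region) {
  stopifnot(inherits(region, "variable_region"))
  wt_codons <- region_codons(region$wt_dna)
  sense <- sense_codons()
  rows <- lapply(seq_along(wt_codons), function(i) {
    alts <- setdiff(sense, wt_codons[i])
    data.frame(position = i, codon = alts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pre <- substring(region$wt_dna, 1L, (out$position - 1L) * 3L)
  post <- substring(region$wt_dna, out$position * 3L + 1L, nchar(region$wt_dna))
  out$dna <- paste0(pre, out$codon, post)
  out$aa <- translate_dna(out$dna)
  out$id <- sprintf("%s_s%03d", region$name, seq_len(nrow(out)))
  out[, c("id", "dna", "aa", "position", "codon")]
}

#' Sample distinct multi-codon variants of a region
#'
#' Variants with exactly `n_mutations` mutated codon positions: positions are
#' drawn uniformly without replacement, replacement codons uniformly over the
#' 60 non-WT sense codons at each chosen position. Sampling is rejection-based
#' so the returned variants are distinct, and reproducible under `seed`.
#'
#' @param region A [variable_region()].
#' @param n_mutations Number of mutated codon positions (e.g. 2 or 3).
#' @param count Number of distinct variants to draw (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A data frame with columns `id`, `dna`, `aa`.
#' @export
sample_multi_codon_variants <- function(region, n_mutations, count,
                                        seed = NULL) {
  stopifnot(inherits(region, "variable_region"))
  stopifnot_scalar(count, "count", nonneg = TRUE)
  n_pos <- nchar(region$wt_dna) %/% 3L
  if (n_mutations < 1L || n_mutations > n_pos)
    stop("n_mutations must be in 1..", n_pos)
  n_possible <- choose(n_pos, n_mutations) * 60^n_mutations
  if (count > n_possible)
    stop("count exceeds the number of distinct variants (", n_possible, ")")
  if (count == 0L)
    return(data.frame(id = character(0), dna = character(0),
                      aa = character(0), stringsAsFactors = FALSE))
  wt_codons <- region_codons(region$wt_dna)
  sense <- sense_codons()
  with_seed(seed, {
    seen <- character(0)
    while (length(seen) < count) {
      need <- count - length(seen)
      batch <- vapply(seq_len(need * 2L), function(i) {
        pos <- sort(sample.int(n_pos, n_mutations))
        cods <- vapply(pos, function(p)
          sample(setdiff(sense, wt_codons[p]), 1L), character(1))
        apply_codon_mutations(region, pos, cods)
      }, character(1))
      seen <- unique(c(seen, batch))
    }
    dna <- seen[seq_len(count)]
    data.frame(id = sprintf("%s_m%d_%04d", region$name, n_mutations,
                            seq_len(count)),
               dna = dna, aa = translate_dna(dna), stringsAsFactors = FALSE)
  })
}

#' Codon-level differences between a variant and the region WT
#'
#' @param dna Variant DNA sequence (same length as the region WT).
#' @param region A [variable_region()].
#' @return Data frame with `position` (codon index), `wt_codon`, `codon`.
#' @export
codon_mutations <- function(dna, region) {
  stopifnot(inherits(region, "variable_region"))
  if (nchar(dna) != nchar(region$wt_dna))
    stop("variant length differs from the region WT (indels not supported)")
  v <- region_codons(toupper(dna))
  w <- region_codons(region$wt_dna)
  i <- which(v != w)
  data.frame(position = i, wt_codon = w[i], codon = v[i],
             stringsAsFactors = FALSE)
}

#' Amino-acid substitutions of a variant, in antibody numbering
#'
#' Synonymous-WT variants return an empty set. Substitutions are reported
#' against the region's residue numbering (28-37 for CDR1H, 100-109 for
#' CDR3H), sorted by position.
#'
#' @param dna Variant DNA (or an amino-acid sequence of the window length,
#'   detected by length).
#' @param region A [variable_region()].
#' @return Data frame with `residue` (antibody numbering), `wt_aa`, `aa`.
#' @export
aa_mutations <- function(dna, region) {
  stopifnot(inherits(region, "variable_region"))
  n_pos <- nchar(region$wt_dna) %/% 3L
  aa <- if (nchar(dna) == n_pos) toupper(dna) else {
    if (nchar(dna) != nchar(region$wt_dna))
      stop("variant length differs from the region WT")
    translate_dna(toupper(dna))
  }
  v <- strsplit(aa, "")[[1]]
  w <- strsplit(region$wt_aa, "")[[1]]
  i <- which(v != w)
  data.frame(residue = region$residue_numbers[i], wt_aa = w[i], aa = v[i],
             stringsAsFactors = FALSE)
}

#' Write library sequences to FASTA
#'
#' @param variants Data frame with `id` and `dna` columns (as returned by the
#'   enumeration/sampling functions).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_library_fasta <- function(variants, file) {
  x <- Biostrings::DNAStringSet(stats::setNames(variants$dna, variants$id))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
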