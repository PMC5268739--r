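# Paired-end amplicon read processing: demultiplex by sort-condition
# barcode, excise the 30-nt variable region between the constant flanks,
# translate, and tally reads into a variant count table. The library is
# substitution-only by construction, so fixed-length excision (no
# indel-tolerant alignment) is exact.

#' Constant-flank layout of the sequencing amplicons
#'
#' Coding-strand flanks bordering the two 30-nt variable regions, taken from
#' the library primer design (the CDR3H primer is synthesized antisense; its
#' flanks are reverse-complemented here to coding-strand orientation).
#'
#' @return An object of class `amplicon_layout`: per region, `upstream` and
#'   `downstream` flank sequences and the `insert_length` (30).
#' @export
amplicon_layout <- function() {
  structure(list(
    "1H" = list(upstream = "GTGTTGCCTCTGGATTC",
                downstream = "CGCCAGTCTCCAGA", insert_length = 30L),
    "3H" = list(upstream = "ATGGGTATCTATTACTGTACG",
                downstream = "CAAGGAACCTCAGTCAC", insert_length = 30L)
  ), class = "amplicon_layout")
}

#' Default barcode set for the sorted bins
#'
#' One barcode per sorted bin (concentration sorts plus the expression sort).
#' Barcodes are 7 nt: the first four bases carry the bin index in base 4 plus
#' a parity base, giving pairwise Hamming distance >= 2 at equal length, and
#' a constant 3-nt pad.
#'
#' @param design A [sort_design()].
#' @return Data frame of class `barcode_set`: `barcode`, `condition` (label),
#'   `type` (`"affinity"`/`"expression"`), `concentration` (molar, `NA` for
#'   expression bins), `bin` (0-based).
#' @export
default_barcodes <- function(design) {
  stopifnot(inherits(design, "sort_design"))
  nc <- length(design$concentrations)
  nb <- design$n_bins
  n <- nc * nb + nb
  if (n > 64L) stop("barcode scheme supports at most 64 conditions")
  base4 <- c("A", "C", "G", "T")
  idx <- seq_len(n) - 1L
  d1 <- idx %/% 16L; d2 <- (idx %/% 4L) %% 4L; d3 <- idx %% 4L
  parity <- (d1 + d2 + d3) %% 4L
  bc <- paste0(base4[d1 + 1L], base4[d2 + 1L], base4[d3 + 1L],
               base4[parity + 1L], "ACT")
  aff <- expand.grid(bin = 0:(nb - 1L), ci = seq_len(nc),
                     KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    barcode = bc,
    condition = c(sprintf("c%02d_b%d", aff$ci, aff$bin),
                  sprintf("e_b%d", 0:(nb - 1L))),
    type = c(rep("affinity", nc * nb), rep("expression", nb)),
    concentration = c(design$concentrations[aff$ci], rep(NA_real_, nb)),
    bin = c(aff$bin, 0:(nb - 1L)),
    stringsAsFactors = FALSE)
  class(out) <- c("barcode_set", "data.frame")
  out
}

#' Assign reads to sort conditions by barcode
#'
#' Matches the read prefix against every barcode of its own length. Exact
#' matches and single-mismatch matches are accepted; a read whose best match
#' is not unique, or is more than one mismatch from every barcode, is
#' unassigned.
#'
#' @param reads Character vector of read sequences (barcode at the 5' end).
#' @param barcodes A [default_barcodes()] table (or any data frame with a
#'   `barcode` column).
#' @return Integer vector of row indices into `barcodes` (`NA` =
#'   unassigned).
#' @export
demultiplex <- function(reads, barcodes) {
  if (length(reads) == 0L) return(integer(0))
  bc <- barcodes$barcode
  best <- rep(NA_integer_, length(reads))
  best_mm <- rep(Inf, length(reads))
  tied <- rep(FALSE, length(reads))
  for (L in unique(nchar(bc))) {
    pref <- substr(reads, 1L, L)
    M <- matrix(unlist(strsplit(pref, ""), use.names = FALSE),
                ncol = L, byrow = TRUE)
    for (j in which(nchar(bc) == L)) {
      mm <- rowSums(M != matrix(strsplit(bc[j], "")[[1]], nrow(M), L,
                                byrow = TRUE))
      better <- mm < best_mm
      tied <- ifelse(mm == best_mm & is.finite(best_mm), TRUE, tied)
      tied[better] <- FALSE
      best[better] <- j
      best_mm[better] <- mm[better]
    }
  }
  best[best_mm > 1 | tied] <- NA_integer_
  best
}

# Locate a region's insert in a single read. Returns a list(region, insert)
# or a character reject reason, or NULL if no flank is present at all.
locate_insert <- function(read, layout) {
  for (rn in names(layout)) {
    lay <- layout[[rn]]
    i <- regexpr(lay$upstream, read, fixed = TRUE)[1]
    if (i < 0) next
    start <- i + nchar(lay$upstream)
    insert <- substr(read, start, start + lay$insert_length - 1L)
    # downstream flank must sit immediately after the fixed-length insert;
    # found elsewhere means an indel in the insert
    after <- substr(read, start + lay$insert_length,
                    start + lay$insert_length + nchar(lay$downstream) - 1L)
    want <- substr(lay$downstream, 1L, nchar(after))
    if (nchar(after) < 5L) return("reject_short")
    if (after != want) {
      j <- regexpr(lay$downstream, read, fixed = TRUE)[1]
      return(if (j > 0) "reject_indel" else "reject_flank")
    }
    if (nchar(insert) < lay$insert_length) return("reject_short")
    if (grepl("[^ACGT]", insert)) return("reject_ambiguous")
    return(list(region = rn, insert = insert, start = start))
  }
  NULL
}

#' Extract the variable region from a read pair
#'
#' Locates the constant flanks (exact match) on the forward read and on the
#' reverse complement of the reverse read, excises the fixed-length insert,
#' and classifies the region by flank identity. Reads with indels (the
#' downstream flank displaced), ambiguous bases, internal stop codons, or
#' disagreeing mates are rejected; rejects are reported, not raised.
#'
#' @param r1,r2 Read sequences of one pair (`r2` may be `NA` for single-end
#'   records).
#' @param layout An [amplicon_layout()].
#' @return A list with `region`, `dna`, `aa` on success, or a reject marker
#'   (`NA`, not a list) with attribute `"reason"` naming the reject class.
#' @export
extract_variable_region <- function(r1, r2 = NA_character_,
                                    layout = amplicon_layout()) {
  reject <- function(reason) structure(NA, reason = reason)
  hits <- list()
  reasons <- character(0)
  for (read in c(r1, if (!is.na(r2)) reverse_complement(r2))) {
    h <- locate_insert(read, layout)
    if (is.null(h)) reasons <- c(reasons, "reject_flank")
    else if (is.character(h)) reasons <- c(reasons, h)
    else hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L)
    return(reject(reasons[1] %||% "reject_flank"))
  if (length(hits) == 2L &&
      (hits[[1]]$region != hits[[2]]$region ||
       hits[[1]]$insert != hits[[2]]$insert))
    return(reject("reject_disagree"))
  insert <- hits[[1]]$insert
  aa <- translate_dna(insert)
  if (grepl("\\*", aa)) return(reject("reject_stop"))
  list(region = hits[[1]]$region, dna = insert, aa = aa)
}

#' Tally assigned reads into a count table
#'
#' @param assignments Data frame with one row per assigned read: columns
#'   `region`, `dna`, `aa`, `condition`, `type`, `concentration`, `bin`.
#' @return Data frame of read counts grouped by (variant, condition), with a
#'   `reads` column; zero rows for empty input.
#' @export
tally <- function(assignments) {
  cols <- c("region", "dna", "aa", "condition", "type", "concentration", "bin")
  if (is.null(assignments) || nrow(assignments) == 0L) {
    out <- stats::setNames(
      as.data.frame(c(replicate(5, character(0), simplify = FALSE),
                      list(numeric(0), integer(0), integer(0))),
                    stringsAsFactors = FALSE),
      c(cols[1:5], "concentration", "bin", "reads"))
    return(out[, c(cols, "reads")])
  }
  # group by key directly: aggregate() would drop NA concentrations
  # (the expression-sort rows)
  key <- do.call(paste, c(assignments[cols], sep = "\r"))
  agg <- assignments[!duplicated(key), cols, drop = FALSE]
  tab <- table(key)
  agg$reads <- as.integer(tab[do.call(paste, c(agg, sep = "\r"))])
  agg <- agg[order(agg$condition, agg$region, agg$dna), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

mean_phred <- function(qual, from, to) {
  s <- substr(qual, from, to)
  vapply(s, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

#' Process paired-end FASTQ files into a variant count table
#'
#' Runs demultiplexing, variable-region extraction and tallying over a pair
#' of FASTQ files, with a minimum mean-Phred filter over the excised insert.
#'
#' @param r1_file,r2_file FASTQ paths (forward / reverse reads, record-matched;
#'   `r2_file` may be `NULL` for single-end data).
#' @param barcodes A [default_barcodes()] table.
#' @param layout An [amplicon_layout()].
#' @param min_phred Minimum mean Phred score over the insert (default 20).
#' @return A list with `counts` (see [tally()]) and `qc`, a list with
#'   `total`, `assigned`, `unassigned`, `rejected` and a `reject_reasons`
#'   table; `assigned + rejected + unassigned == total` exactly.
#' @export
process_fastq <- function(r1_file, r2_file = NULL, barcodes,
                          layout = amplicon_layout(), min_phred = 20) {
  r1 <- Biostrings::readDNAStringSet(r1_file, format = "fastq",
                                     with.qualities = TRUE)
  q1 <- as.character(S4Vectors::mcols(r1)$qualities)
  s1 <- as.character(r1)
  if (!is.null(r2_file)) {
    r2 <- Biostrings::readDNAStringSet(r2_file, format = "fastq",
                                       with.qualities = TRUE)
    if (length(r2) != length(r1))
      stop("FASTQ parse error: mate files differ in record count")
    q2 <- as.character(S4Vectors::mcols(r2)$qualities)
    s2 <- as.character(r2)
  } else {
    s2 <- rep(NA_character_, length(s1)); q2 <- s2
  }
  cond <- demultiplex(s1, barcodes)
  n <- length(s1)
  rows <- vector("list", n)
  reasons <- character(0)
  for (k in seq_len(n)) {
    if (is.na(cond[k])) next
    hit <- extract_variable_region(s1[k], s2[k], layout)
    if (!is.list(hit)) { reasons <- c(reasons, attr(hit, "reason")); next }
    # quality filter on the insert, evaluated on the forward read when it
    # covers the insert, else on the reverse mate
    loc <- locate_insert(s1[k], layout)
    ok <- if (is.list(loc)) {
      mean_phred(q1[k], loc$start, loc$start + nchar(hit$dna) - 1L) >= min_phred
    } else if (!is.na(s2[k])) {
      loc2 <- locate_insert(reverse_complement(s2[k]), layout)
      if (is.list(loc2)) {
        to <- nchar(s2[k]) - loc2$start + 1L
        mean_phred(q2[k], to - nchar(hit$dna) + 1L, to) >= min_phred
      } else TRUE
    } else TRUE
    if (!ok) { reasons <- c(reasons, "reject_quality"); next }
    bcrow <- barcodes[cond[k], ]
    rows[[k]] <- data.frame(region = hit$region, dna = hit$dna, aa = hit$aa,
                            condition = bcrow$condition, type = bcrow$type,
                            concentration = bcrow$concentration,
                            bin = bcrow$bin, stringsAsFactors = FALSE)
  }
  assigned_rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n_assigned <- if (is.null(assigned_rows)) 0L else nrow(assigned_rows)
  qc <- list(total = n,
             assigned = n_assigned,
             unassigned = sum(is.na(cond)),
             rejected = n - n_assigned - sum(is.na(cond)),
             reject_reasons = as.list(table(reasons)))
  list(counts = tally(assigned_rows), qc = qc)
}

#' Write a QC report as JSON
#'
#' @param qc The `qc` element returned by [process_fastq()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(qc, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON QC reports")
  jsonlite::write_json(qc, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Emit synthetic amplicon reads for a count manifest
#'
#' Writes paired-end FASTQ files containing error-free amplicon reads: the
#' forward read carries the condition barcode followed by the amplicon, the
#' reverse read is the amplicon's reverse complement. Used for closed-loop
#' validation of the read-processing pipeline against simulator ground
#' truth.
#'
#' @param manifest Data frame with columns `dna` (30-nt insert), `region`
#'   (`"1H"`/`"3H"`), `condition` (label present in `barcodes`), `reads`
#'   (count to emit).
#' @param barcodes A [default_barcodes()] table.
#' @param r1_file,r2_file Output FASTQ paths.
#' @param layout An [amplicon_layout()].
#' @param read_length Length of each mate (default 75).
#' @return Invisibly, the number of read pairs written.
#' @export
simulate_fastq <- function(manifest, barcodes, r1_file, r2_file,
                           layout = amplicon_layout(), read_length = 75L) {
  stopifnot(all(c("dna", "region", "condition", "reads") %in% names(manifest)))
  manifest <- manifest[manifest$reads > 0, , drop = FALSE]
  bc_of <- stats::setNames(barcodes$barcode, barcodes$condition)
  if (any(!manifest$condition %in% names(bc_of)))
    stop("manifest condition not present in the barcode set")
  r1 <- r2 <- character(sum(manifest$reads))
  pos <- 1L
  for (k in seq_len(nrow(manifest))) {
    lay <- layout[[manifest$region[k]]]
    amp <- paste0(lay$upstream, manifest$dna[k], lay$downstream)
    fwd <- substr(paste0(bc_of[[manifest$condition[k]]], amp),
                  1L, read_length)
    rev <- substr(reverse_complement(amp), 1L, read_length)
    n <- manifest$reads[k]
    r1[pos:(pos + n - 1L)] <- fwd
    r2[pos:(pos + n - 1L)] <- rev
    pos <- pos + n
  }
  ids <- sprintf("read%06d", seq_along(r1))
  for (side in list(list(seqs = r1, file = r1_file),
                    list(seqs = r2, file = r2_file))) {
    x <- Biostrings::DNAStringSet(stats::setNames(side$seqs, ids))
    qual <- Biostrings::BStringSet(strrep("I", nchar(side$seqs)))
    Biostrings::writeXStringSet(x, side$file, format = "fastq",
                                qualities = qual)
  }
  invisible(length(r1))
}
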