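# Structural correlates of mutational sensitivity: per-residue contact
# counts and residue-antigen distances from a crystal structure (e.g. the
# anti-fluorescein scFv/fluorescein complex, PDB 1FLR), correlated with the
# per-position sensitivity statistics. Coordinate files are read with bio3d;
# a packaged synthetic complex exercises all code paths so the real PDB
# download is never required.

#' Per-residue structural environment
#'
#' For each target residue: the number of contacts it makes within the
#' protein (distinct other protein residues with any heavy-atom pair within
#' `contact_cutoff`, excluding the sequence neighbors i-1 and i+1 on the same
#' chain), and the minimum heavy-atom distance to the ligand.
#'
#' @param pdb Path to a PDB-format coordinate file, or a `bio3d` `pdb`
#'   object.
#' @param residues Residue numbers of interest (default the CDR1H and CDR3H
#'   windows, 28-37 and 100-109).
#' @param chain Optional chain identifier restricting the target residues.
#' @param ligand Residue name of the ligand (default `"FLU"`, fluorescein).
#' @param contact_cutoff Heavy-atom contact distance, Angstrom (default
#'   4.5).
#' @return A data frame with `residue`, `chain`, `n_contacts`,
#'   `antigen_distance`.
#' @export
residue_environment <- function(pdb, residues = c(28:37, 100:109),
                                chain = NULL, ligand = "FLU",
                                contact_cutoff = 4.5) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  heavy <- is.na(at$elesy) | !at$elesy %in% "H"
  heavy <- heavy & !grepl("^H", at$elety)
  at <- at[heavy, , drop = FALSE]
  prot <- at[at$type == "ATOM", , drop = FALSE]
  lig <- at[at$resid == ligand, , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand '", ligand, "' not found in structure")
  tgt <- prot
  if (!is.null(chain)) tgt <- tgt[tgt$chain %in% chain, , drop = FALSE]
  missing <- setdiff(residues, unique(tgt$resno))
  if (length(missing) > 0L)
    stop("structure is missing target residues: ",
         paste(missing, collapse = ", "))
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  res_key <- paste(prot$chain, prot$resno)
  rows <- lapply(residues, function(r) {
    sel <- tgt$resno == r
    ch <- unique(tgt$chain[sel])[1]
    mine <- which(res_key == paste(ch, r))
    d <- sqrt(pmax(outer(rowSums(prot_xyz[mine, , drop = FALSE]^2),
                         rowSums(prot_xyz^2), "+") -
                   2 * prot_xyz[mine, , drop = FALSE] %*% t(prot_xyz), 0))
    mind <- tapply(apply(d, 2, min), res_key, min)
    near <- names(mind)[mind <= contact_cutoff]
    excl <- paste(ch, (r - 1):(r + 1))
    dl <- sqrt(pmax(outer(rowSums(prot_xyz[mine, , drop = FALSE]^2),
                          rowSums(lig_xyz^2), "+") -
                    2 * prot_xyz[mine, , drop = FALSE] %*% t(lig_xyz), 0))
    data.frame(residue = r, chain = ch,
               n_contacts = length(setdiff(near, excl)),
               antigen_distance = min(dl), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate sensitivity with structural environment
#'
#' Ordinary least-squares coefficients of determination between the
#' per-position sensitivity statistics and each structural covariate:
#' S_K vs contacts, S_K vs antigen distance, S_E vs contacts, S_E vs antigen
#' distance.
#'
#' @param environments A [residue_environment()] data frame.
#' @param profile A [sensitivity_profile()] data frame (matched on
#'   `position` / `residue`).
#' @return A named numeric vector of R-squared values (entries for `s_e` are
#'   present only when the profile carries it).
#' @export
correlate_sensitivity <- function(environments, profile) {
  m <- merge(environments, profile, by.x = "residue", by.y = "position")
  if (nrow(m) < 3L) stop("need at least 3 matched residues")
  r2 <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::var(y[ok]) == 0) return(0)  # flat response explains nothing
    suppressWarnings(summary(stats::lm(y[ok] ~ x[ok]))$r.squared)
  }
  out <- c(s_k_contacts = r2(m$s_k, m$n_contacts),
           s_k_distance = r2(m$s_k, m$antigen_distance))
  if ("s_e" %in% names(m))
    out <- c(out, s_e_contacts = r2(m$s_e, m$n_contacts),
             s_e_distance = r2(m$s_e, m$antigen_distance))
  out
}

#' Write a minimal PDB-format coordinate file
#'
#' Fixed-width ATOM/HETATM records for synthetic test structures. Not a
#' general PDB writer; intended for building small, fully controlled
#' fixtures.
#'
#' @param atoms Data frame with columns `type` (`"ATOM"`/`"HETATM"`),
#'   `elety` (atom name), `resid` (residue name), `chain`, `resno`, `x`,
#'   `y`, `z`, and optionally `elesy` (element symbol).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_coordinate_file <- function(atoms, file) {
  elesy <- atoms$elesy %||% substr(atoms$elety, 1, 1)
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$type, seq_len(nrow(atoms)),
    substr(atoms$elety, 1, 4), atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1, 0, elesy)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Synthetic scFv-like complex for the structure module
#'
#' Builds (in code, with fixed deterministic coordinates) a small synthetic
#' coordinate set emulating the two CDR windows: twenty residues numbered
#' 28-37 and 100-109 on chain H, two heavy atoms each, arranged on two
#' loops, plus a three-atom ligand (`FLU`) placed near the 100-109 loop. It
#' is a stand-in geometry for exercising contact counting and
#' ligand-distance code, not a model of the real crystal structure. A
#' pre-written copy ships with the package:
#' `system.file("extdata", "synthetic_scfv_complex.pdb", package = "titeseq")`.
#'
#' @param file Optional path; when given, the structure is also written in
#'   PDB format.
#' @return The atoms data frame (invisibly when `file` is given).
#' @export
synthetic_scfv_structure <- function(file = NULL) {
  res <- c(28:37, 100:109)
  t1 <- seq(0, pi, length.out = 10)
  t2 <- seq(0, pi, length.out = 10)
  ca <- rbind(
    cbind(6 * cos(t1), 6 * sin(t1), 0),          # CDR1H loop, z = 0
    cbind(6 * cos(t2), 6 * sin(t2), 5))          # CDR3H loop, z = 5
  cb <- ca + matrix(c(0.9, 0.9, 0.9), nrow(ca), 3, byrow = TRUE)
  atoms <- data.frame(
    type = "ATOM",
    elety = rep(c("CA", "CB"), each = length(res)),
    resid = "ALA", chain = "H",
    resno = rep(res, 2),
    x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
    z = c(ca[, 3], cb[, 3]),
    elesy = "C", stringsAsFactors = FALSE)
  lig <- data.frame(
    type = "HETATM", elety = c("C1", "C2", "O1"), resid = "FLU",
    chain = "L", resno = 500,
    x = c(0, 1.4, 2.4), y = c(7.5, 7.5, 7.5), z = c(5, 5, 5),
    elesy = c("C", "C", "O"), stringsAsFactors = FALSE)
  atoms <- rbind(atoms, lig)
  atoms <- atoms[order(atoms$type, atoms$resno, atoms$elety), ]
  if (!is.null(file)) {
    write_coordinate_file(atoms, file)
    return(invisible(atoms))
  }
  atoms
}
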