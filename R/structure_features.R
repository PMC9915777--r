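# Per-residue structural features from predicted structures: model
# confidence (pLDDT, stored in the PDB temperature-factor column by
# AlphaFold convention) and solvent accessibility.

#' Parse a predicted structure into per-residue features
#'
#' Reads a PDB file and returns one row per (chain, residue), with the
#' residue's pLDDT confidence taken from the temperature-factor column of
#' its CA atom (AlphaFold writes the same value on every atom of a
#' residue; CA is present in every complete residue). Residues lacking a
#' CA atom are skipped with a warning. SASA columns are NA until
#' [compute_sasa()] fills them.
#'
#' @param path Path to a PDB file with ATOM records.
#' @return data.frame with columns `chain`, `residue_number`,
#'   `residue_name`, `plddt`, `sasa_abs`, `sasa_percent`.
#' @export
parse_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path)
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  res_keys <- unique(key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, sep = "\r")
  no_ca <- setdiff(res_keys, ca_key)
  if (length(no_ca) > 0) {
    warning(length(no_ca), " residue(s) lack a CA atom and were skipped")
  }
  keep <- res_keys[res_keys %in% ca_key]
  idx <- match(keep, ca_key)
  data.frame(
    chain = ca$chain[idx],
    residue_number = as.integer(ca$resno[idx]),
    residue_name = ca$resid[idx],
    plddt = as.numeric(ca$b[idx]),
    sasa_abs = NA_real_,
    sasa_percent = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Element symbol per atom: use the PDB element column when present,
# otherwise the first letter of the atom name (digits stripped).
atom_elements <- function(atoms) {
  el <- atoms$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(atoms))
  el <- toupper(trimws(el))
  blank <- is.na(el) | el == ""
  if (any(blank)) {
    nm <- gsub("[0-9']", "", toupper(trimws(atoms$elety[blank])))
    el[blank] <- substr(nm, 1, 1)
  }
  el
}

#' Compute per-residue solvent accessible surface area
#'
#' Runs the Shrake-Rupley sphere-sampling algorithm over all ATOM-record
#' atoms of a structure, sums atom areas per residue, and normalizes by
#' the theoretical maximum ASA of the residue type ([max_asa_table()]) to
#' a relative percentage. Relative values above 100 are reported as-is,
#' never clamped. Residue types absent from the normalization table get
#' `sasa_abs` but no `sasa_percent`.
#'
#' @param structure Path to a PDB file, or a `bio3d` pdb object.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points Number of sphere sample points per atom (default 960).
#' @return Per-residue feature data.frame as from [parse_structure()]
#'   with `sasa_abs` (Angstrom^2) and `sasa_percent` filled.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  pdb <- if (inherits(structure, "pdb")) structure else {
    bio3d::read.pdb(structure, verbose = FALSE)
  }
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in structure")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  areas <- atom_sasa(xyz, atom_elements(atoms),
                     probe_radius = probe_radius, n_points = n_points)
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  res_area <- tapply(areas, key, sum)

  feats <- parse_structure_from_atoms(atoms)
  fkey <- paste(feats$chain, feats$residue_number, sep = "\r")
  feats$sasa_abs <- as.numeric(res_area[fkey])
  maxasa <- max_asa_table()[feats$residue_name]
  feats$sasa_percent <- 100 * feats$sasa_abs / unname(maxasa)
  feats
}

# parse_structure's residue pass over an already-read atom table.
parse_structure_from_atoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  res_keys <- unique(key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, sep = "\r")
  no_ca <- setdiff(res_keys, ca_key)
  if (length(no_ca) > 0) {
    warning(length(no_ca), " residue(s) lack a CA atom and were skipped")
  }
  keep <- res_keys[res_keys %in% ca_key]
  idx <- match(keep, ca_key)
  data.frame(
    chain = ca$chain[idx],
    residue_number = as.integer(ca$resno[idx]),
    residue_name = ca$resid[idx],
    plddt = as.numeric(ca$b[idx]),
    sasa_abs = NA_real_,
    sasa_percent = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Bin a pLDDT confidence value
#'
#' The four confidence strata used for cross-tabulations: `"<50"`,
#' `"50-70"`, `"70-90"`, `">90"`. Bins are left-closed and half-open
#' (50 falls in `"50-70"`, 90 in `">90"`); the top bin is closed at 100,
#' so the four bins partition \[0, 100\] exactly.
#'
#' @param plddt Numeric vector of confidence values in \[0, 100\].
#' @return Factor with levels `"<50"`, `"50-70"`, `"70-90"`, `">90"`.
#' @export
confidence_bin <- function(plddt) {
  if (any(is.na(plddt)) || any(plddt < 0 | plddt > 100)) {
    stop("plddt must lie in [0, 100]")
  }
  lev <- c("<50", "50-70", "70-90", ">90")
  idx <- findInterval(plddt, c(50, 70, 90)) + 1L
  factor(lev[idx], levels = lev)
}

#' Low-confidence cutoff
#'
#' Residues with pLDDT below this value are considered to lie in
#' low-confidence (often natively disordered) regions; at or above it,
#' high-confidence regions.
#'
#' @return The cutoff, 70.
#' @export
low_confidence_cutoff <- function() 70

#' Residue number encoded in a protein-level HGVS change
#'
#' Extracts the residue number from strings like
#' `"NP_076927.1:p.Met384Lys"` or `"p.Ala12Val"` (the digits between the
#' reference and variant amino acid codes). Unparseable strings give NA.
#'
#' @param protein_change Character vector.
#' @return Integer vector of residue numbers (NA where unparseable).
#' @export
protein_change_residue <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexpr("p\\.[A-Za-z]{3}([0-9]+)", protein_change))
  out <- rep(NA_integer_, length(protein_change))
  hit <- lengths(regmatches(protein_change,
                            gregexpr("p\\.[A-Za-z]{3}[0-9]+",
                                     protein_change))) > 0
  out[hit] <- as.integer(sub("p\\.[A-Za-z]{3}", "", m))
  out
}

#' Annotate variants with per-residue structural features
#'
#' Fills the `confidence` and `sasa_percent` columns of a variant table
#' from a per-residue feature table (as produced by [compute_sasa()],
#' plus a `gene` column identifying which protein each feature row
#' belongs to). Variants whose protein change cannot be parsed to a
#' residue number are skipped with a warning; variants without a matching
#' (gene, residue) feature are left unchanged. Both are counted in the
#' returned report.
#'
#' @param records A variant table.
#' @param features A data.frame with columns `gene`, `residue_number`,
#'   `plddt`, `sasa_percent`.
#' @return List with `records` (annotated table) and `report` (list of
#'   counts: `n_matched`, `n_unmatched`, `n_unparseable`).
#' @export
annotate_variants <- function(records, features) {
  records <- validate_variant_table(records)
  stopifnot(all(c("gene", "residue_number", "plddt", "sasa_percent")
                %in% names(features)))
  resno <- protein_change_residue(records$protein_change)
  unparseable <- is.na(resno)
  if (any(unparseable)) {
    warning(sum(unparseable),
            " variant(s) with unparseable protein_change were skipped")
  }
  key <- paste(records$gene, resno, sep = "\r")
  fkey <- paste(features$gene, features$residue_number, sep = "\r")
  idx <- match(key, fkey)
  matched <- !unparseable & !is.na(idx)
  records$confidence[matched] <- features$plddt[idx[matched]]
  records$sasa_percent[matched] <- features$sasa_percent[idx[matched]]
  list(
    records = records,
    report = list(
      n_matched = sum(matched),
      n_unmatched = sum(!matched & !unparseable),
      n_unparseable = sum(unparseable)
    )
  )
}
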