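#' Aggregate atomic ASA to per-residue relative solvent accessibility
#'
#' Sums atomic accessible surface areas over each residue's heavy atoms and
#' expresses the sum as a percentage of that residue type's reference area
#' in an extended Ala-X-Ala tripeptide (RSA).
#'
#' @param atoms data.frame from [parse_structure()].
#' @param atom_asa Numeric vector of per-atom ASA from [lee_richards_asa()]
#'   (same order as `atoms`).
#' @param reference Named numeric vector of reference areas per 3-letter
#'   residue name; defaults to [reference_asa()].
#' @return data.frame with one row per residue: `chain`, `residue_index`,
#'   `residue_name`, `asa` (Angstrom^2), `rsa` (percent).
#' @export
residue_rsa <- function(atoms, atom_asa, reference = reference_asa()) {
  stopifnot(nrow(atoms) == length(atom_asa))
  key <- paste(atoms$chain, atoms$residue_index, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(
    chain = atoms$chain[first],
    residue_index = atoms$residue_index[first],
    residue_name = atoms$residue_name[first],
    stringsAsFactors = FALSE)
  res$asa <- as.numeric(tapply(atom_asa, factor(key, levels = unique(key)), sum))
  missing <- setdiff(unique(res$residue_name), names(reference))
  if (length(missing)) {
    stop(sprintf("no reference ASA for residue type(s): %s",
                 paste(missing, collapse = ", ")))
  }
  res$rsa <- 100 * res$asa / unname(reference[res$residue_name])
  rownames(res) <- NULL
  res
}

#' Two-state solvation classification from RSA
#'
#' Classifies a residue as `"exposed"` if its relative solvent accessibility
#' is at least `threshold` percent, else `"buried"`. The default threshold
#' of 7 percent is the two-state cut-off of Zhu and Blundell; the boundary
#' value is assigned to the exposed state (one consistent half-open rule).
#'
#' @param rsa Numeric vector of RSA percentages (>= 0).
#' @param threshold RSA threshold in percent.
#' @return Character vector of `"buried"` / `"exposed"`.
#' @export
classify_state <- function(rsa, threshold = 7) {
  if (any(!is.finite(rsa)) || any(rsa < 0)) stop("rsa must be non-negative")
  ifelse(rsa >= threshold, "exposed", "buried")
}

#' Structure to classified residue accessibility table
#'
#' One-call wrapper: parse the structure, run the Lee-Richards slice
#' calculation, aggregate to residues and classify each as buried or
#' exposed.
#'
#' @inheritParams parse_structure
#' @inheritParams lee_richards_asa
#' @inheritParams classify_state
#' @param reference Reference ASA table, see [residue_rsa()].
#' @return data.frame with columns `chain`, `residue_index`,
#'   `residue_name`, `asa`, `rsa`, `state`.
#' @export
compute_accessibility <- function(pdb, probe = 1.4, slice = 0.05,
                                  threshold = 7, radii = vdw_radii(),
                                  reference = reference_asa()) {
  atoms <- parse_structure(pdb, radii = radii)
  asa <- lee_richards_asa(atoms, probe = probe, slice = slice)
  res <- residue_rsa(atoms, asa, reference = reference)
  res$state <- classify_state(res$rsa, threshold = threshold)
  res
}

#' Read or write a residue accessibility table
#'
#' Tab-separated mirror of a per-residue accessibility summary with columns
#' chain, index, residue, asa, rsa, state.
#'
#' @param res Residue table from [compute_accessibility()].
#' @param path Output (or input) TSV path.
#' @return `write_rsa_tsv()` returns `path` invisibly; `read_rsa_tsv()`
#'   returns the residue data.frame.
#' @export
write_rsa_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rsa_tsv
#' @export
read_rsa_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
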