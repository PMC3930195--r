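#' Parse a protein structure into atomic spheres
#'
#' Reads ATOM records from a PDB file and returns one row per heavy atom
#' with an assigned van der Waals radius, ready for accessible-surface-area
#' calculation. Following standard accessibility practice: hydrogens and
#' HETATM records are dropped, only the first model of a multi-model file is
#' read, and where alternate locations exist the highest-occupancy altloc is
#' kept (ties broken by first encountered). Residues are re-indexed 1-based
#' sequentially per chain, flattening insertion codes.
#'
#' @param pdb Path to a PDB file, or the file content as a character vector
#'   (a single string with newlines, or one string per line).
#' @param radii Named numeric vector mapping element symbols to van der
#'   Waals radii in Angstrom; defaults to [vdw_radii()].
#' @return A data.frame with columns `chain`, `residue_index`,
#'   `residue_name` (3-letter), `atom_name`, `x`, `y`, `z` (Angstrom) and
#'   `radius` (Angstrom, van der Waals only, no probe).
#' @export
parse_structure <- function(pdb, radii = vdw_radii()) {
  path <- pdb_as_path(pdb)
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  nonstd <- !(at$resid %in% standard_residues())
  if (any(nonstd)) {
    warning(sprintf("dropping %d atoms in non-standard residues (%s)",
                    sum(nonstd), paste(unique(at$resid[nonstd]), collapse = ", ")))
    at <- at[!nonstd, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty structure: no ATOM records with standard residues")

  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- element_from_atom_name(at$elety[miss])
  elem <- toupper(trimws(elem))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  if (nrow(at) == 0L) stop("empty structure: only hydrogens present")

  unknown <- !(elem %in% names(radii))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf("unknown element '%s' for atom '%s' (chain %s residue %s %s)",
                 elem[i], trimws(at$elety[i]), at$chain[i], at$resno[i], at$resid[i]))
  }

  # highest-occupancy altloc per atom site; ties keep the first encountered
  occ <- at$o
  occ[is.na(occ)] <- 1
  site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(site, unique(site)), -occ, seq_len(nrow(at)))
  keep <- !duplicated(site[ord])
  sel <- sort(seq_len(nrow(at))[ord][keep])
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]

  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  rkey <- paste(at$resno, at$insert, sep = "\r")
  idx <- integer(nrow(at))
  for (ch in unique(chain)) {
    m <- chain == ch
    idx[m] <- match(rkey[m], unique(rkey[m]))
  }

  out <- data.frame(
    chain = chain, residue_index = idx, residue_name = at$resid,
    atom_name = trimws(at$elety), x = at$x, y = at$y, z = at$z,
    radius = unname(radii[elem]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

pdb_as_path <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  path <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  path
}
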