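#' Standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, the only residue types
#' accepted by the structure parser.
#'
#' @return Character vector of 20 three-letter codes.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Default van der Waals radius table
#'
#' Element-keyed van der Waals radii (in Angstrom) for protein heavy atoms,
#' the Chothia-style values conventionally used for accessible-surface-area
#' calculation: C 1.87, N 1.65, O 1.40, S 1.85. Hydrogen is listed for
#' completeness but hydrogens are dropped by [parse_structure()].
#'
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00)
}

#' Reference residue accessible surface areas
#'
#' Per-residue-type reference ASA (Angstrom^2) of residue X in an extended
#' Ala-X-Ala tripeptide, used as the denominator of relative solvent
#' accessibility. Two conventions are available:
#'
#' * `"ala-x-ala"` (default): the Hubbard & Thornton tabulation used by
#'   standard accessibility software for real protein structures.
#' * `"single-sphere"`: computed at call time from an extended three-sphere
#'   chain of 1.87-Angstrom pseudo-atoms spaced 3.8 Angstrom apart, matching
#'   the one-pseudo-atom-per-residue convention of [gen_structure()]. Every
#'   residue type gets the same value; this keeps the synthetic pipeline
#'   self-consistent and is a test convention, not biology.
#'
#' @param convention `"ala-x-ala"` or `"single-sphere"`.
#' @param probe Probe radius in Angstrom (used by `"single-sphere"` only).
#' @param slice Slice spacing in Angstrom (used by `"single-sphere"` only).
#' @return Named numeric vector over the 20 standard residues, Angstrom^2.
#' @export
reference_asa <- function(convention = c("ala-x-ala", "single-sphere"),
                          probe = 1.4, slice = 0.05) {
  convention <- match.arg(convention)
  if (convention == "ala-x-ala") {
    return(c(
      ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39, CYS = 134.28,
      GLN = 178.50, GLU = 172.25, GLY =  80.10, HIS = 182.88, ILE = 175.12,
      LEU = 178.63, LYS = 200.81, MET = 194.15, PHE = 199.48, PRO = 136.13,
      SER = 116.50, THR = 139.27, TRP = 249.36, TYR = 212.76, VAL = 151.44))
  }
  r <- unname(vdw_radii()["C"])
  chain <- data.frame(
    chain = "A", residue_index = 1:3, residue_name = c("ALA", "ALA", "ALA"),
    atom_name = "CB", x = c(0, 3.8, 7.6), y = 0, z = 0, radius = r,
    stringsAsFactors = FALSE)
  asa <- lee_richards_asa(chain, probe = probe, slice = slice)
  stats::setNames(rep(asa[2], 20L), standard_residues())
}

# element symbol from a PDB atom name (columns 13-16), used when the
# element field (columns 77-78) is absent. Digits strip; "1HB"-style
# hydrogen names resolve to H; two-character elements other than S/C/N/O/H
# do not occur in standard amino acids.
element_from_atom_name <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  substr(nm, 1L, 1L)
}
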