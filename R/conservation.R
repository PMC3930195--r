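#' Parse a query-anchored multiple alignment
#'
#' Reads an aligned FASTA file (20 amino-acid letters plus `-` for gaps),
#' checks that all rows have equal length and that the query is present,
#' and returns the alignment with the query row first.
#'
#' @param aligned_fasta Path to an aligned FASTA file, or its content as a
#'   character string.
#' @param query_id Identifier of the query sequence (matched against the
#'   first whitespace-delimited token of each FASTA header).
#' @return An object of class `hydro_alignment`: a list with `query_id`,
#'   `ids` (query first) and `mat`, an n x L character matrix of aligned
#'   residues.
#' @export
parse_alignment <- function(aligned_fasta, query_id) {
  path <- aligned_fasta
  if (length(aligned_fasta) != 1L || grepl("\n", aligned_fasta) ||
      !file.exists(aligned_fasta)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(unlist(strsplit(aligned_fasta, "\n", fixed = TRUE)), path)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment file")
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (length(unique(Biostrings::width(seqs))) != 1L) stop("ragged alignment: rows differ in length")
  qi <- match(query_id, ids)
  if (is.na(qi)) stop(sprintf("query not found: no sequence named '%s'", query_id))
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  bad <- !(mat %in% c(aa1_codes(), "-"))
  if (any(bad)) {
    stop(sprintf("non-amino-acid character(s) in alignment: %s",
                 paste(unique(mat[bad]), collapse = " ")))
  }
  ord <- c(qi, setdiff(seq_along(ids), qi))
  structure(list(query_id = query_id, ids = ids[ord],
                 mat = mat[ord, , drop = FALSE]),
            class = "hydro_alignment")
}

#' @export
print.hydro_alignment <- function(x, ...) {
  cat(sprintf("hydro_alignment: %d sequences x %d columns (query '%s')\n",
              nrow(x$mat), ncol(x$mat), x$query_id))
  invisible(x)
}

aa1_codes <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Pairwise identity of each homolog to the query
#'
#' Identity is the number of matching columns divided by the number of
#' columns where both the query and the homolog have a residue (gap-gap and
#' gap-residue columns excluded), times 100.
#'
#' @param aln A `hydro_alignment`.
#' @return Named numeric vector of identities in percent, one per homolog
#'   row (NaN when no column is shared).
#' @export
pairwise_identity <- function(aln) {
  q <- aln$mat[1L, ]
  homs <- aln$mat[-1L, , drop = FALSE]
  out <- apply(homs, 1L, function(h) {
    both <- q != "-" & h != "-"
    if (!any(both)) return(NaN)
    100 * sum(q[both] == h[both]) / sum(both)
  })
  stats::setNames(as.numeric(out), aln$ids[-1L])
}

#' Filter homologs by identity to the query
#'
#' Retains the query plus homologs whose pairwise identity to the query
#' exceeds `min_identity` percent (strictly greater, matching the
#' convention of keeping homologs with identity greater than 30%).
#' Homologs sharing no non-gap column with the query are excluded with a
#' warning.
#'
#' @inheritParams pairwise_identity
#' @param min_identity Identity threshold in percent.
#' @return A filtered `hydro_alignment`.
#' @export
identity_filter <- function(aln, min_identity = 30) {
  idt <- pairwise_identity(aln)
  orphan <- is.nan(idt)
  if (any(orphan)) {
    warning(sprintf("excluding homolog(s) sharing no aligned column with the query: %s",
                    paste(aln$ids[-1L][orphan], collapse = ", ")))
  }
  keep <- c(TRUE, !orphan & idt > min_identity)
  structure(list(query_id = aln$query_id, ids = aln$ids[keep],
                 mat = aln$mat[keep, , drop = FALSE]),
            class = "hydro_alignment")
}

#' Hydrophobicity conservation weight scheme
#'
#' Residue weights for conservation scoring: the hydrophobic residues V, I,
#' L, M, F score 1; the partially hydrophobic A, Y, W score 0.5; all polar
#' residues score -2. Cysteine is unassigned by the original scheme and
#' defaults to 0.5 here (intermediate hydrophobicity, and weight 1 in the
#' flanking scheme); override via `cys`.
#'
#' @param cys Weight assigned to cysteine.
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
conservation_weights <- function(cys = 0.5) {
  w <- stats::setNames(rep(-2, 20L), aa1_codes())
  w[c("V", "I", "L", "M", "F")] <- 1
  w[c("A", "Y", "W")] <- 0.5
  w["C"] <- cys
  w
}

#' Per-residue hydrophobicity conservation profile
#'
#' For every non-gap query position, sums the conservation weights of the
#' homolog characters in that alignment column (query row excluded); each
#' gap contributes `gap_score + gap_extra`. The raw sum is normalised to a
#' percent-of-maximum scale: 100 * raw / (n_homologs * max weight), so an
#' all-hydrophobic column scores exactly 100 and columns dominated by polar
#' residues or gaps go below 0 (with the defaults the floor is -400).
#'
#' @inheritParams pairwise_identity
#' @param weights Residue weight map, see [conservation_weights()].
#' @param gap_score Base score of a gap character.
#' @param gap_extra Extra gap penalty added on top of `gap_score`.
#' @param include_query If `TRUE`, the query row is scored as one of the
#'   homologs (off by default: self-counting inflates conservation).
#' @return data.frame with one row per query residue: `position` (1-based
#'   ungapped query coordinate), `residue_name` (1-letter), `raw_score`,
#'   `n_homologs`, `normalized_score`, `bin_label`.
#' @export
conservation_profile <- function(aln, weights = conservation_weights(),
                                 gap_score = -2, gap_extra = -2,
                                 include_query = FALSE) {
  rows <- if (include_query) aln$mat else aln$mat[-1L, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty alignment after filtering: no homolog rows")
  q <- aln$mat[1L, ]
  cols <- which(q != "-")
  gap_total <- gap_score + gap_extra
  wmax <- max(weights)
  raw <- vapply(cols, function(j) {
    ch <- rows[, j]
    sum(ifelse(ch == "-", gap_total, weights[ch]))
  }, 0)
  norm <- 100 * raw / (nrow(rows) * wmax)
  data.frame(
    position = seq_along(cols),
    residue_name = q[cols],
    raw_score = raw,
    n_homologs = nrow(rows),
    normalized_score = norm,
    bin_label = assign_bin(norm),
    stringsAsFactors = FALSE)
}

#' Conservation-score bins
#'
#' Bin labels for normalised conservation scores: `"<0"` for negative
#' scores, then half-open decades `[0,10)`, `[10,20)`, ... `[80,90)`, with
#' the top bin `[90,100]` closed. Scores cannot exceed 100.
#'
#' @param normalized_score Numeric vector of normalised scores (<= 100).
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(normalized_score) {
  if (any(normalized_score > 100 + 1e-9)) stop("normalized score above 100")
  lv <- bin_levels()
  idx <- ifelse(normalized_score < 0, 1L,
                pmin(floor(normalized_score / 10), 9) + 2L)
  lv[idx]
}

#' @rdname assign_bin
#' @export
bin_levels <- function() {
  c("<0", paste(seq(0, 90, 10), "to", seq(10, 100, 10)))
}

#' Read or write a conservation profile
#'
#' Tab-separated per-residue conservation table (position, residue, raw,
#' normalised score, bin).
#'
#' @param profile data.frame from [conservation_profile()].
#' @param path TSV path.
#' @return `write_conservation_tsv()` returns `path` invisibly;
#'   `read_conservation_tsv()` returns the profile data.frame.
#' @export
write_conservation_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conservation_tsv
#' @export
read_conservation_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
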