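#' Confidence scores from bin frequencies
#'
#' Converts the relative frequencies of exposed and buried hydrophobic
#' residues in one conservation-score bin into the pair of confidence
#' scores: `confidence_exposed = rel_freq_exposed / rel_freq_buried` and
#' `confidence_buried` its reciprocal. The ratio is invariant to any common
#' normalisation of the two frequency columns. A zero denominator yields
#' `Inf` (flagged infinite confidence); a bin with both frequencies zero is
#' undefined and returns `NA` for both.
#'
#' @param rel_freq_exposed,rel_freq_buried Non-negative relative
#'   frequencies (percent), vectorised over bins.
#' @return data.frame with columns `confidence_exposed`,
#'   `confidence_buried`.
#' @export
confidence_from_freqs <- function(rel_freq_exposed, rel_freq_buried) {
  stopifnot(length(rel_freq_exposed) == length(rel_freq_buried))
  if (any(rel_freq_exposed < 0 | rel_freq_buried < 0, na.rm = TRUE)) {
    stop("relative frequencies must be non-negative")
  }
  both_zero <- rel_freq_exposed == 0 & rel_freq_buried == 0
  ce <- rel_freq_exposed / rel_freq_buried
  cb <- rel_freq_buried / rel_freq_exposed
  ce[both_zero] <- NA_real_
  cb[both_zero] <- NA_real_
  data.frame(confidence_exposed = ce, confidence_buried = cb)
}

#' Build the bin-frequency / confidence table
#'
#' From hydrophobic residues carrying both a conservation bin label and an
#' observed solvation state, tabulates per bin the percentage relative
#' frequency of exposed and of buried residues (each column sums to 100)
#' and derives the confidence scores via [confidence_from_freqs()].
#'
#' @param bin_label Character vector of bin labels (see [assign_bin()]).
#' @param state Character vector of observed states (`"buried"` /
#'   `"exposed"`), same length.
#' @return data.frame with one row per bin (ordered as [bin_levels()]):
#'   `bin`, `rel_freq_exposed`, `rel_freq_buried`, `confidence_exposed`,
#'   `confidence_buried`.
#' @export
build_bin_table <- function(bin_label, state) {
  stopifnot(length(bin_label) == length(state))
  if (!any(state == "exposed")) stop("no exposed residues in input")
  if (!any(state == "buried")) stop("no buried residues in input")
  lv <- bin_levels()
  bad <- !(bin_label %in% lv)
  if (any(bad)) stop(sprintf("unknown bin label(s): %s",
                             paste(unique(bin_label[bad]), collapse = ", ")))
  f <- factor(bin_label, levels = lv)
  fe <- 100 * as.numeric(table(f[state == "exposed"])) / sum(state == "exposed")
  fb <- 100 * as.numeric(table(f[state == "buried"])) / sum(state == "buried")
  cbind(data.frame(bin = lv, rel_freq_exposed = fe, rel_freq_buried = fb,
                   stringsAsFactors = FALSE),
        confidence_from_freqs(fe, fb))
}

#' Reference bin-frequency table
#'
#' The bundled per-bin relative frequencies of solvent-exposed and buried
#' hydrophobic residues, derived from a structural survey of 218
#' nonredundant monomeric proteins, with confidence scores recomputed from
#' the frequencies. This is the default "trained model" for sequence-only
#' prediction when no training structures are supplied.
#'
#' @return data.frame in the layout of [build_bin_table()].
#' @export
reference_bin_table <- function() {
  path <- system.file("extdata", "ref_bin_frequencies.tsv",
                      package = "hydroscan", mustWork = TRUE)
  read_bin_table(path)
}

#' Read or write a bin table
#'
#' Tab-separated bin table in the layout of [build_bin_table()]. Reading
#' recomputes the confidence columns from the frequency columns when they
#' are absent.
#'
#' @param table Bin table data.frame.
#' @param path TSV path.
#' @return `write_bin_table()` returns `path` invisibly; `read_bin_table()`
#'   returns the bin table.
#' @export
write_bin_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("bin", "rel_freq_exposed", "rel_freq_buried") %in% names(tb)))
  if (!all(c("confidence_exposed", "confidence_buried") %in% names(tb))) {
    tb <- cbind(tb, confidence_from_freqs(tb$rel_freq_exposed, tb$rel_freq_buried))
  }
  tb
}

#' Predict solvation state of hydrophobic residues from conservation bins
#'
#' For each hydrophobic residue of a conservation profile, looks up its
#' bin's exposed-state confidence score in the bin table and calls the
#' residue `"exposed"` when that confidence is strictly above `threshold`
#' (default 2.07), else `"buried"`. Low conservation of hydrophobicity thus
#' signals exposure. Residues outside the hydrophobic prediction set are
#' skipped; bins with undefined confidence give `NA` with a warning.
#'
#' @param profile data.frame from [conservation_profile()] (needs columns
#'   `position`, `residue_name`, `bin_label`).
#' @param table Bin table, e.g. [reference_bin_table()] or
#'   [build_bin_table()].
#' @param threshold Exposed-confidence decision threshold.
#' @param hydrophobic_set 1-letter codes of the residues to predict.
#' @return data.frame with one row per predicted residue: `position`,
#'   `residue_name`, `bin_label`, `confidence_exposed`, `predicted_state`.
#' @export
predict_state <- function(profile, table = reference_bin_table(),
                          threshold = 2.07,
                          hydrophobic_set = c("V", "I", "L", "M", "F")) {
  keep <- to_aa1(profile$residue_name) %in% hydrophobic_set
  pred <- profile[keep, c("position", "residue_name", "bin_label")]
  ce <- table$confidence_exposed[match(pred$bin_label, table$bin)]
  if (any(is.na(ce) & !is.na(pred$bin_label))) {
    warning("residues in bins with undefined confidence left unpredicted")
  }
  pred$confidence_exposed <- ce
  pred$predicted_state <- ifelse(is.na(ce), NA_character_,
                                 ifelse(ce > threshold, "exposed", "buried"))
  rownames(pred) <- NULL
  pred
}
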