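#' Flanking hydrophobicity weight scheme
#'
#' Weights describing how hydrophobic a flanking residue is: F, I, L, M, V
#' and C score 1; the partially hydrophobic A, Y, W score 0.75; S and T
#' score 0.35; every other (hydrophilic) residue scores 0.15.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
flanking_weights <- function() {
  w <- stats::setNames(rep(0.15, 20L), aa1_codes())
  w[c("F", "I", "L", "M", "V", "C")] <- 1
  w[c("A", "Y", "W")] <- 0.75
  w[c("S", "T")] <- 0.35
  w
}

#' Flanking hydrophobicity index of a sequence position
#'
#' Mean flanking weight of the residues at offsets -window..+window
#' (excluding 0) around a position, truncated at the chain termini, so the
#' index lies in [0.15, 1]: 1 when every neighbour is strongly hydrophobic,
#' 0.15 when all are hydrophilic.
#'
#' @param sequence Protein sequence, as a single string or a character
#'   vector of 1-letter codes.
#' @param position 1-based position(s) in the sequence (vectorised).
#' @param window Number of neighbours considered on each side.
#' @param weights Weight map, see [flanking_weights()].
#' @return Numeric vector of flanking indices.
#' @export
flanking_index <- function(sequence, position, window = 2,
                           weights = flanking_weights()) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  sequence <- to_aa1(sequence)
  n <- length(sequence)
  if (n < 2L) stop("no flanking residues: sequence has fewer than 2 residues")
  stopifnot(all(position >= 1L & position <= n))
  vapply(position, function(p) {
    nb <- p + setdiff(-window:window, 0L)
    nb <- nb[nb >= 1L & nb <= n]
    mean(weights[sequence[nb]])
  }, 0)
}

#' Refine near-threshold predictions with flanking hydrophobicity
#'
#' Second-pass rule over [predict_state()] calls: a residue called exposed
#' whose bin confidence lies within `margin` of the decision threshold but
#' which sits in a strongly hydrophobic window (`flanking_index >=
#' flank_high`) is flipped to buried; a near-threshold buried call in a
#' hydrophilic window (`flanking_index <= flank_low`) is flipped to
#' exposed. All other calls pass through. With `margin = 0` no call changes.
#'
#' @param predictions data.frame from [predict_state()].
#' @param sequence The query protein sequence (for the flanking window).
#' @param flank_high,flank_low Flanking-index cut-offs for flipping.
#' @param margin Half-width of the near-threshold confidence band.
#' @param threshold Decision threshold used for the original calls.
#' @param window,weights Passed to [flanking_index()].
#' @return `predictions` with added columns `flanking_index` and
#'   `refined_state`, and an attribute `"flips"` with the flipped rows.
#' @export
refine_predictions <- function(predictions, sequence, flank_high = 0.75,
                               flank_low = 0.35, margin = 1.0,
                               threshold = 2.07, window = 2,
                               weights = flanking_weights()) {
  fi <- flanking_index(sequence, predictions$position, window = window,
                       weights = weights)
  ce <- predictions$confidence_exposed
  st <- predictions$predicted_state
  to_buried <- !is.na(st) & st == "exposed" & ce < threshold + margin &
    fi >= flank_high
  to_exposed <- !is.na(st) & st == "buried" & ce > threshold - margin &
    fi <= flank_low
  refined <- st
  refined[to_buried] <- "buried"
  refined[to_exposed] <- "exposed"
  predictions$flanking_index <- fi
  predictions$refined_state <- refined
  flips <- predictions[to_buried | to_exposed, , drop = FALSE]
  if (nrow(flips)) {
    message(sprintf("flanking refinement flipped %d call(s) at position(s) %s",
                    nrow(flips), paste(flips$position, collapse = ", ")))
  }
  attr(predictions, "flips") <- flips
  predictions
}
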