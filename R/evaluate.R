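#' Confusion counts for two-state solvation prediction
#'
#' Tallies predictions against observed states with the exposed state as
#' positive: tp = exposed called exposed, tn = buried called buried,
#' fp = buried called exposed, fn = exposed called buried. NA predictions
#' are dropped.
#'
#' @param observed,predicted Character vectors of `"buried"`/`"exposed"`.
#' @return Named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  list(tp = sum(observed == "exposed" & predicted == "exposed"),
       tn = sum(observed == "buried" & predicted == "buried"),
       fp = sum(observed == "buried" & predicted == "exposed"),
       fn = sum(observed == "exposed" & predicted == "buried"))
}

#' Prediction accuracy from confusion counts
#'
#' (tp + tn) / (tp + fp + fn + tn).
#'
#' @param counts List with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return Fraction in [0, 1].
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (!isTRUE(total > 0)) stop("no predictions to score: total count is zero")
  (counts$tp + counts$tn) / total
}
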