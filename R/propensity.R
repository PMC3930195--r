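#' Surface and buried propensity of a residue type
#'
#' Propensity of a residue type for the protein surface (or interior): the
#' fraction that type contributes to the exposed (or buried) residue
#' population divided by its fraction of the whole population. A value of 1
#' means no preference; above 1, enrichment.
#'
#' `data` is a labelled residue set: a data.frame with columns
#' `residue_name` (1- or 3-letter) and `state` (`"buried"`/`"exposed"`),
#' plus `protein_id`, `chain` and `residue_index` when flanking statistics
#' are wanted. Tables from [compute_accessibility()] qualify directly;
#' tables from several proteins can be row-bound with a `protein_id`
#' column.
#'
#' @param data Labelled residue set.
#' @param residue_name Residue type (1- or 3-letter code).
#' @return Dimensionless propensity (single number).
#' @export
surface_propensity <- function(data, residue_name) {
  state_propensity(data, residue_name, "exposed")
}

#' @rdname surface_propensity
#' @export
buried_propensity <- function(data, residue_name) {
  state_propensity(data, residue_name, "buried")
}

state_propensity <- function(data, residue_name, state) {
  aa <- to_aa1(data$residue_name)
  type <- to_aa1(residue_name)
  n_all <- length(aa)
  n_state <- sum(data$state == state)
  n_type <- sum(aa == type)
  n_state_type <- sum(aa == type & data$state == state)
  if (n_state == 0L) stop(sprintf("no %s residues in dataset", state))
  if (n_type == 0L) stop(sprintf("no residues of type %s in dataset", residue_name))
  (n_state_type / n_state) / (n_type / n_all)
}

#' Flanking-position propensity around hydrophobic anchors
#'
#' Propensity of a residue type to occur at a fixed sequence offset (-2, -1,
#' +1 or +2) from hydrophobic anchor residues of a given solvation state,
#' normalised by the type's background frequency in the whole dataset
#' exactly as the surface/buried propensities are. Anchors whose offset
#' neighbour falls outside the chain are skipped (no wrap, no padding).
#'
#' @inheritParams surface_propensity
#' @param offset Sequence offset, one of -2, -1, 1, 2.
#' @param anchor_state Solvation state of the anchors, `"buried"` or
#'   `"exposed"`.
#' @param anchors Character vector of 1-letter codes defining the
#'   hydrophobic anchor set.
#' @return Dimensionless propensity (single number).
#' @export
flanking_propensity <- function(data, offset, residue_name,
                                anchor_state = c("buried", "exposed"),
                                anchors = c("V", "I", "L", "M", "F")) {
  anchor_state <- match.arg(anchor_state)
  stopifnot(offset %in% c(-2L, -1L, 1L, 2L))
  aa <- to_aa1(data$residue_name)
  type <- to_aa1(residue_name)
  nb <- neighbour_types(data, aa, offset, anchor_state, anchors)
  if (length(nb) == 0L) stop("no anchor/neighbour pairs at this offset")
  n_all <- length(aa)
  n_type <- sum(aa == type)
  if (n_type == 0L) stop(sprintf("no residues of type %s in dataset", residue_name))
  (sum(nb == type) / length(nb)) / (n_type / n_all)
}

# 1-letter types of the residues found `offset` positions from each anchor
neighbour_types <- function(data, aa, offset, anchor_state, anchors) {
  pid <- if ("protein_id" %in% names(data)) data$protein_id else "p1"
  chain <- if ("chain" %in% names(data)) data$chain else "A"
  key <- paste(pid, chain, data$residue_index, sep = "\r")
  is_anchor <- aa %in% anchors & data$state == anchor_state
  target <- paste(pid, chain, data$residue_index + offset, sep = "\r")[is_anchor]
  hit <- match(target, key)
  aa[hit[!is.na(hit)]]
}

#' Full propensity table
#'
#' Surface and buried propensities for every residue type present in the
#' dataset, with optional flanking-position propensities at offsets -2, -1,
#' +1, +2 for each anchor state, plus the pooled (+k with -k) values.
#'
#' @inheritParams flanking_propensity
#' @param flanking If `TRUE`, add flanking propensity columns.
#' @return data.frame keyed by `residue` (1-letter), with columns
#'   `surface_propensity`, `buried_propensity` and, when `flanking = TRUE`,
#'   `flank_<state>_<offset>` and pooled `flank_<state>_pm<k>` columns
#'   (NA where a type never occurs at that offset).
#' @export
propensity_table <- function(data, flanking = FALSE,
                             anchors = c("V", "I", "L", "M", "F")) {
  aa <- to_aa1(data$residue_name)
  types <- sort(unique(aa))
  out <- data.frame(residue = types, stringsAsFactors = FALSE)
  out$surface_propensity <- vapply(types, function(t) surface_propensity(data, t), 0)
  out$buried_propensity <- vapply(types, function(t) buried_propensity(data, t), 0)
  if (flanking) {
    n_all <- length(aa)
    for (st in c("buried", "exposed")) {
      pooled <- list()
      for (off in c(-2L, -1L, 1L, 2L)) {
        nb <- neighbour_types(data, aa, off, st, anchors)
        prop <- vapply(types, function(t) {
          bg <- sum(aa == t) / n_all
          if (length(nb) == 0L) return(NA_real_)
          (sum(nb == t) / length(nb)) / bg
        }, 0)
        nm <- sprintf("flank_%s_%+d", st, off)
        out[[nm]] <- prop
        pooled[[as.character(abs(off))]] <- c(pooled[[as.character(abs(off))]], list(nb))
      }
      for (k in c("1", "2")) {
        nb <- unlist(pooled[[k]])
        out[[sprintf("flank_%s_pm%s", st, k)]] <- vapply(types, function(t) {
          bg <- sum(aa == t) / n_all
          if (length(nb) == 0L) return(NA_real_)
          (sum(nb == t) / length(nb)) / bg
        }, 0)
      }
    }
  }
  rownames(out) <- NULL
  out
}

# 1-letter amino-acid codes from either coding
to_aa1 <- function(x) {
  x <- as.character(x)
  long <- nchar(x) == 3L
  if (any(long)) x[long] <- bio3d::aa321(x[long])
  toupper(x)
}
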