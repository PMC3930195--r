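#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one list: the geometry of the
#' accessibility calculation (probe 1.4 Angstrom, slice 0.05 Angstrom), the
#' 7 percent two-state RSA threshold, the 30 percent homolog identity
#' cut-off, the gap extra penalty of the conservation scheme, the 2.07
#' exposed-confidence prediction threshold, the hydrophobic prediction set,
#' and the flanking-refinement parameters (refinement off by default).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    probe_radius = 1.4,
    slice_spacing = 0.05,
    rsa_threshold = 7,
    reference_asa = "ala-x-ala",
    min_identity = 30,
    gap_extra_penalty = -2,
    prediction_threshold = 2.07,
    hydrophobic_set = c("V", "I", "L", "M", "F"),
    refine = FALSE,
    flank_high = 0.75,
    flank_low = 0.35,
    margin = 1.0,
    seed = 1L)
}

#' Read or write a pipeline configuration
#'
#' Plain-text (YAML) serialisation of the configuration list; unknown keys
#' are rejected, missing keys fall back to [default_config()].
#'
#' @param config Configuration list.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the full configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(base, cfg)
  merged$hydrophobic_set <- as.character(merged$hydrophobic_set)
  merged
}

#' Run the full prediction pipeline
#'
#' Wires the stages end to end: structure accessibility (PDB to classified
#' RSA table), conservation profiling (aligned FASTA to per-residue scores
#' and bins), training (bin-frequency table from labelled residues),
#' sequence-only prediction of hydrophobic residue solvation (with optional
#' flanking refinement) and evaluation against the structure-derived
#' states. Stages are skippable: give only `structure` for an
#' accessibility run, only `alignment` for sequence-only prediction
#' (against the bundled [reference_bin_table()]), or both for train +
#' evaluate. Outputs are TSVs in `out_dir`, together with the effective
#' configuration (`config.yaml`) and a run log.
#'
#' For train/evaluate the structure's chain given by `chain` (default: the
#' first) is matched position-by-position to the alignment query.
#'
#' @param config Configuration list, see [default_config()]; missing
#'   entries are filled with defaults.
#' @param structure Path to a PDB file or PDB text (optional).
#' @param alignment Path to an aligned FASTA or its text (optional).
#' @param query_id Query identifier in the alignment.
#' @param out_dir Output directory, created if needed.
#' @param train If `TRUE` (and both inputs are given) build the bin table
#'   from this structure/alignment pair instead of using the bundled one.
#' @param chain Chain identifier used to pair structure residues with
#'   alignment positions; defaults to the first chain.
#' @return Invisible list with the computed tables (`rsa`, `profile`,
#'   `bin_table`, `predictions`, `metrics`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), structure = NULL,
                         alignment = NULL, query_id = "query",
                         out_dir = tempfile("hydroscan_run_"),
                         train = FALSE, chain = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  if (is.null(structure) && is.null(alignment)) {
    stop("nothing to do: supply a structure, an alignment, or both")
  }

  res <- prof <- bin_table <- pred <- metrics <- NULL

  if (!is.null(structure)) {
    res <- tryCatch(
      compute_accessibility(structure, probe = cfg$probe_radius,
                            slice = cfg$slice_spacing,
                            threshold = cfg$rsa_threshold,
                            reference = reference_asa(cfg$reference_asa)),
      error = function(e) stop("stage 'asa' failed: ", conditionMessage(e)))
    write_rsa_tsv(res, file.path(out_dir, "rsa.tsv"))
    logf("asa: %d residues, %d exposed / %d buried (threshold %g%%)",
         nrow(res), sum(res$state == "exposed"), sum(res$state == "buried"),
         cfg$rsa_threshold)
  }

  if (!is.null(alignment)) {
    prof <- tryCatch({
      aln <- parse_alignment(alignment, query_id)
      n0 <- length(aln$ids) - 1L
      aln <- identity_filter(aln, min_identity = cfg$min_identity)
      logf("conserve: %d/%d homologs pass the %g%% identity filter",
           length(aln$ids) - 1L, n0, cfg$min_identity)
      conservation_profile(aln, gap_extra = cfg$gap_extra_penalty)
    }, error = function(e) stop("stage 'conserve' failed: ", conditionMessage(e)))
    write_conservation_tsv(prof, file.path(out_dir, "conservation.tsv"))
  }

  if (train) {
    if (is.null(res) || is.null(prof)) {
      stop("stage 'train' failed: training needs both a structure and an alignment")
    }
    bin_table <- tryCatch({
      paired <- pair_profile_states(prof, res, chain, cfg$hydrophobic_set)
      build_bin_table(paired$bin_label, paired$state)
    }, error = function(e) stop("stage 'train' failed: ", conditionMessage(e)))
    write_bin_table(bin_table, file.path(out_dir, "bin_table.tsv"))
    logf("train: bin table from %d hydrophobic residues", nrow(prof))
  } else if (!is.null(prof)) {
    bin_table <- reference_bin_table()
    logf("predict: using bundled reference bin table")
  }

  if (!is.null(prof)) {
    pred <- predict_state(prof, table = bin_table,
                          threshold = cfg$prediction_threshold,
                          hydrophobic_set = cfg$hydrophobic_set)
    if (isTRUE(cfg$refine)) {
      qseq <- paste(prof$residue_name, collapse = "")
      pred <- withCallingHandlers(
        refine_predictions(pred, qseq, flank_high = cfg$flank_high,
                           flank_low = cfg$flank_low, margin = cfg$margin,
                           threshold = cfg$prediction_threshold),
        message = function(m) {
          logf("refine: %s", trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
    }
    utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("predict: %d hydrophobic residues called (threshold %g)",
         nrow(pred), cfg$prediction_threshold)
  }

  if (!is.null(pred) && !is.null(res)) {
    paired <- pair_profile_states(prof, res, chain, cfg$hydrophobic_set)
    call_col <- if ("refined_state" %in% names(pred)) "refined_state" else "predicted_state"
    calls <- pred[[call_col]][match(paired$position, pred$position)]
    cc <- confusion_counts(paired$state, calls)
    metrics <- data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
                          accuracy = accuracy(cc))
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("evaluate: accuracy %.4f (tp %d tn %d fp %d fn %d)",
         metrics$accuracy, cc$tp, cc$tn, cc$fp, cc$fn)
  }

  write_config(cfg, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(rsa = res, profile = prof, bin_table = bin_table,
                 predictions = pred, metrics = metrics, out_dir = out_dir,
                 config = cfg))
}

# hydrophobic residues of one chain, with conservation bin + observed state
pair_profile_states <- function(prof, res, chain, hydrophobic_set) {
  ch <- if (is.null(chain)) res$chain[1L] else chain
  res <- res[res$chain == ch, , drop = FALSE]
  m <- match(prof$position, res$residue_index)
  if (any(is.na(m))) {
    stop("alignment query and structure chain differ in length/positions")
  }
  aa_prof <- to_aa1(prof$residue_name)
  aa_res <- to_aa1(res$residue_name[m])
  if (mean(aa_prof == aa_res) < 0.9) {
    stop("alignment query sequence does not match the structure chain")
  }
  keep <- aa_prof %in% hydrophobic_set
  data.frame(position = prof$position[keep],
             bin_label = prof$bin_label[keep],
             state = res$state[m][keep], stringsAsFactors = FALSE)
}
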