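#' Specification for a synthetic fixture
#'
#' Bundles the parameters of the synthetic structure/alignment generators.
#' Generation is deterministic given `seed` (the global RNG state is left
#' untouched).
#'
#' @param seed Integer seed.
#' @param n_residues Number of residues.
#' @param fold_style `"extended"` (straight chain, everything exposed),
#'   `"compact-cluster"` (jittered dense ball, mixed burial) or
#'   `"two-shell"` (planned buried residues sealed inside icosahedral cages
#'   of exposed residues).
#' @param burial_plan Intended per-residue state, a character vector of
#'   `"buried"`/`"exposed"` of length `n_residues` (used by `"two-shell"`).
#' @param alignment_depth Number of homolog rows for [gen_alignment()].
#' @param conservation_plan Per-position target bin labels (see
#'   [bin_levels()]), NA for positions without a target; length
#'   `n_residues`.
#' @param identity_target Minimum homolog-to-query identity in percent.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_residues = 10L,
                         fold_style = c("extended", "compact-cluster", "two-shell"),
                         burial_plan = NULL, alignment_depth = 10L,
                         conservation_plan = NULL, identity_target = 35) {
  fold_style <- match.arg(fold_style)
  stopifnot(n_residues >= 1L, alignment_depth >= 1L,
            identity_target >= 0, identity_target <= 100)
  if (!is.null(burial_plan)) {
    stopifnot(length(burial_plan) == n_residues,
              all(burial_plan %in% c("buried", "exposed")))
  }
  if (!is.null(conservation_plan)) {
    stopifnot(length(conservation_plan) == n_residues,
              all(is.na(conservation_plan) | conservation_plan %in% bin_levels()))
  }
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 fold_style = fold_style, burial_plan = burial_plan,
                 alignment_depth = as.integer(alignment_depth),
                 conservation_plan = conservation_plan,
                 identity_target = identity_target),
            class = "fixture_spec")
}

#' Generate a synthetic structure with known burial labels
#'
#' Emits a PDB-format poly-residue structure built from one pseudo-atom per
#' residue (a CB-like 1.87-Angstrom carbon sphere) plus the true burial
#' label of every residue. Three geometries:
#'
#' * `extended`: residues on a straight line 3.8 Angstrom apart; every
#'   residue is solvent exposed.
#' * `two-shell`: each planned buried residue sits at the centre of an
#'   icosahedral cage of 12 exposed residues 3.3 Angstrom away, which for a
#'   1.4-Angstrom probe seals the central sphere completely (true RSA 0);
#'   leftover exposed residues go on a distant line. Requires at least 12
#'   exposed residues per buried one, else an infeasible-geometry error.
#' * `compact-cluster`: a seeded jittered ball of atoms; burial labels are
#'   derived from the point-sampling oracle ([shrake_rupley_asa()]) at the
#'   7 percent threshold against the single-sphere reference.
#'
#' Single-sphere residues are a test convention for analytic tractability,
#' not a model of side-chain geometry.
#'
#' @param spec A [fixture_spec()].
#' @return List with `pdb` (character scalar, PDB text), `labels`
#'   (data.frame `chain`, `residue_index`, `residue_name`, `state`).
#' @export
gen_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    resnames <- sample(standard_residues(), n, replace = TRUE)
    if (spec$fold_style == "extended") {
      xyz <- cbind(3.8 * seq_len(n), 0, 0)
      state <- rep("exposed", n)
    } else if (spec$fold_style == "two-shell") {
      plan <- spec$burial_plan
      if (is.null(plan)) stop("two-shell fixtures need a burial_plan")
      state <- plan
      resnames[plan == "buried"] <- sample(c("VAL", "ILE", "LEU", "MET", "PHE"),
                                           sum(plan == "buried"), replace = TRUE)
      xyz <- two_shell_coords(plan)
    } else {
      rad <- 1.7 * max(1, n)^(1/3)
      xyz <- matrix(stats::runif(3L * n, -rad, rad), ncol = 3L)
      atoms <- data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                          radius = unname(vdw_radii()["C"]))
      asa <- shrake_rupley_asa(atoms, n_points = 2000L)
      ref <- unname(reference_asa("single-sphere")[1L])
      state <- classify_state(100 * asa / ref)
    }
    pdb <- paste(c(vapply(seq_len(n), function(i) {
      sprintf("ATOM  %5d  CB  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
              i, resnames[i], i, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], 1.0, 0.0)
    }, ""), "END"), collapse = "\n")
    list(pdb = pdb,
         labels = data.frame(chain = "A", residue_index = seq_len(n),
                             residue_name = resnames, state = state,
                             stringsAsFactors = FALSE))
  })
}

# coordinates honouring a buried/exposed plan: one sealed cage per buried
# residue, cage vertices and overflow positions taken by exposed residues
two_shell_coords <- function(plan) {
  n <- length(plan)
  buried <- which(plan == "buried")
  exposed <- which(plan == "exposed")
  if (length(exposed) < 12L * length(buried)) {
    stop(sprintf(
      "infeasible geometry: %d buried residues need %d cage residues but only %d exposed available",
      length(buried), 12L * length(buried), length(exposed)))
  }
  xyz <- matrix(0, n, 3L)
  verts <- icosahedron_vertices() * 3.3
  for (k in seq_along(buried)) {
    centre <- c(30 * k, 0, 0)
    xyz[buried[k], ] <- centre
    cage <- exposed[(12L * (k - 1L) + 1L):(12L * k)]
    xyz[cage, ] <- sweep(verts, 2L, centre, "+")
  }
  leftover <- exposed[seq_len(length(exposed)) > 12L * length(buried)]
  if (length(leftover)) {
    xyz[leftover, ] <- cbind(10 * seq_along(leftover), 60, 0)
  }
  xyz
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

#' Generate a synthetic alignment with known conservation scores
#'
#' Builds a query-anchored aligned FASTA whose columns are composed to hit
#' each position's target conservation bin exactly under the default weight
#' scheme. Positions with a target bin get a hydrophobic query residue and
#' a homolog column mixing weight-1 (the query residue), weight-0.5 (`A`),
#' polar (`D`) and gap characters, rotated across rows so mismatches spread
#' evenly; positions without a target copy the query. Errors if a target
#' bin is unreachable at the requested depth or if the construction cannot
#' keep every homolog's identity at or above `identity_target`.
#'
#' @param spec A [fixture_spec()]; uses `n_residues`, `alignment_depth`,
#'   `conservation_plan`, `identity_target` and `seed`.
#' @return List with `fasta` (character scalar), `query_id`, and `truth`
#'   (data.frame `position`, `residue_name`, `target_bin`,
#'   `normalized_score`).
#' @export
gen_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  plan <- spec$conservation_plan
  if (is.null(plan)) plan <- rep(NA_character_, spec$n_residues)
  D <- spec$alignment_depth
  with_seed(spec$seed + 1L, {
    n <- spec$n_residues
    hydro <- c("V", "I", "L", "M", "F")
    query <- sample(setdiff(aa1_codes(), hydro), n, replace = TRUE)
    query[!is.na(plan)] <- sample(hydro, sum(!is.na(plan)), replace = TRUE)
    mat <- matrix(rep(query, each = D), nrow = D)
    norm <- rep(NA_real_, n)
    for (j in which(!is.na(plan))) {
      combo <- bin_column_combo(plan[j], D)
      chars <- rep(c(query[j], "A", "D", "-"), combo)
      rot <- ((seq_len(D) - 1L + j) %% D) + 1L
      mat[, j] <- chars[rot]
      norm[j] <- 100 * sum(combo * c(1, 0.5, -2, -4)) / D
    }
    idt <- vapply(seq_len(D), function(r) {
      h <- mat[r, ]
      both <- h != "-"
      100 * sum(query[both] == h[both]) / sum(both)
    }, 0)
    if (any(idt < spec$identity_target)) {
      stop(sprintf(
        "identity target unreachable: minimum homolog identity %.1f%% < %.1f%%",
        min(idt), spec$identity_target))
    }
    ids <- c("query", sprintf("hom%d", seq_len(D)))
    seqs <- c(paste(query, collapse = ""),
              apply(mat, 1L, paste, collapse = ""))
    fasta <- paste(rbind(paste0(">", ids), seqs), collapse = "\n")
    list(fasta = fasta, query_id = "query",
         truth = data.frame(position = seq_len(n), residue_name = query,
                            target_bin = plan, normalized_score = norm,
                            stringsAsFactors = FALSE))
  })
}

# counts (n_weight1, n_weight0.5, n_polar, n_gap) summing to depth whose
# normalised score lands in the target bin, closest to the bin midpoint;
# ties prefer more weight-1 (query-matching) characters, then fewer gaps
bin_column_combo <- function(bin, depth) {
  lv <- bin_levels()
  stopifnot(bin %in% lv)
  i <- match(bin, lv)
  lo <- if (i == 1L) -Inf else 10 * (i - 2L)
  hi <- if (i == 1L) 0 else 10 * (i - 1L)
  mid <- if (i == 1L) -50 else (lo + hi) / 2
  in_bin <- function(x) if (i == 11L) x >= lo & x <= hi else x >= lo & x < hi
  best <- NULL
  best_key <- NULL
  for (g in 0:depth) for (p in 0:(depth - g)) for (k in 0:(depth - g - p)) {
    m <- depth - g - p - k
    score <- 100 * (k + 0.5 * m - 2 * p - 4 * g) / depth
    if (!in_bin(score)) next
    key <- c(abs(score - mid), -k, g, p)
    if (is.null(best) || lex_less(key, best_key)) {
      best <- c(k = k, m = m, p = p, g = g)
      best_key <- key
    }
  }
  if (is.null(best)) {
    stop(sprintf("unreachable target bin '%s' at alignment depth %d", bin, depth))
  }
  best
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-9) return(TRUE)
    if (a[i] > b[i] + 1e-9) return(FALSE)
  }
  FALSE
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
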