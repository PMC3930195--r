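#' Per-atom accessible surface area by the Lee-Richards slice method
#'
#' Rolls a spherical solvent probe over the van der Waals surface: each atom
#' is inflated by the probe radius to R = r_vdw + r_probe, the inflated
#' sphere is cut into sections perpendicular to z at spacing `slice`, and on
#' each section circle the arc length L accessible (not inside any
#' neighbouring inflated sphere) is measured. The atom's ASA is the sum over
#' sections of R / sqrt(R^2 - Z^2) * L * D, where Z is the distance from the
#' sphere centre to the section and D is the section's slab thickness
#' (`slice` for interior sections, shortened at the poles so the slabs tile
#' the sphere exactly; for a lone atom the sum is 4*pi*R^2 for any spacing).
#'
#' Coincident atoms with identical radii are treated as duplicates: the
#' first keeps its full area, later ones contribute 0 and do not occlude.
#'
#' @param atoms data.frame from [parse_structure()] (needs columns `x`, `y`,
#'   `z`, `radius`).
#' @param probe Probe radius in Angstrom (1.4 for water).
#' @param slice Section spacing Delta-Z in Angstrom.
#' @return Numeric vector, ASA in Angstrom^2 per atom (same order).
#' @export
lee_richards_asa <- function(atoms, probe = 1.4, slice = 0.05) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L, probe >= 0, slice > 0)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  R <- atoms$radius + probe
  if (any(R <= 0)) stop("non-positive atom radius")
  n <- nrow(xyz)
  dup <- duplicate_atoms(xyz, atoms$radius)

  asa <- numeric(n)
  for (i in seq_len(n)) {
    if (dup[i]) next
    Ri <- R[i]
    dx <- xyz[, 1L] - xyz[i, 1L]
    dy <- xyz[, 2L] - xyz[i, 2L]
    dz <- xyz[, 3L] - xyz[i, 3L]
    cand <- which(!dup & seq_len(n) != i & dx * dx + dy * dy + dz * dz < (Ri + R)^2)

    breaks <- seq(-Ri, Ri, by = slice)
    if (breaks[length(breaks)] < Ri) breaks <- c(breaks, Ri)
    zmid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
    width <- diff(breaks)

    area <- 0
    for (s in seq_along(zmid)) {
      Z <- zmid[s]
      ri2 <- Ri * Ri - Z * Z
      if (ri2 <= 0) next
      ri <- sqrt(ri2)
      open_angle <- 2 * pi
      if (length(cand)) {
        zj <- dz[cand] - Z          # neighbour centre height above this section
        cut <- which(abs(zj) < R[cand])
        ivs <- NULL
        blocked <- FALSE
        for (k in cut) {
          j <- cand[k]
          rj <- sqrt(R[j]^2 - (dz[j] - Z)^2)
          dxy <- sqrt(dx[j]^2 + dy[j]^2)
          if (dxy >= ri + rj) next                 # circles apart
          if (dxy + ri <= rj) { blocked <- TRUE; break }  # section swallowed
          if (dxy + rj <= ri) next                 # neighbour disk inside circle
          ca <- (dxy * dxy + ri2 - rj * rj) / (2 * dxy * ri)
          alpha <- acos(min(1, max(-1, ca)))
          beta <- atan2(dy[j], dx[j])
          ivs <- rbind(ivs, c(beta - alpha, beta + alpha))
        }
        if (blocked) next
        if (!is.null(ivs)) open_angle <- 2 * pi - arc_union(ivs)
      }
      # R/sqrt(R^2 - Z^2) * L * D with L = ri * open_angle
      area <- area + Ri * open_angle * width[s]
    }
    asa[i] <- area
  }
  asa
}

#' Per-atom accessible surface area by point sampling (Shrake-Rupley)
#'
#' Independent brute-force check for [lee_richards_asa()]: quasi-uniform
#' points are spread on each probe-inflated sphere (deterministic Fibonacci
#' lattice) and the ASA is the sphere area times the fraction of points not
#' inside any neighbouring inflated sphere. Intended for testing; it shares
#' no code path with the slice method.
#'
#' @inheritParams lee_richards_asa
#' @param n_points Number of surface sample points per atom (>= 100).
#' @return Numeric vector, ASA in Angstrom^2 per atom.
#' @export
shrake_rupley_asa <- function(atoms, probe = 1.4, n_points = 2000L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L, probe >= 0, n_points >= 100L)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  R <- atoms$radius + probe
  n <- nrow(xyz)
  dup <- duplicate_atoms(xyz, atoms$radius)
  pts <- fibonacci_sphere(n_points)

  asa <- numeric(n)
  for (i in seq_len(n)) {
    if (dup[i]) next
    p <- pts * R[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i || dup[j]) next
      d2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
            (p[, 3L] - xyz[j, 3L])^2
      free <- free & d2 >= R[j]^2
      if (!any(free)) break
    }
    asa[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  asa
}

# deterministic quasi-uniform unit-sphere points (golden-angle lattice)
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

# flag exact duplicates (same centre, same radius); first occurrence kept
duplicate_atoms <- function(xyz, radius) {
  key <- paste(xyz[, 1L], xyz[, 2L], xyz[, 3L], radius, sep = "\r")
  duplicated(key)
}

# total length of the union of angular intervals on a circle;
# ivs is a 2-column matrix of (start, end), end > start, any real values
arc_union <- function(ivs) {
  a <- ivs[, 1L] %% (2 * pi)
  b <- a + (ivs[, 2L] - ivs[, 1L])
  wrap <- b > 2 * pi
  if (any(wrap)) {
    extra <- cbind(0, b[wrap] - 2 * pi)
    ivs <- rbind(cbind(a, pmin(b, 2 * pi)), extra)
  } else {
    ivs <- cbind(a, b)
  }
  o <- order(ivs[, 1L])
  ivs <- ivs[o, , drop = FALSE]
  total <- 0
  cur_s <- ivs[1L, 1L]; cur_e <- ivs[1L, 2L]
  if (nrow(ivs) > 1L) {
    for (k in 2:nrow(ivs)) {
      if (ivs[k, 1L] > cur_e) {
        total <- total + (cur_e - cur_s)
        cur_s <- ivs[k, 1L]; cur_e <- ivs[k, 2L]
      } else if (ivs[k, 2L] > cur_e) cur_e <- ivs[k, 2L]
    }
  }
  min(total + (cur_e - cur_s), 2 * pi)
}
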