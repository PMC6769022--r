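#' Default van der Waals radii (angstrom)
#'
#' A single documented table keyed by element symbol. Values follow the
#' commonly used Bondi-style set for protein heavy atoms. Calcium and other
#' ions are hetero atoms and excluded from SASA by default, so they need no
#' entry unless explicitly included.
#'
#' @return named numeric vector of radii
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

#' Parameters for Shrake-Rupley SASA
#'
#' @param probe_radius solvent probe radius in angstrom (default 1.4, a water
#'   molecule)
#' @param n_points sphere sample points per atom (default 960); must be >= 32
#' @param radii named radius table, element symbol -> angstrom
#' @param fallback_radius radius used for elements absent from `radii`
#'   (default NULL: unknown elements are an error). When used, the result is
#'   flagged.
#' @return list of class `sasa_params`
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii = default_vdw_radii(), fallback_radius = NULL) {
  stopifnot(probe_radius >= 0, n_points >= 32)
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii = radii, fallback_radius = fallback_radius),
            class = "sasa_params")
}

#' Deterministic unit-sphere sample points (generalized spiral)
#'
#' Golden-angle spiral: near-uniform, fully deterministic, so SASA values are
#' bit-stable across runs for fixed parameters.
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# resolve per-atom radii from the params table; error lists offenders
atom_radii <- function(elements, p) {
  r <- unname(p$radii[elements])
  miss <- is.na(r)
  if (any(miss)) {
    if (is.null(p$fallback_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(sort(unique(elements[miss])), collapse = ", "),
           "; extend the radii table or set fallback_radius")
    }
    r[miss] <- p$fallback_radius
  }
  list(r = r, used_fallback = any(miss))
}

#' Solvent-accessible surface area by Shrake-Rupley sphere sampling
#'
#' Each atom is inflated by the probe radius and sampled with a fixed spiral
#' point set; a sample point is accessible if it lies outside every
#' neighboring inflated sphere. Per-atom area is the accessible fraction
#' times the inflated-sphere area. Neighbor search uses spatial binning with
#' bin width `2 * max(radius) + 2 * probe`, so cost scales with atoms times
#' local neighbors.
#'
#' @param s a `Structure`
#' @param params a [sasa_params()] object
#' @param include_hetero include hetero atoms (waters are still excluded)
#' @return list of class `sasa_result`: `per_atom_area` (one value per atom
#'   used, with the atom subset in `$atoms`), `per_residue_area` data.frame,
#'   `total_area`, and the parameters used
#' @export
compute_sasa <- function(s, params = sasa_params(), include_hetero = FALSE) {
  a <- s$atoms
  keep <- if (include_hetero) !(a$residue_name %in% WATER_NAMES) else !a$is_hetero
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms to compute SASA for")
  X <- as.matrix(a[, c("x", "y", "z")])
  rr <- atom_radii(a$element, params)
  r <- rr$r + params$probe_radius          # inflated radii
  n <- nrow(X)
  P <- sphere_points(params$n_points)

  # spatial binning
  w <- 2 * max(rr$r) + 2 * params$probe_radius
  bin <- floor(sweep(X, 2, apply(X, 2, min)) / w)
  key <- bin[, 1] + 4096 * (bin[, 2] + 4096 * bin[, 3])
  cells <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  area <- numeric(n)
  for (i in seq_len(n)) {
    nb_keys <- (bin[i, 1] + offsets[, 1]) +
      4096 * ((bin[i, 2] + offsets[, 2]) + 4096 * (bin[i, 3] + offsets[, 3]))
    cand <- unlist(cells[as.character(nb_keys)], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) > 0) {
      d2 <- colSums((t(X[cand, , drop = FALSE]) - X[i, ])^2)
      cand <- cand[d2 < (r[i] + r[cand])^2]
    }
    if (length(cand) == 0) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sweep(P * r[i], 2, X[i, ], "+")          # n_points x 3
    C <- X[cand, , drop = FALSE]                    # k x 3
    # squared distances points x neighbors
    d2 <- outer(rowSums(pts^2), rowSums(C^2), "+") - 2 * pts %*% t(C)
    buried <- rowSums(d2 < matrix(r[cand]^2, nrow(pts), length(cand),
                                  byrow = TRUE)) > 0
    area[i] <- mean(!buried) * 4 * pi * r[i]^2
  }

  key_res <- residue_key(a)
  per_res <- data.frame(chain = a$chain_id, residue_number = a$residue_number,
                        residue_name = a$residue_name, key = key_res,
                        stringsAsFactors = FALSE)
  first <- !duplicated(key_res)
  res_area <- tapply(area, factor(key_res, levels = key_res[first]), sum)
  per_residue <- data.frame(
    chain = per_res$chain[first],
    residue_number = per_res$residue_number[first],
    residue_name = per_res$residue_name[first],
    area = as.numeric(res_area),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(per_atom_area = area, per_residue_area = per_residue,
                 total_area = sum(area), atoms = a, params = params,
                 used_fallback_radius = rr$used_fallback),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("SASA:", sprintf("%.2f", x$total_area), "A^2 over",
      length(x$per_atom_area), "atoms (probe",
      x$params$probe_radius, "A,", x$params$n_points, "points)\n")
  invisible(x)
}

#' Analytic SASA of one or two intersecting spheres
#'
#' Closed-form reference for sphere fixtures: an isolated atom exposes
#' `4 pi (r + probe)^2`; for two overlapping atoms each loses a spherical
#' cap. Valid for at most pairwise overlap, which is all the generator emits.
#'
#' @param radii vector of van der Waals radii
#' @param centers n x 3 matrix of centers
#' @param probe_radius probe radius
#' @return list with `per_atom` and `total` analytic areas
#' @export
analytic_sphere_sasa <- function(radii, centers, probe_radius = 1.4) {
  centers <- matrix(centers, ncol = 3)
  R <- radii + probe_radius
  n <- length(R)
  per <- 4 * pi * R^2
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
        if (d < R[i] + R[j] && d > abs(R[i] - R[j])) {
          hi <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
          hj <- R[j] - (d^2 + R[j]^2 - R[i]^2) / (2 * d)
          per[i] <- per[i] - 2 * pi * R[i] * hi
          per[j] <- per[j] - 2 * pi * R[j] * hj
        } else if (d <= abs(R[i] - R[j])) {
          # one sphere engulfed
          if (R[i] < R[j]) per[i] <- 0 else per[j] <- 0
        }
      }
    }
  }
  list(per_atom = pmax(per, 0), total = sum(pmax(per, 0)))
}
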