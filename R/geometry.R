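## Kabsch superposition on paired coordinate sets
kabsch <- function(P, Q) {
  # P, Q: n x 3, rows paired; returns rotation R, translation t minimizing
  # || (P R^T + t) - Q ||  (i.e. transform applied to P)
  n <- nrow(P)
  if (n < 3) stop("need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(crossprod(P0, Q0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop("degenerate geometry: paired points are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- sweep(P %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, n_pairs = n)
}

#' Optimal Calpha superposition (Kabsch) and RMSD
#'
#' Pairs Calpha atoms of one chain in each structure, either by shared
#' author residue numbers (the default; the intersection of modeled residues
#' carrying a Calpha in both chains, which tolerates different missing
#' loops) or by an explicit pair list, and returns the least-squares proper
#' rotation, translation, and RMSD.
#'
#' @param a,b `Structure` objects
#' @param chain_a,chain_b chain ids (defaults: first chain of each)
#' @param pairs optional two-column matrix/data.frame of residue numbers
#'   (a, b) to pair explicitly
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (angstrom), `n_pairs`
#' @export
superpose_ca <- function(a, b, chain_a = NULL, chain_b = NULL, pairs = NULL) {
  if (is.null(chain_a)) chain_a <- a$atoms$chain_id[1]
  if (is.null(chain_b)) chain_b <- b$atoms$chain_id[1]
  ca_a <- a$atoms[a$atoms$chain_id == chain_a & a$atoms$atom_name == "CA" &
                    !a$atoms$is_hetero, , drop = FALSE]
  ca_b <- b$atoms[b$atoms$chain_id == chain_b & b$atoms$atom_name == "CA" &
                    !b$atoms$is_hetero, , drop = FALSE]
  if (is.null(pairs)) {
    shared <- intersect(ca_a$residue_number, ca_b$residue_number)
    pairs <- cbind(shared, shared)
  } else {
    pairs <- as.matrix(pairs)
  }
  if (nrow(pairs) < 3)
    stop("fewer than 3 Calpha pairs; cannot superpose")
  ia <- match(pairs[, 1], ca_a$residue_number)
  ib <- match(pairs[, 2], ca_b$residue_number)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("pair list references residues without a modeled Calpha")
  P <- as.matrix(ca_a[ia, c("x", "y", "z")])
  Q <- as.matrix(ca_b[ib, c("x", "y", "z")])
  out <- kabsch(P, Q)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d Calpha pairs: rmsd %.4f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Principal (long) axis of a point cloud
#'
#' Largest-variance eigenvector of the unweighted coordinate covariance.
#' The sign is fixed to point from the centroid of the N-terminal half of
#' the points toward the centroid of the C-terminal half, so axes of tandem
#' repeats consistently run N to C. If the top two eigenvalues agree within
#' 1% the cloud has no unique long axis and the result carries a
#' `degenerate` attribute.
#'
#' @param X n x 3 matrix of coordinates in N-to-C order (n >= 3)
#' @return unit 3-vector; attribute `degenerate` TRUE/FALSE
#' @export
principal_axis <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 points")
  X0 <- sweep(X, 2, colMeans(X))
  if (max(abs(X0)) < 1e-9) stop("all points coincident")
  ev <- eigen(crossprod(X0) / nrow(X), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  n <- nrow(X)
  half_n <- colMeans(X[seq_len(floor(n / 2)), , drop = FALSE])
  half_c <- colMeans(X[(floor(n / 2) + 1):n, , drop = FALSE])
  if (sum(axis * (half_c - half_n)) < 0) axis <- -axis
  attr(axis, "degenerate") <-
    (ev$values[1] - ev$values[2]) < 0.01 * ev$values[1]
  axis
}

ca_coords_of_repeat <- function(s, annotations, label) {
  k <- which(annotations$label == label)
  if (length(k) != 1) stop("repeat label not found: ", label)
  a <- s$atoms
  sel <- a$chain_id == annotations$chain[k] & a$atom_name == "CA" &
    !a$is_hetero & a$residue_number >= annotations$start[k] &
    a$residue_number <= annotations$end[k]
  X <- as.matrix(a[sel, c("x", "y", "z")])
  if (nrow(X) < 3) stop("repeat ", label, " has fewer than 3 Calpha atoms")
  X[order(a$residue_number[sel]), , drop = FALSE]
}

# Kabsch on two equal-shape clouds paired by N-to-C order (truncated to the
# shorter); adequate when repeats share a common template, as for the
# synthetic rods and for an external reference repeat of matching length.
superpose_clouds <- function(P, Q) {
  m <- min(nrow(P), nrow(Q))
  kabsch(P[seq_len(m), , drop = FALSE], Q[seq_len(m), , drop = FALSE])
}

#' Azimuthal-angle profile of tandem repeats
#'
#' Builds a reference frame in which the long axis of a reference repeat is
#' +z and the projected long axis of a second reference repeat is +x
#' (phi = 0). Then, for every consecutive repeat pair along the chain, the
#' N-terminal repeat is superposed onto the z-reference repeat and the
#' azimuthal angle phi of the C-terminal repeat's projected axis is
#' reported, with its polar tilt from +z. phi is measured counterclockwise
#' about +z viewed from +z, in (-180, 180].
#'
#' The reference defaults to the first two annotated repeats of the chain
#' itself (internal mode, so the first profile entry is 0 by construction);
#' an external reference structure with its own two annotated repeats can be
#' supplied instead.
#'
#' @param s a `Structure`
#' @param annotations `repeat_annotation` in N-to-C order
#' @param reference NULL for internal mode, or
#'   `list(structure=, annotations=, z_repeat=, x_repeat=)`
#' @param degeneracy_tol minimum length of the xy-projection of a unit axis
#'   for phi to be defined (default 0.05, i.e. tilt below ~2.9 degrees is
#'   flagged undefined)
#' @return data.frame of class `azimuthal_profile` (repeat, phi, tilt,
#'   defined) for repeats 2..n; attribute `frame` describes the reference
#' @export
azimuthal_profile <- function(s, annotations, reference = NULL,
                              degeneracy_tol = 0.05) {
  if (is.null(reference)) {
    if (nrow(annotations) < 2)
      stop("internal reference mode needs at least two annotated repeats")
    reference <- list(structure = s, annotations = annotations,
                      z_repeat = annotations$label[1],
                      x_repeat = annotations$label[2])
    frame_desc <- sprintf("internal: z = %s axis, x = %s projection",
                          reference$z_repeat, reference$x_repeat)
  } else {
    frame_desc <- sprintf("external: z = %s axis, x = %s projection",
                          reference$z_repeat, reference$x_repeat)
  }
  ref_z_X <- ca_coords_of_repeat(reference$structure, reference$annotations,
                                 reference$z_repeat)
  ref_x_X <- ca_coords_of_repeat(reference$structure, reference$annotations,
                                 reference$x_repeat)
  zax <- principal_axis(ref_z_X)
  xraw <- principal_axis(ref_x_X)
  xp <- xraw - sum(xraw * zax) * zax
  if (sqrt(sum(xp^2)) < degeneracy_tol)
    stop("reference x-repeat axis is parallel to z; frame undefined")
  xax <- xp / sqrt(sum(xp^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])

  labs <- annotations$label
  out <- data.frame(repeat_label = labs[-1], phi = NA_real_,
                    tilt = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(annotations) - 1)) {
    Xn <- ca_coords_of_repeat(s, annotations, labs[k])
    Xc <- ca_coords_of_repeat(s, annotations, labs[k + 1])
    fit <- superpose_clouds(Xn, ref_z_X)
    Xc_f <- sweep(Xc %*% t(fit$rotation), 2, fit$translation, "+")
    ax <- principal_axis(Xc_f)
    az <- sum(ax * zax)
    proj <- c(sum(ax * xax), sum(ax * yax))
    out$tilt[k] <- acos(pmin(pmax(az, -1), 1)) * 180 / pi
    if (sqrt(sum(proj^2)) >= degeneracy_tol) {
      phi <- atan2(proj[2], proj[1]) * 180 / pi
      if (phi <= -180) phi <- phi + 360
      out$phi[k] <- phi
      out$defined[k] <- TRUE
    }
  }
  attr(out, "frame") <- frame_desc
  class(out) <- c("azimuthal_profile", "data.frame")
  out
}
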