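## Synthetic fixtures with ground truth. Every generator writes payloads in
## the same standard formats the analysis functions read (PDB, FASTA, CSV,
## PNG) plus a JSON manifest, and returns the ground truth alongside, so the
## whole pipeline is testable without any external structure downloads.

fixture_bundle <- function(dir, paths, truth, seed = NA_integer_) {
  manifest <- list(files = paths, seed = seed, truth = truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(dir = dir, paths = paths, truth = truth, seed = seed),
            class = "fixture_bundle")
}

sphere_atoms <- function(elements, centers, resname = "SPH") {
  centers <- matrix(centers, ncol = 3)
  n <- length(elements)
  data.frame(serial = seq_len(n), atom_name = elements, element = elements,
             residue_name = resname, chain_id = "A",
             residue_number = seq_len(n), insertion_code = "",
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             occupancy = 1, b_factor = 0, is_hetero = FALSE,
             stringsAsFactors = FALSE)
}

#' Sphere-cluster fixture with analytic SASA ground truth
#'
#' Writes a PDB of pseudo-atoms whose van der Waals radii come from the
#' standard element table (each requested radius must match a table entry),
#' together with the closed-form accessible area: isolated spheres expose
#' their full inflated surface, and a pairwise-overlapping pair each lose a
#' spherical cap.
#'
#' @param dir output directory (created if needed)
#' @param radii vector of van der Waals radii; each must equal a
#'   [default_vdw_radii()] value so the standard reader/SASA path applies
#' @param centers n x 3 matrix of centers (angstrom)
#' @param probe_radius probe used for the analytic truth (default 1.4)
#' @return `fixture_bundle` with `truth$per_atom`, `truth$total`
#' @export
make_sphere_system <- function(dir, radii, centers, probe_radius = 1.4) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(all(radii > 0), nrow(centers) == length(radii))
  if (nrow(centers) > 1 &&
      min(dist(centers)) < 1e-9)
    stop("coincident sphere centers")
  tab <- default_vdw_radii()
  el <- names(tab)[match(radii, tab)]
  if (any(is.na(el)))
    stop("radius not representable by an element in the standard table: ",
         paste(radii[is.na(el)], collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- new_structure(sphere_atoms(el, centers),
                     cell = c(200, 200, 200, 90, 90, 90),
                     sym_ops = list(list(R = diag(3), t = c(0, 0, 0))))
  pdb <- file.path(dir, "spheres.pdb")
  cif <- file.path(dir, "spheres.cif")
  write_structure(s, pdb, "pdb")
  write_structure(s, cif, "mmcif")
  truth <- analytic_sphere_sasa(radii, centers, probe_radius)
  fixture_bundle(dir, list(pdb = pdb, mmcif = cif),
                 list(per_atom = truth$per_atom, total = truth$total,
                      probe_radius = probe_radius))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}

# canonical prolate repeat cloud: a gentle helix of Calpha points, centered,
# rotated so its principal axis is exactly +z with the N-to-C sign convention
canonical_repeat_cloud <- function(m, rise_per_res = 1.5, helix_radius = 2) {
  i <- seq_len(m)
  X <- cbind(helix_radius * cos(2 * pi * i / 7),
             helix_radius * sin(2 * pi * i / 7),
             (i - (m + 1) / 2) * rise_per_res)
  X <- sweep(X, 2, colMeans(X))
  ax <- principal_axis(X)
  # exact rotation taking ax -> +z: express points in an orthonormal basis
  # whose third vector is ax
  seed_v <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed_v - sum(seed_v * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  R <- rbind(e1, e2, ax)
  X <- X %*% t(R)
  # re-fix the sign convention exactly
  if (principal_axis(X)[3] < 0) X <- X %*% diag(c(1, -1, -1))
  X
}

#' Idealized tandem-repeat rod with prescribed inter-repeat twists
#'
#' Builds a Calpha-only chain of identical prolate repeat clouds. Repeat
#' k+1 is placed by rotating the frame of repeat k by the prescribed twist
#' about its axis, tilting by `tilt` degrees, and rising along the axis, so
#' the azimuthal angle recovered for each consecutive pair (against the
#' emitted two-repeat reference structure, whose second repeat tilts at
#' azimuth zero) equals the prescribed twist by construction. A rod built
#' with zero tilt has degenerate azimuths and triggers a warning.
#'
#' @param dir output directory
#' @param n_repeats number of repeats (labels `EC1`..)
#' @param twist_list degrees, length `n_repeats - 1`
#' @param residues_per_repeat Calpha count per repeat (default 24)
#' @param tilt inter-repeat tilt in degrees (default 10)
#' @param rise center-to-center rise in angstrom (default 40)
#' @param jitter_sd optional isotropic coordinate jitter, angstrom
#' @param seed RNG seed for the jitter
#' @return `fixture_bundle`; payloads `rod.pdb`, `reference.pdb`,
#'   `annotations.csv`, `reference_annotations.csv`; `truth$twists`
#' @export
make_repeat_rod <- function(dir, n_repeats, twist_list,
                            residues_per_repeat = 24, tilt = 10, rise = 40,
                            jitter_sd = 0, seed = 1L) {
  if (n_repeats < 1) stop("need at least one repeat")
  if (length(twist_list) != max(n_repeats - 1, 0))
    stop("twist_list must have n_repeats - 1 entries")
  if (tilt == 0 && any(twist_list != 0))
    warning("tilt is 0: azimuthal angles are degenerate by construction")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- residues_per_repeat
  C0 <- canonical_repeat_cloud(m)

  place <- function(R, t) sweep(C0 %*% t(R), 2, t, "+")
  Rk <- diag(3); tk <- c(0, 0, 0)
  clouds <- list(place(Rk, tk))
  if (n_repeats > 1) {
    for (k in seq_len(n_repeats - 1)) {
      step <- rot_z(twist_list[k]) %*% rot_y(tilt)
      tk <- tk + as.numeric(Rk %*% c(0, 0, rise))
      Rk <- Rk %*% step
      clouds[[k + 1]] <- place(Rk, tk)
    }
  }
  X <- do.call(rbind, clouds)
  if (jitter_sd > 0) {
    set.seed(seed)
    X <- X + matrix(rnorm(length(X), 0, jitter_sd), ncol = 3)
  }
  n <- nrow(X)
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA", element = "C",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = seq_len(n), insertion_code = "",
                      x = X[, 1], y = X[, 2], z = X[, 3], occupancy = 1,
                      b_factor = 0, is_hetero = FALSE,
                      stringsAsFactors = FALSE)
  rod <- new_structure(atoms)
  ann <- data.frame(label = paste0("EC", seq_len(n_repeats)), chain = "A",
                    start = (seq_len(n_repeats) - 1) * m + 1,
                    end = seq_len(n_repeats) * m)

  # external reference: repeat 1 in canonical pose, repeat 2 tilted at
  # azimuth zero
  Xr <- rbind(place(diag(3), c(0, 0, 0)),
              place(rot_y(tilt), c(0, 0, rise)))
  ref_atoms <- atoms[seq_len(2 * m), ]
  ref_atoms$x <- Xr[, 1]; ref_atoms$y <- Xr[, 2]; ref_atoms$z <- Xr[, 3]
  ref_atoms$chain_id <- "R"
  ref <- new_structure(ref_atoms)
  ref_ann <- data.frame(label = c("REF1", "REF2"), chain = "R",
                        start = c(1, m + 1), end = c(m, 2 * m))

  paths <- list(rod = file.path(dir, "rod.pdb"),
                reference = file.path(dir, "reference.pdb"),
                annotations = file.path(dir, "annotations.csv"),
                reference_annotations = file.path(dir,
                                                  "reference_annotations.csv"))
  write_structure(rod, paths$rod, "pdb")
  write_structure(ref, paths$reference, "pdb")
  write.csv(ann, paths$annotations, row.names = FALSE)
  write.csv(ref_ann, paths$reference_annotations, row.names = FALSE)
  fixture_bundle(dir, paths,
                 list(twists = twist_list, tilt = tilt,
                      n_repeats = n_repeats), seed)
}

#' Antiparallel toy dimer with known contacts
#'
#' Two identical Calpha-only tandem-repeat chains; chain B is flipped
#' head-to-tail (antiparallel) and offset laterally by `gap`, overlapping
#' chain A over the last `overlap_residues` residues of each chain. With
#' full overlap every repeat i of one chain faces repeat n+1-i of the
#' other, the geometry of a fully overlapped antiparallel EC1-4 adhesion
#' dimer. The ground truth (contacting residues and touching repeat pairs)
#' is derived from the construction by a direct distance check at the SASA
#' contact radius.
#'
#' @param dir output directory
#' @param n_repeats repeats per chain (default 4)
#' @param residues_per_repeat default 10
#' @param gap lateral axis-to-axis separation, angstrom (default 5); chains
#'   closer than 1 angstrom anywhere are a clash and an error
#' @param overlap_residues residues of each chain inside the overlap zone
#'   (default: all of them)
#' @param resname residue name given to all residues (default `"ALA"`)
#' @param probe_radius probe for the contact-truth distance check
#' @return `fixture_bundle`; payloads `dimer.pdb`, `annotations.csv`;
#'   `truth$contact_residues`, `truth$contact_pairs`
#' @export
make_toy_dimer <- function(dir, n_repeats = 4, residues_per_repeat = 10,
                           gap = 5, overlap_residues = NULL, resname = "ALA",
                           probe_radius = 1.4) {
  stopifnot(gap > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- n_repeats * residues_per_repeat
  if (is.null(overlap_residues)) overlap_residues <- m
  stopifnot(overlap_residues >= 1, overlap_residues <= m)
  dz <- 3.8
  i <- seq_len(m)
  # slight lateral stagger keeps the cloud non-collinear
  XA <- cbind(0.5 * cos(2 * pi * i / 7), 0.5 * sin(2 * pi * i / 7),
              (i - 1) * dz)
  # antiparallel copy: rotate 180 degrees about x (y -> -y, z -> -z),
  # shift so the overlap zone covers the top `overlap_residues` of A
  XB <- XA %*% diag(c(1, -1, -1))
  shift_z <- max(XA[, 3]) + min(XA[, 3]) + (m - overlap_residues) * dz
  XB[, 3] <- XB[, 3] + shift_z
  XB[, 1] <- XB[, 1] + gap

  D <- as.matrix(dist(rbind(XA, XB)))[seq_len(m), m + seq_len(m)]
  if (min(D) < 1)
    stop("chains clash (minimum inter-chain distance ",
         sprintf("%.2f", min(D)), " A < 1 A); increase gap")

  mk <- function(X, ch) {
    data.frame(serial = seq_len(m), atom_name = "CA", element = "C",
               residue_name = resname, chain_id = ch,
               residue_number = seq_len(m), insertion_code = "",
               x = X[, 1], y = X[, 2], z = X[, 3], occupancy = 1,
               b_factor = 0, is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  s <- new_structure(rbind(mk(XA, "A"), mk(XB, "B")))
  ann <- rbind(
    data.frame(label = paste0("EC", seq_len(n_repeats)), chain = "A",
               start = (seq_len(n_repeats) - 1) * residues_per_repeat + 1,
               end = seq_len(n_repeats) * residues_per_repeat),
    data.frame(label = paste0("EC", seq_len(n_repeats)), chain = "B",
               start = (seq_len(n_repeats) - 1) * residues_per_repeat + 1,
               end = seq_len(n_repeats) * residues_per_repeat))

  # construction truth: residues whose inflated spheres can lose area
  contact_r <- 2 * (default_vdw_radii()[["C"]] + probe_radius)
  touching <- D < contact_r
  res_a <- which(apply(touching, 1, any))
  res_b <- which(apply(touching, 2, any))
  rep_of <- function(r) paste0("EC", (r - 1) %/% residues_per_repeat + 1)
  pairs <- unique(apply(which(touching, arr.ind = TRUE), 1, function(ij)
    paste(rep_of(ij[1]), rep_of(ij[2]), sep = ":")))
  paths <- list(dimer = file.path(dir, "dimer.pdb"),
                annotations = file.path(dir, "annotations.csv"))
  write_structure(s, paths$dimer, "pdb")
  write.csv(ann, paths$annotations, row.names = FALSE)
  fixture_bundle(dir, paths,
                 list(contact_residues_a = res_a, contact_residues_b = res_b,
                      contact_pairs = sort(pairs), gap = gap,
                      overlap_residues = overlap_residues))
}

#' Synthetic alignment with prescribed conserved columns
#'
#' Listed columns are invariant (a fixed residue, cycled over the amino-acid
#' alphabet); every other column is drawn uniformly over the 20 residues,
#' independently per sequence, under the seed. Emulates an MSA of
#' orthologous ectodomain sequences with a known conservation pattern.
#'
#' @param dir output directory
#' @param n_seqs number of sequences (>= 2)
#' @param length alignment columns
#' @param conserved_columns integer vector within `1..length`
#' @param seed RNG seed
#' @return `fixture_bundle`; payload `alignment.fasta`;
#'   `truth$conserved` logical per column
#' @export
make_alignment <- function(dir, n_seqs, length, conserved_columns = integer(0),
                           seed = 1L) {
  if (n_seqs < 2) stop("alignment needs at least 2 sequences")
  stopifnot(all(conserved_columns >= 1), all(conserved_columns <= length))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  M <- matrix(sample(AA20, n_seqs * length, replace = TRUE), n_seqs, length)
  for (idx in seq_along(conserved_columns)) {
    M[, conserved_columns[idx]] <- AA20[(idx - 1) %% 20 + 1]
  }
  ids <- sprintf("seq%03d", seq_len(n_seqs))
  a <- new_alignment(ids, apply(M, 1, paste, collapse = ""))
  path <- file.path(dir, "alignment.fasta")
  write_alignment(a, path)
  truth_cons <- seq_len(length) %in% conserved_columns
  fixture_bundle(dir, list(alignment = path),
                 list(conserved = truth_cons), seed)
}

#' Synthetic sigmoidal melt curve with known midpoint
#'
#' Logistic fluorescence trace on the instrument's temperature grid
#' (10 to 95 degrees C in 0.2-degree steps by default) plus optional
#' Gaussian noise, written as CSV.
#'
#' @param dir output directory
#' @param tm true midpoint, degrees C (must lie inside the grid)
#' @param slope logistic width parameter, degrees (default 2)
#' @param noise_sd Gaussian noise SD as a fraction of the signal range
#' @param seed RNG seed
#' @param t_min,t_max,step temperature grid
#' @return `fixture_bundle`; payload `melt.csv`; `truth$tm`
#' @export
make_melt_curve <- function(dir, tm, slope = 2, noise_sd = 0, seed = 1L,
                            t_min = 10, t_max = 95, step = 0.2) {
  stopifnot(tm > t_min, tm < t_max)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  temps <- seq(t_min, t_max, by = step)
  f <- 1 / (1 + exp(-(temps - tm) / slope))
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(f), 0, noise_sd)
  }
  path <- file.path(dir, "melt.csv")
  write.csv(data.frame(temperature = temps, fluorescence = f), path,
            row.names = FALSE)
  fixture_bundle(dir, list(curve = path), list(tm = tm, slope = slope,
                                               noise_sd = noise_sd), seed)
}

#' Synthetic bead-aggregate image with known particle areas
#'
#' Bright discs on a dim background with optional Gaussian noise, written as
#' grayscale PNG. The truth records each disc's exact pixel area (the count
#' of pixel centers inside the disc).
#'
#' @param dir output directory
#' @param shape `c(rows, cols)` in pixels
#' @param discs data.frame with columns `x`, `y`, `r` (pixels)
#' @param noise_sd Gaussian noise SD (intensity units)
#' @param intensity disc intensity (default 0.9)
#' @param background background intensity (default 0.1)
#' @param seed RNG seed
#' @return `fixture_bundle`; payload `beads.png`; `truth$areas`
#' @export
make_bead_image <- function(dir, shape = c(200, 200), discs,
                            noise_sd = 0, intensity = 0.9, background = 0.1,
                            seed = 1L) {
  stopifnot(is.data.frame(discs), all(c("x", "y", "r") %in% names(discs)))
  if (any(discs$x - discs$r < 1 | discs$x + discs$r > shape[2] |
            discs$y - discs$r < 1 | discs$y + discs$r > shape[1]))
    stop("disc(s) extend outside the image")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- matrix(background, shape[1], shape[2])
  cx <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  cy <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  areas <- integer(nrow(discs))
  for (k in seq_len(nrow(discs))) {
    inside <- (cx - discs$x[k])^2 + (cy - discs$y[k])^2 <= discs$r[k]^2
    img[inside] <- intensity
    areas[k] <- sum(inside)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
  }
  img <- pmin(pmax(img, 0), 1)
  path <- file.path(dir, "beads.png")
  png::writePNG(img, path)
  fixture_bundle(dir, list(image = path),
                 list(areas = areas, n_discs = nrow(discs)), seed)
}
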