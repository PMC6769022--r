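# in-code fixture builders shared across test files

fixture_dir <- function(...) {
  d <- file.path(tempfile("fix"), ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# a minimal polymer atom table: one atom per residue unless atom_names given
toy_atoms <- function(chain = "A", resno = 1:5, x = NULL, y = 0, z = NULL,
                      atom_name = "CA", element = "C", resname = "ALA",
                      hetero = FALSE) {
  n <- length(resno)
  if (is.null(x)) x <- seq_len(n) * 3.8
  if (is.null(z)) z <- 0
  data.frame(serial = seq_len(n), atom_name = atom_name, element = element,
             residue_name = resname, chain_id = chain, residue_number = resno,
             insertion_code = "", x = x, y = y, z = z, occupancy = 1,
             b_factor = 0, is_hetero = hetero, stringsAsFactors = FALSE)
}

toy_structure <- function(...) new_structure(toy_atoms(...))

# a non-collinear Calpha chain for superposition tests
helix_structure <- function(n = 30, chain = "A", seed_phase = 0) {
  i <- seq_len(n)
  new_structure(toy_atoms(chain = chain, resno = i,
                          x = 2.3 * cos(2 * pi * i / 3.6 + seed_phase),
                          y = 2.3 * sin(2 * pi * i / 3.6 + seed_phase),
                          z = 1.5 * i))
}

rigid_transform <- function(s, R, t) {
  X <- coords(s) %*% t(R)
  X <- sweep(X, 2, t, "+")
  out <- s
  out$atoms$x <- X[, 1]; out$atoms$y <- X[, 2]; out$atoms$z <- X[, 3]
  out
}

rotation_about <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# fast SASA parameters for property loops
fast_sasa <- function() sasa_params(n_points = 240)
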