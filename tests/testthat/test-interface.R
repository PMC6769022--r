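make_dimer_bs <- function(gap = 5, n_repeats = 4, residues_per_repeat = 10,
                          params = sasa_params(), ...) {
  b <- make_toy_dimer(fixture_dir(), n_repeats = n_repeats,
                      residues_per_repeat = residues_per_repeat, gap = gap,
                      ...)
  s <- read_structure(b$paths$dimer)
  ann <- read_repeat_annotation(s, b$paths$annotations)
  list(bundle = b, s = s, ann = ann,
       bs = buried_surface(s, "A", "B", params, ann))
}

test_that("distant protomers bury nothing", {
  f <- make_dimer_bs(gap = 100, n_repeats = 2, residues_per_repeat = 5)
  expect_true(all(f$bs$bsa == 0))
  expect_equal(interface_area(f$bs), 0)
})

test_that("burial is local to the constructed contacts", {
  f <- make_dimer_bs(n_repeats = 2, residues_per_repeat = 8,
                     overlap_residues = 4)
  buried_a <- f$bs$residue_number[f$bs$protomer == "A" & f$bs$bsa > 0]
  expect_true(all(buried_a %in% f$bundle$truth$contact_residues_a))
  buried_b <- f$bs$residue_number[f$bs$protomer == "B" & f$bs$bsa > 0]
  expect_true(all(buried_b %in% f$bundle$truth$contact_residues_b))
})

test_that("two-sphere protomers reproduce the analytic cap loss", {
  at <- rbind(toy_atoms(chain = "A", resno = 1, x = 0, y = 0, z = 0),
              toy_atoms(chain = "B", resno = 1, x = 2, y = 0, z = 0))
  s <- new_structure(at)
  bs <- buried_surface(s, "A", "B")
  truth <- analytic_sphere_sasa(c(1.7, 1.7), rbind(c(0, 0, 0), c(2, 0, 0)))
  iso <- 4 * pi * 3.1^2
  expect_equal(bs$bsa, rep(iso - truth$per_atom[1], 2), tolerance = 0.02)
  expect_equal(bs$asa_free, rep(iso, 2), tolerance = 1e-6)
})

test_that("buried surface equals an independent three-way SASA subtraction", {
  f <- make_dimer_bs(n_repeats = 2, residues_per_repeat = 6,
                     params = fast_sasa())
  a <- select_atoms(f$s, chains = "A")
  b <- select_atoms(f$s, chains = "B")
  free <- rbind(compute_sasa(a, fast_sasa())$per_residue_area,
                compute_sasa(b, fast_sasa())$per_residue_area)
  bound <- compute_sasa(f$s, fast_sasa())$per_residue_area
  key <- paste(free$chain, free$residue_number)
  direct <- pmax(free$area -
                   bound$area[match(key, paste(bound$chain,
                                               bound$residue_number))], 0)
  got <- f$bs$bsa[match(key, paste(f$bs$chain, f$bs$residue_number))]
  expect_equal(got, direct, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("symmetric dimers bury equal area on both protomers", {
  f <- make_dimer_bs()
  burial_a <- sum(f$bs$bsa[f$bs$protomer == "A"])
  burial_b <- sum(f$bs$bsa[f$bs$protomer == "B"])
  expect_equal(burial_a, burial_b, tolerance = 0.05)
  # swapping protomer roles leaves the interface area identical
  bs_swapped <- buried_surface(f$s, "B", "A", sasa_params(), f$ann)
  expect_equal(interface_area(bs_swapped), interface_area(f$bs),
               tolerance = 1e-9)
})

test_that("repeat-pair decomposition conserves the total exactly", {
  f <- make_dimer_bs()
  pp <- repeat_pair_areas(f$bs)
  expect_equal(sum(pp$area), interface_area(f$bs), tolerance = 1e-3)
  # antiparallel full overlap touches the reversed repeat pairing
  expect_true(all(c("EC1:EC4", "EC2:EC3", "EC3:EC2", "EC4:EC1") %in% pp$pair))
  expect_true(all(pp$pair %in% c(f$bundle$truth$contact_pairs, "other")))
  expect_true(all(pp$area >= 0))
})

test_that("a single-contact toy yields a single repeat pair", {
  f <- make_dimer_bs(n_repeats = 2, residues_per_repeat = 8,
                     overlap_residues = 3)
  pp <- repeat_pair_areas(f$bs)
  expect_equal(pp$pair[pp$area > 1], "EC2:EC2")
})

test_that("interface residues follow the buried-fraction threshold", {
  f <- make_dimer_bs()
  ir20 <- interface_residues(f$bs, 0.20)
  expect_true(all(ir20$buried_fraction >= 0.20))
  expect_true(all(ir20$asa_free > 0))
  # raising the threshold never adds residues
  prev <- nrow(interface_residues(f$bs, 0.05))
  for (th in c(0.1, 0.2, 0.4, 0.8)) {
    cur <- nrow(interface_residues(f$bs, th))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("composition fractions sum to one and follow the class map", {
  f <- make_dimer_bs(resname = "LEU")
  comp <- composition(f$bs)
  expect_equal(sum(comp$overall), 1, tolerance = 1e-6)
  expect_equal(unname(comp$overall["hydrophobic"]), 1)
  # unmapped residue names are an error naming the offender
  f2 <- make_dimer_bs(n_repeats = 2, residues_per_repeat = 5,
                      resname = "XYZ", params = fast_sasa())
  expect_error(composition(f2$bs), "XYZ")
})

test_that("per-pair composition covers every buried pair", {
  f <- make_dimer_bs()
  comp <- composition(f$bs, per_pair = TRUE)
  expect_true(all(abs(rowSums(comp$per_pair[, -1]) - 1) < 1e-6))
})

test_that("salt bridges are detected across protomers within the cutoff", {
  lys <- toy_atoms(chain = "A", resno = 1, atom_name = "NZ", element = "N",
                   resname = "LYS", x = 0, y = 0, z = 0)
  glu <- toy_atoms(chain = "B", resno = 2, atom_name = "OE1", element = "O",
                   resname = "GLU", x = 3, y = 0, z = 0)
  s <- new_structure(rbind(lys, glu))
  sb <- detect_salt_bridges(s, "A", "B", cutoff = 4.0)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.0, tolerance = 1e-9)
  expect_equal(sb$atom_a, "NZ")
  # beyond the cutoff: nothing
  glu_far <- glu; glu_far$x <- 4.5
  s2 <- new_structure(rbind(lys, glu_far))
  expect_equal(nrow(detect_salt_bridges(s2, "A", "B", cutoff = 4.0)), 0)
  # histidine only when opted in
  his <- toy_atoms(chain = "A", resno = 1, atom_name = "NE2", element = "N",
                   resname = "HIS", x = 0, y = 0, z = 0)
  s3 <- new_structure(rbind(his, glu))
  expect_equal(nrow(detect_salt_bridges(s3, "A", "B")), 0)
  expect_equal(nrow(detect_salt_bridges(s3, "A", "B", include_his = TRUE)), 1)
})

test_that("acid on protomer A against base on protomer B is also found", {
  asp <- toy_atoms(chain = "A", resno = 7, atom_name = "OD2", element = "O",
                   resname = "ASP", x = 0, y = 0, z = 0)
  arg <- toy_atoms(chain = "B", resno = 9, atom_name = "NH1", element = "N",
                   resname = "ARG", x = 0, y = 3.5, z = 0)
  s <- new_structure(rbind(asp, arg))
  sb <- detect_salt_bridges(s, "A", "B")
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)
})

test_that("interface classification uses a strict cutoff", {
  expect_equal(classify_interface(1539, 856), "plausible-biological")
  expect_equal(classify_interface(1270, 856), "plausible-biological")
  expect_equal(classify_interface(100, 856), "crystal-contact-scale")
  expect_equal(classify_interface(856, 856), "crystal-contact-scale")
})

test_that("overlapping protomer chain sets are rejected", {
  f <- make_dimer_bs(n_repeats = 2, residues_per_repeat = 5,
                     params = fast_sasa())
  expect_error(buried_surface(f$s, c("A", "B"), "B"), "overlap")
})
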