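test_that("a one-atom PDB round-trips through read_structure", {
  d <- fixture_dir()
  path <- file.path(d, "one.pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 20.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(n_atoms(s), 1)
  expect_equal(unname(coords(s)[1, ]), c(1, 2, 3))
  expect_equal(s$atoms$residue_name, "ALA")
  expect_equal(s$atoms$chain_id, "A")
  expect_false(s$atoms$is_hetero)
})

test_that("read-write-read round-trips preserve atoms in both formats", {
  b <- make_sphere_system(fixture_dir(), radii = c(1.7, 1.55, 1.52),
                          centers = rbind(c(0, 0, 0), c(10, 0, 0),
                                          c(0, 12, 3)))
  for (fmt in c("pdb", "mmcif")) {
    s1 <- read_structure(b$paths[[if (fmt == "pdb") "pdb" else "mmcif"]])
    d <- fixture_dir()
    p2 <- file.path(d, paste0("again.", if (fmt == "pdb") "pdb" else "cif"))
    write_structure(s1, p2, fmt)
    s2 <- read_structure(p2)
    expect_equal(n_atoms(s2), n_atoms(s1))
    expect_equal(s2$atoms$atom_name, s1$atoms$atom_name)
    expect_equal(s2$atoms$element, s1$atoms$element)
    expect_lt(max(abs(coords(s2) - coords(s1))), 1e-3)
    expect_equal(s2$cell, s1$cell, tolerance = 1e-6)
  }
})

test_that("truncated mmCIF input is a parse error", {
  d <- fixture_dir()
  path <- file.path(d, "broken.cif")
  writeLines(c("data_x", "loop_", "_atom_site.group_PDB"), path)
  expect_error(read_structure(path), "parse|atoms")
})

test_that("alternate locations resolve to the highest occupancy conformer", {
  d <- fixture_dir()
  path <- file.path(d, "alt.pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70 10.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$atoms$x, 5)
})

test_that("select_atoms filters chains, residues and atom names", {
  s <- new_structure(rbind(toy_atoms(chain = "A", resno = 1:8),
                           toy_atoms(chain = "B", resno = 1:4)))
  expect_equal(unique(select_atoms(s, chains = "A")$atoms$chain_id), "A")
  sel <- select_atoms(s, chains = "A", residues = 3:10, atom_names = "CA")
  expect_equal(n_atoms(sel), 6)  # residues 3..8 exist
  expect_error(select_atoms(s, chains = "Z"), "not present")
  expect_error(select_atoms(s, chains = "A", residues = 100),
               "matched no atoms")
})

test_that("repeat assignment validates ranges and labels residues", {
  s <- toy_structure(resno = c(50, 150, 500))
  ann <- assign_repeats(s, data.frame(label = c("EC1", "EC2"), chain = "A",
                                      start = c(3, 103), end = c(102, 214)))
  rr <- residue_repeats(s, ann)
  expect_equal(rr$repeat_label, c("EC1", "EC2", "unassigned"))
  expect_error(
    assign_repeats(s, data.frame(label = c("a", "b"), chain = "A",
                                 start = c(1, 5), end = c(10, 15))),
    "overlapping")
  expect_error(
    assign_repeats(s, data.frame(label = "a", chain = "Q", start = 1,
                                 end = 2)),
    "absent chain")
})

test_that("span_residue_count matches loop and insertion lengths", {
  s <- toy_structure(resno = 1:450)
  expect_identical(span_residue_count(s, "A", 66, 75), 10L)
  expect_identical(span_residue_count(s, "A", 335, 345), 11L)
  expect_identical(span_residue_count(s, "A", 392, 397), 6L)
  short <- toy_structure(resno = 1:5)
  expect_identical(span_residue_count(short, "A", 3, 9), 3L)
  expect_error(span_residue_count(short, "Z", 1, 2), "chain")
  # monotone non-decreasing in end residue
  counts <- vapply(66:80, function(e) span_residue_count(s, "A", 66, e),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("insertion-coded residues count as distinct", {
  at <- rbind(toy_atoms(resno = c(1, 2, 2, 3)), deparse.level = 0)
  at$insertion_code <- c("", "", "A", "")
  s <- new_structure(at)
  expect_identical(span_residue_count(s, "A", 1, 3), 4L)
})

test_that("apply_symmetry is exact for identity and involutions", {
  b <- make_sphere_system(fixture_dir(), radii = c(1.7, 1.7),
                          centers = rbind(c(0, 0, 0), c(3, 4, 5)))
  s <- read_structure(b$paths$mmcif)
  id <- apply_symmetry(s, 1)
  expect_lt(max(abs(coords(id) - coords(s))), 1e-9)

  # add a 2-fold about z and apply it twice
  s$sym_ops <- c(s$sym_ops, list(parse_twofold <- list(
    R = diag(c(-1, -1, 1)), t = c(0, 0, 0))))
  twice <- apply_symmetry(apply_symmetry(s, 2), 2)
  expect_lt(max(abs(coords(twice) - coords(s))), 1e-6)
  expect_false(any(twice$atoms$chain_id %in% s$atoms$chain_id))
})

test_that("P1 lattice shift translates by the orthogonalized cell vector", {
  # triclinic cell: hand-computed orthogonalization, a along x so a shift of
  # (1,0,0) adds exactly a to x; a (0,1,0) shift adds (b cos(gamma),
  # b sin(gamma), 0)
  at <- toy_atoms(resno = 1:3)
  s <- new_structure(at, cell = c(10, 12, 14, 90, 90, 120),
                     sym_ops = list(list(R = diag(3), t = c(0, 0, 0))))
  sx <- apply_symmetry(s, 1, lattice_shift = c(1, 0, 0))
  expect_equal(coords(sx) - coords(s),
               matrix(rep(c(10, 0, 0), each = 3), ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  sy <- apply_symmetry(s, 1, lattice_shift = c(0, 1, 0))
  expect_equal(coords(sy) - coords(s),
               matrix(rep(c(12 * cos(2 * pi / 3), 12 * sin(2 * pi / 3), 0),
                          each = 3), ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("apply_symmetry preserves intra-chain distances", {
  b <- make_repeat_rod(fixture_dir(), 2, 45)
  s <- read_structure(b$paths$rod)
  # c-unique monoclinic-style cell: a two-fold about z is a rigid transform
  s$cell <- c(50, 60, 70, 90, 90, 110)
  s$sym_ops <- list(list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0)))
  sm <- apply_symmetry(s, 1, lattice_shift = c(1, -1, 0))
  expect_lt(max(abs(dist(coords(sm)) - dist(coords(s)))), 1e-6)
})

test_that("missing cell or symmetry instructs the user", {
  s <- toy_structure()
  expect_error(apply_symmetry(s, 1), "pre-assembled")
})

test_that("chain sequences derive from polymer residues only", {
  at <- rbind(toy_atoms(resname = "ALA", resno = 1:3),
              toy_atoms(chain = "W", resname = "HOH", resno = 1,
                        atom_name = "O", element = "O", hetero = TRUE))
  s <- new_structure(at)
  expect_equal(unname(chain_sequences(s)), "AAA")
})
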