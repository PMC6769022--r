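write_fasta <- function(ids, seqs) {
  p <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), p)
  p
}

write_clustal <- function(ids, seqs) {
  p <- tempfile(fileext = ".aln")
  nm <- formatC(ids, width = 15, flag = "-")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               paste0(nm, " ", seqs),
               paste0(strrep(" ", 16), strrep("*", nchar(seqs[1])))), p)
  p
}

test_that("FASTA and Clustal inputs parse to the same alignment", {
  ids <- c("q", "r"); seqs <- c("ACWWGT", "AC--GT")
  a1 <- read_alignment(write_fasta(ids, seqs))
  a2 <- read_alignment(write_clustal(ids, seqs))
  expect_equal(a1$seqs, a2$seqs, ignore_attr = TRUE)
  expect_equal(a1$n_col, 6)
})

test_that("ragged and illegal alignments are rejected", {
  expect_error(read_alignment(write_fasta(c("a", "b"), c("ACD", "AC"))),
               "ragged|parse")
  expect_error(new_alignment(c("a", "b"), c("AC1", "ACD")), "illegal.*1")
  expect_error(new_alignment("a", "ACD"), "at least 2")
})

test_that("conservation scores match entropy closed forms", {
  a <- new_alignment(c("s1", "s2"), c("DA", "DV"))
  prof <- conservation_scores(a)
  expect_equal(prof$score[1], 1.0)
  expect_equal(prof$bin[1], 9L)
  expect_equal(prof$score[2], 1 - log(2) / log(20), tolerance = 1e-12)
  expect_equal(prof$bin[2], 7L)
  # column uniform over all 20 residues scores zero, bin 1
  a20 <- new_alignment(sprintf("q%02d", 1:20), AA <- strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  p20 <- conservation_scores(a20)
  expect_equal(p20$score[1], 0)
  expect_equal(p20$bin[1], 1L)
})

test_that("gappy columns are masked and row order does not matter", {
  a <- new_alignment(c("a", "b", "c"), c("A-", "A-", "AC"))
  prof <- conservation_scores(a)
  expect_false(prof$masked[1])
  expect_true(prof$masked[2])       # gap fraction 2/3 > 0.5
  expect_true(is.na(prof$score[2]))
  b <- make_alignment(fixture_dir(), n_seqs = 12, length = 40,
                      conserved_columns = c(3, 17, 30), seed = 5)
  aln <- read_alignment(b$paths$alignment)
  p1 <- conservation_scores(aln)
  perm <- new_alignment(rev(aln$ids), rev(unname(aln$seqs)))
  p2 <- conservation_scores(perm)
  expect_equal(p1$score, p2$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1, na.rm = TRUE))
  expect_true(all(p1$score[b$truth$conserved] == 1))
})

test_that("conserved columns of synthetic alignments score one, noise low", {
  b <- make_alignment(fixture_dir(), n_seqs = 200, length = 60,
                      conserved_columns = integer(0), seed = 11)
  prof <- conservation_scores(read_alignment(b$paths$alignment))
  expect_lt(mean(prof$score), 0.2)
})

test_that("alignment maps onto structure residues through author numbering", {
  a <- new_alignment(c("ref", "other"), c("ADEF", "ADEF"))
  s <- new_structure(toy_atoms(resno = 1:4,
                               resname = c("ALA", "ASP", "GLU", "PHE")))
  m <- map_alignment_to_structure(a, "ref", s, "A")
  expect_equal(nrow(m), 4)
  expect_equal(m$score, rep(1, 4))
  # unmodeled residues are simply unmapped
  s2 <- new_structure(toy_atoms(resno = c(1, 4),
                                resname = c("ALA", "PHE")))
  m2 <- map_alignment_to_structure(a, "ref", s2, "A")
  expect_equal(m2$residue_number, c(1, 4))
  # too many disagreements abort
  s3 <- new_structure(toy_atoms(resno = 1:4, resname = "TRP"))
  expect_error(map_alignment_to_structure(a, "ref", s3, "A",
                                          max_mismatch = 2), "mismatch")
  expect_error(map_alignment_to_structure(a, "absent", s, "A"), "absent")
})

test_that("identity and similarity follow the column-counting rules", {
  a <- new_alignment(c("x", "y"), c("AAAA", "AAAA"))
  is0 <- identity_similarity(a)
  expect_equal(is0$identity[1, 2], 100)
  expect_equal(diag(is0$identity), c(x = 100, y = 100))
  a1 <- new_alignment(c("x", "y"), c("AAAA", "VVVV"))
  is1 <- identity_similarity(a1, groups = list(c("A", "V")))
  expect_equal(is1$identity[1, 2], 0)
  expect_equal(is1$similarity[1, 2], 100)
  a2 <- new_alignment(c("x", "y"), c("AAD-", "AAE-"))
  is2 <- identity_similarity(a2)   # D/E grouped by default
  expect_equal(is2$identity[1, 2], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(is2$similarity[1, 2], 100)
  expect_true(all(is2$similarity >= is2$identity))
})

test_that("insertions relative to a reference are located in query coordinates", {
  a <- new_alignment(c("q", "r"), c("ACWWGT", "AC--GT"))
  ins <- find_insertions(a, "q", "r")
  expect_equal(ins, data.frame(start = 3L, end = 4L, length = 2L))
  expect_equal(nrow(find_insertions(a, "r", "q")), 0)
  same <- new_alignment(c("q", "r"), c("AC-GT", "AC-GT"))
  expect_equal(nrow(find_insertions(same, "q", "r")), 0)
})

test_that("insertion spans agree with a brute-force scanner on small cases", {
  # enumerate gap placements on 6-column toys
  brute <- function(q, r) {
    qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
    qpos <- cumsum(qs != "-")
    hits <- which(rs == "-" & qs != "-")
    if (length(hits) == 0) return(0L)
    length(unique(cumsum(c(1, diff(hits) != 1))))
  }
  set.seed(3)
  for (rep in 1:40) {
    q <- paste(sample(c("A", "C", "G"), 6, TRUE), collapse = "")
    rch <- sample(c("D", "-"), 6, TRUE)
    r <- paste(rch, collapse = "")
    a <- new_alignment(c("q", "r"), c(q, r))
    expect_equal(nrow(find_insertions(a, "q", "r")), brute(q, r))
  }
})

test_that("glycosylation sequons follow the N-X(not P)-S/T and WXXW rules", {
  hits <- scan_glyco_sequons("ANGSA")
  expect_equal(hits$position[hits$motif == "N-linked"], 2L)
  expect_equal(nrow(scan_glyco_sequons("ANPSA")), 0)
  ch <- scan_glyco_sequons("WAAWAAW")
  expect_equal(ch$position[ch$motif == "C-mannosylation"], c(1L, 4L))
  # brute-force cross-check on random sequences
  set.seed(9)
  for (rep in 1:25) {
    seqc <- sample(c("N", "P", "S", "T", "W", "A"), 30, TRUE)
    sq <- paste(seqc, collapse = "")
    want_n <- which(vapply(1:28, function(i)
      seqc[i] == "N" && seqc[i + 1] != "P" && seqc[i + 2] %in% c("S", "T"),
      logical(1)))
    got <- scan_glyco_sequons(sq)
    expect_equal(got$position[got$motif == "N-linked"], as.integer(want_n))
  }
})

test_that("named ectodomain N-sites appear among sequon hits", {
  # sequence engineered to carry sequons at the positions of the three
  # predicted N-glycosylation sites of the PCDH1 ectodomain
  n_sites <- c(89, 248, 346)
  seqc <- rep("A", 400)
  for (p in n_sites) { seqc[p] <- "N"; seqc[p + 2] <- "T" }
  hits <- scan_glyco_sequons(paste(seqc, collapse = ""))
  expect_true(all(n_sites %in% hits$position[hits$motif == "N-linked"]))
})

test_that("calcium motifs scan with DXNDN suppressing its inner DXD", {
  h1 <- scan_calcium_motifs("ADINDNA")
  expect_equal(h1$motif, "DXNDN")
  expect_equal(h1$position, 2L)
  expect_equal(scan_calcium_motifs("DRE")$position, 1L)
  h3 <- scan_calcium_motifs("DADADAD")
  expect_equal(h3$position[h3$motif == "DXD"], c(1L, 3L, 5L))
  h4 <- scan_calcium_motifs("DYEA")
  expect_equal(h4$motif, "DYE")
})

test_that("conservation bins paint into the B-factor column", {
  a <- new_alignment(c("ref", "o"), c("ADEF", "ADEF"))
  s <- new_structure(toy_atoms(resno = 1:4,
                               resname = c("ALA", "ASP", "GLU", "PHE")))
  m <- map_alignment_to_structure(a, "ref", s, "A")
  p <- tempfile(fileext = ".pdb")
  paint_conservation(s, "A", m, p)
  painted <- read_structure(p)
  expect_equal(painted$atoms$b_factor, rep(9, 4))
})
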