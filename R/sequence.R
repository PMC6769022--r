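AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a validated multiple sequence alignment
#'
#' @param ids character vector of record ids (unique)
#' @param seqs character vector of gapped sequences (equal lengths; residues
#'   are the 20 amino acids, gap is `-`; `.` is normalized to `-`)
#' @return list of class `alignment` with `ids`, `seqs`, `n_col`
#' @export
new_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2) stop("alignment needs at least 2 records")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  seqs <- toupper(gsub("\\.", "-", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths ", paste(unique(lens),
                                                      collapse = ", "))
  ok <- c(AA20, "-")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ok)
  if (length(bad) > 0)
    stop("illegal alignment character(s): ", paste(bad, collapse = " "))
  structure(list(ids = ids, seqs = setNames(seqs, ids), n_col = lens[1]),
            class = "alignment")
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`
#' @return an `alignment`
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("aln", "clustal", "clu")) "clustal" else "fasta"
  }
  msa <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("failed to parse ", format, " alignment '",
                             path, "': ", conditionMessage(e), call. = FALSE))
  seqs <- as.character(Biostrings::unmasked(msa))
  new_alignment(names(seqs), unname(seqs))
}

#' Write an alignment as aligned FASTA
#' @param a an `alignment`
#' @param path output path
#' @return the path, invisibly
#' @export
write_alignment <- function(a, path) {
  writeLines(as.vector(rbind(paste0(">", a$ids), unname(a$seqs))), path)
  invisible(path)
}

aln_matrix <- function(a) {
  do.call(rbind, strsplit(unname(a$seqs), ""))
}

#' Per-column conservation scores with nine bins
#'
#' Score of a column is `1 - H / ln(20)` where `H` is the Shannon entropy of
#' its amino-acid frequencies, gaps excluded: an invariant column scores 1,
#' a column uniform over the 20 residues scores 0. Columns with gap fraction
#' above 0.5 (including all-gap columns) are masked: their score and bin are
#' NA. Bins partition [0, 1] into nine equal-width intervals (bin 1 least,
#' bin 9 most conserved), mirroring the nine-color conservation palette
#' customary for structure figures.
#'
#' @param a an `alignment`
#' @return data.frame of class `conservation_profile`: `column`, `score`,
#'   `bin`, `gap_fraction`, `masked`
#' @export
conservation_scores <- function(a) {
  M <- aln_matrix(a)
  n <- nrow(M)
  out <- data.frame(column = seq_len(ncol(M)), score = NA_real_,
                    bin = NA_integer_, gap_fraction = NA_real_,
                    masked = FALSE)
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    gaps <- col == "-"
    out$gap_fraction[j] <- mean(gaps)
    if (out$gap_fraction[j] > 0.5) {
      out$masked[j] <- TRUE
      next
    }
    freq <- table(col[!gaps]) / sum(!gaps)
    H <- -sum(freq * log(freq))
    sc <- max(0, 1 - H / log(20))
    out$score[j] <- sc
    out$bin[j] <- min(9L, as.integer(floor(sc * 9)) + 1L)
  }
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Map alignment conservation onto structure residues
#'
#' Uses the reference alignment row: its k-th ungapped position is taken to
#' be author residue number `k + offset` of the chain. Modeled residues
#' whose amino acid disagrees with the reference row are counted as
#' mismatches; more than `max_mismatch` aborts (unmodeled residues are
#' simply absent, as structures routinely miss loops).
#'
#' @param a an `alignment`
#' @param reference_id id of the row matching the structure's sequence
#' @param s a `Structure`
#' @param chain chain id
#' @param offset author number of reference position 1, minus 1 (default 0)
#' @param max_mismatch tolerated sequence disagreements (default 5)
#' @return data.frame (residue_number, residue_name, column, score, bin)
#' @export
map_alignment_to_structure <- function(a, reference_id, s, chain,
                                       offset = 0, max_mismatch = 5) {
  if (!reference_id %in% a$ids)
    stop("reference id not in alignment: ", reference_id)
  prof <- conservation_scores(a)
  ref <- strsplit(a$seqs[[reference_id]], "")[[1]]
  ungapped_pos <- cumsum(ref != "-")
  at <- s$atoms[!s$atoms$is_hetero & s$atoms$chain_id == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not present: ", chain)
  res <- at[!duplicated(residue_key(at)), , drop = FALSE]
  res_one <- three_to_one(res$residue_name)

  cols <- integer(0); rows <- integer(0)
  mism <- 0
  for (i in seq_len(nrow(res))) {
    k <- res$residue_number[i] - offset
    j <- match(k, ungapped_pos * (ref != "-"))  # alignment column of pos k
    if (is.na(j) || k < 1) next
    if (ref[j] != res_one[i]) mism <- mism + 1
    cols <- c(cols, j); rows <- c(rows, i)
  }
  if (mism > max_mismatch)
    stop("structure/alignment sequence mismatch at ", mism,
         " residues (max_mismatch = ", max_mismatch, ")")
  data.frame(residue_number = res$residue_number[rows],
             residue_name = res$residue_name[rows],
             column = cols,
             score = prof$score[cols],
             bin = prof$bin[cols],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default similarity groups
#'
#' Conservative-substitution classes used for percent similarity:
#' \{I,L,V,M\}, \{F,W,Y\}, \{K,R,H\}, \{D,E\}, \{S,T\}, \{N,Q\}, \{A,G\},
#' \{C\}, \{P\}.
#' @return list of character vectors
#' @export
default_similarity_groups <- function() {
  list(c("I", "L", "V", "M"), c("F", "W", "Y"), c("K", "R", "H"),
       c("D", "E"), c("S", "T"), c("N", "Q"), c("A", "G"), "C", "P")
}

#' Pairwise percent identity and similarity
#'
#' For each sequence pair, columns where both records are gapped are
#' excluded; identity is the percentage of remaining columns with identical
#' residues (a gap against a residue is a difference), and similarity
#' additionally counts substitutions within a similarity group.
#'
#' @param a an `alignment`
#' @param groups list of character vectors of interchangeable residues
#' @return list with symmetric `identity` and `similarity` matrices (%),
#'   diagonal 100
#' @export
identity_similarity <- function(a, groups = default_similarity_groups()) {
  M <- aln_matrix(a)
  n <- nrow(M)
  grp <- setNames(rep(seq_along(groups), lengths(groups)),
                  unlist(groups))
  gidx <- function(x) {
    g <- unname(grp[x]); g[is.na(g)] <- -match(x[is.na(g)], AA20)
    g
  }
  idm <- simm <- matrix(100, n, n, dimnames = list(a$ids, a$ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      x <- M[i, ]; y <- M[j, ]
      scored <- !(x == "-" & y == "-")
      ns <- sum(scored)
      ident <- sum(x[scored] == y[scored] & x[scored] != "-")
      both <- x[scored] != "-" & y[scored] != "-"
      simil <- ident + sum(both & x[scored] != y[scored] &
                             gidx(x[scored]) == gidx(y[scored]))
      idm[i, j] <- idm[j, i] <- 100 * ident / ns
      simm[i, j] <- simm[j, i] <- 100 * simil / ns
    }
  }
  list(identity = idm, similarity = simm)
}

#' Insertions of a query relative to a reference row
#'
#' Maximal alignment runs where the reference is gapped and the query has
#' residues; reported in 1-based ungapped query coordinates. The six-residue
#' and eleven-residue EC4 insertions that distinguish delta-protocadherin
#' sequences are found this way.
#'
#' @param a an `alignment`
#' @param query_id,reference_id row ids
#' @return data.frame (start, end, length) in query coordinates
#' @export
find_insertions <- function(a, query_id, reference_id) {
  for (id in c(query_id, reference_id))
    if (!id %in% a$ids) stop("id not in alignment: ", id)
  q <- strsplit(a$seqs[[query_id]], "")[[1]]
  r <- strsplit(a$seqs[[reference_id]], "")[[1]]
  qpos <- cumsum(q != "-")
  ins <- r == "-" & q != "-"
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  if (!any(ins)) return(out)
  rle_ <- rle(ins)
  ends <- cumsum(rle_$lengths)
  starts <- ends - rle_$lengths + 1
  for (k in which(rle_$values)) {
    out <- rbind(out, data.frame(start = qpos[starts[k]],
                                 end = qpos[ends[k]],
                                 length = ends[k] - starts[k] + 1L))
  }
  rownames(out) <- NULL
  out
}

scan_pattern <- function(sequence, pattern, motif, match_len) {
  hits <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1)
    return(data.frame(motif = character(0), position = integer(0),
                      match = character(0)))
  data.frame(motif = motif, position = as.integer(hits),
             match = vapply(as.integer(hits), function(p)
               substr(sequence, p, p + match_len - 1), character(1)),
             stringsAsFactors = FALSE)
}

#' Scan for glycosylation sequons
#'
#' N-linked sequon N-X-\[S/T\] with X != P (a necessary condition for
#' N-glycosylation; overlapping hits allowed), and the C-mannosylation
#' motif W-X-X-W reported at its first tryptophan.
#'
#' @param sequence ungapped amino-acid sequence
#' @return data.frame of class `motif_hits` (motif, position, match)
#' @export
scan_glyco_sequons <- function(sequence) {
  sequence <- toupper(gsub("-", "", sequence))
  out <- rbind(
    scan_pattern(sequence, "N(?=[^P][ST])", "N-linked", 3),
    scan_pattern(sequence, "W(?=..W)", "C-mannosylation", 4))
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Scan for canonical calcium-binding linker motifs
#'
#' Exact patterns DXNDN, DXD, DRE and DYE (X = any residue), with overlaps
#' allowed; a DXD hit starting inside a DXNDN hit is suppressed since the
#' longer motif subsumes it. The position-dependent XEX/XDX linker motifs
#' are not scannable without anchoring and are left to the caller.
#'
#' @param sequence ungapped amino-acid sequence
#' @return data.frame of class `motif_hits` (motif, position, match)
#' @export
scan_calcium_motifs <- function(sequence) {
  sequence <- toupper(gsub("-", "", sequence))
  dxndn <- scan_pattern(sequence, "D(?=.NDN)", "DXNDN", 5)
  dxd <- scan_pattern(sequence, "D(?=.D)", "DXD", 3)
  if (nrow(dxndn) > 0 && nrow(dxd) > 0) {
    inside <- vapply(dxd$position, function(p)
      any(p >= dxndn$position & p + 2 <= dxndn$position + 4), logical(1))
    dxd <- dxd[!inside, , drop = FALSE]
  }
  out <- rbind(dxndn, dxd,
               scan_pattern(sequence, "DRE", "DRE", 3),
               scan_pattern(sequence, "DYE", "DYE", 3))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Paint conservation bins into the B-factor column of a PDB copy
#'
#' Writes a PDB in which every atom's B-factor is its residue's
#' conservation bin (1-9; unmapped residues get 0), the usual trick for
#' coloring structures by conservation in molecular viewers.
#'
#' @param s a `Structure`
#' @param chain chain id
#' @param mapping output of [map_alignment_to_structure()]
#' @param path output PDB path
#' @return the path, invisibly
#' @export
paint_conservation <- function(s, chain, mapping, path) {
  out <- s
  b <- rep(0, nrow(out$atoms))
  sel <- out$atoms$chain_id == chain
  b[sel] <- mapping$bin[match(out$atoms$residue_number[sel],
                              mapping$residue_number)]
  b[is.na(b)] <- 0
  out$atoms$b_factor <- b
  write_structure(out, path, format = "pdb")
}
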