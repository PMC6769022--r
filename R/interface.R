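#' Default residue classes for interface composition
#'
#' Charged: Asp, Glu, Lys, Arg. Hydrophobic: Ala, Val, Leu, Ile, Met, Phe,
#' Trp, Pro, Gly, Cys. Hydrophilic: Ser, Thr, Asn, Gln, Tyr, His. The scheme
#' is a calibration starting point and fully configurable; any recalibration
#' should travel with the analysis configuration.
#'
#' @return named character vector, residue name -> class
#' @export
default_residue_classes <- function() {
  c(ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged",
    ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
    ILE = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
    TRP = "hydrophobic", PRO = "hydrophobic", GLY = "hydrophobic",
    CYS = "hydrophobic",
    SER = "hydrophilic", THR = "hydrophilic", ASN = "hydrophilic",
    GLN = "hydrophilic", TYR = "hydrophilic", HIS = "hydrophilic")
}

#' Parameters for interface analysis
#'
#' @param residue_fraction_threshold minimum buried fraction of the free-state
#'   accessible area for a residue to count as an interface residue
#'   (default 0.20)
#' @param biological_cutoff interface area (A^2) above which an interface is
#'   called plausibly biological rather than a crystal contact (default 856)
#' @param salt_bridge_cutoff maximum N-O distance (A) for a salt bridge
#'   (default 4.0)
#' @param residue_classes residue -> class map for composition
#' @return list of class `interface_params`
#' @export
interface_params <- function(residue_fraction_threshold = 0.20,
                             biological_cutoff = 856,
                             salt_bridge_cutoff = 4.0,
                             residue_classes = default_residue_classes()) {
  stopifnot(residue_fraction_threshold > 0, biological_cutoff > 0,
            salt_bridge_cutoff > 0)
  structure(list(residue_fraction_threshold = residue_fraction_threshold,
                 biological_cutoff = biological_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 residue_classes = residue_classes),
            class = "interface_params")
}

#' Per-residue buried surface between two protomers
#'
#' Runs three SASA evaluations (protomer A alone, protomer B alone, the
#' complex) and reports, for every polymer residue, its free-state accessible
#' area, its area in the complex, and the buried surface area
#' `bsa = asa_free - asa_complex` (clipped at zero; sampling can produce
#' tiny negative values). Each buried residue also records the repeat label
#' of the nearest heavy atom on the other protomer (`partner_repeat`; ties
#' broken toward the smaller residue number).
#'
#' @param complex a `Structure` containing both protomers
#' @param chains_a,chains_b disjoint chain-id sets defining the protomers
#' @param params a [sasa_params()] object
#' @param annotations optional `repeat_annotation`; without it all repeat
#'   labels are `"unassigned"`
#' @return data.frame of class `buried_surface` with columns `protomer`,
#'   `chain`, `residue_number`, `residue_name`, `repeat_label`, `asa_free`,
#'   `asa_complex`, `bsa`, `partner_repeat`
#' @export
buried_surface <- function(complex, chains_a, chains_b,
                           params = sasa_params(), annotations = NULL) {
  if (length(chains_a) == 0 || length(chains_b) == 0)
    stop("both protomer chain sets must be non-empty")
  if (length(intersect(chains_a, chains_b)) > 0)
    stop("protomer chain sets overlap: ",
         paste(intersect(chains_a, chains_b), collapse = ", "))
  sa <- select_atoms(complex, chains = chains_a)
  sb <- select_atoms(complex, chains = chains_b)
  both <- new_structure(rbind(sa$atoms, sb$atoms), cell = complex$cell,
                        sym_ops = complex$sym_ops)

  free_a <- compute_sasa(sa, params)
  free_b <- compute_sasa(sb, params)
  bound <- compute_sasa(both, params)

  res_free <- rbind(
    cbind(free_a$per_residue_area, protomer = "A"),
    cbind(free_b$per_residue_area, protomer = "B"))
  kf <- paste(res_free$chain, res_free$residue_number)
  kb <- paste(bound$per_residue_area$chain,
              bound$per_residue_area$residue_number)
  asa_complex <- bound$per_residue_area$area[match(kf, kb)]
  asa_complex[is.na(asa_complex)] <- 0

  out <- data.frame(
    protomer = res_free$protomer,
    chain = res_free$chain,
    residue_number = res_free$residue_number,
    residue_name = res_free$residue_name,
    repeat_label = repeat_of(res_free$chain, res_free$residue_number,
                             annotations),
    asa_free = res_free$area,
    asa_complex = asa_complex,
    bsa = pmax(res_free$area - asa_complex, 0),
    stringsAsFactors = FALSE, row.names = NULL)

  # nearest-partner-atom repeat attribution for buried residues
  out$partner_repeat <- NA_character_
  Xa <- coords(sa); Xb <- coords(sb)
  part_a <- data.frame(chain = sb$atoms$chain_id,
                       resno = sb$atoms$residue_number)
  part_b <- data.frame(chain = sa$atoms$chain_id,
                       resno = sa$atoms$residue_number)
  lab_a <- repeat_of(part_a$chain, part_a$resno, annotations)
  lab_b <- repeat_of(part_b$chain, part_b$resno, annotations)
  buried_idx <- which(out$bsa > 0)
  for (i in buried_idx) {
    own <- if (out$protomer[i] == "A") sa else sb
    sel <- own$atoms$chain_id == out$chain[i] &
      own$atoms$residue_number == out$residue_number[i]
    Xi <- coords(own)[sel, , drop = FALSE]
    Xo <- if (out$protomer[i] == "A") Xb else Xa
    labs <- if (out$protomer[i] == "A") lab_a else lab_b
    resnos <- if (out$protomer[i] == "A") part_a$resno else part_b$resno
    # min distance from any atom of this residue to each partner atom
    d2 <- apply(Xi, 1, function(p) colSums((t(Xo) - p)^2))
    dmin <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    ord <- order(dmin, resnos)
    out$partner_repeat[i] <- labs[ord[1]]
  }
  class(out) <- c("buried_surface", "data.frame")
  out
}

#' Total interface area (PISA convention)
#'
#' Half the total solvent-accessible area lost by both protomers on
#' complexation; for a symmetric dimer this equals the area one protomer
#' buries.
#'
#' @param b a `buried_surface`
#' @return area in A^2
#' @export
interface_area <- function(b) sum(b$bsa) / 2

#' Interface residues by buried fraction
#'
#' A residue is at the interface when its buried surface area is at least
#' `threshold` of its free-state accessible surface area. Residues with zero
#' accessible area never qualify.
#'
#' @param b a `buried_surface`
#' @param threshold fraction in (0, 1], default 0.20
#' @return the qualifying rows with an extra `buried_fraction` column
#' @export
interface_residues <- function(b, threshold = 0.20) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- ifelse(b$asa_free > 0, b$bsa / b$asa_free, 0)
  out <- b[b$asa_free > 0 & frac >= threshold, , drop = FALSE]
  out$buried_fraction <- frac[b$asa_free > 0 & frac >= threshold]
  rownames(out) <- NULL
  out
}

# directed pair key seen from protomer A: A-side residue in repeat i buried
# against repeat j contributes to "i:j"; B-side residue in repeat j buried
# against repeat i contributes to the same key.
pair_key <- function(b) {
  ifelse(b$protomer == "A",
         paste(b$repeat_label, b$partner_repeat, sep = ":"),
         paste(b$partner_repeat, b$repeat_label, sep = ":"))
}

#' Interface area decomposed by repeat pair
#'
#' Splits the interface area across ordered repeat pairs `ECi:ECj`
#' (protomer A's repeat first). Attribution is by nearest-partner-atom
#' repeat label, so the pair areas plus any `other` burial (a partner
#' residue outside all annotated repeats) reproduce the total exactly.
#'
#' @param b a `buried_surface` computed with repeat annotations
#' @return data.frame (pair, area) with attribute `total`
#' @export
repeat_pair_areas <- function(b) {
  buried <- b[b$bsa > 0, , drop = FALSE]
  key <- pair_key(buried)
  key[grepl("unassigned", key)] <- "other"
  area <- tapply(buried$bsa / 2, key, sum)
  out <- data.frame(pair = names(area), area = as.numeric(area),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- interface_area(b)
  out
}

#' Interface composition by residue class
#'
#' Fraction of buried area contributed by hydrophobic, charged, and
#' hydrophilic residues, overall and (optionally) per repeat pair.
#'
#' @param b a `buried_surface`
#' @param class_map residue -> class map, default [default_residue_classes()]
#' @param per_pair also return per-repeat-pair fractions
#' @return list with `overall` (named fractions summing to 1) and, when
#'   requested, `per_pair` (data.frame pair x class)
#' @export
composition <- function(b, class_map = default_residue_classes(),
                        per_pair = FALSE) {
  buried <- b[b$bsa > 0, , drop = FALSE]
  if (nrow(buried) == 0) stop("no buried area; composition undefined")
  cls <- unname(class_map[buried$residue_name])
  if (any(is.na(cls)))
    stop("residue name(s) missing from class map: ",
         paste(sort(unique(buried$residue_name[is.na(cls)])), collapse = ", "))
  lev <- c("hydrophobic", "charged", "hydrophilic")
  frac_of <- function(w, cl) {
    tot <- sum(w)
    vapply(lev, function(l) sum(w[cl == l]) / tot, numeric(1))
  }
  out <- list(overall = frac_of(buried$bsa, cls))
  if (per_pair) {
    key <- pair_key(buried)
    key[grepl("unassigned", key)] <- "other"
    pp <- t(vapply(split(seq_len(nrow(buried)), key),
                   function(idx) frac_of(buried$bsa[idx], cls[idx]),
                   numeric(3)))
    out$per_pair <- data.frame(pair = rownames(pp), pp,
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

# side-chain atoms carrying formal charge at neutral pH
SB_DONORS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
SB_DONORS_HIS <- list(HIS = c("ND1", "NE2"))
SB_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

sb_atoms <- function(s, table) {
  a <- s$atoms
  keep <- rep(FALSE, nrow(a))
  for (res in names(table))
    keep <- keep | (a$residue_name == res & a$atom_name %in% table[[res]])
  a[keep, , drop = FALSE]
}

#' Inter-protomer salt bridges
#'
#' Reports basic-side-chain nitrogen / acidic-side-chain oxygen pairs across
#' the two protomers within the cutoff: Lys NZ and Arg NE/NH1/NH2 (His
#' ND1/NE2 optionally, off by default as its charge is pH dependent) versus
#' Asp OD1/OD2 and Glu OE1/OE2. One record per residue pair with the minimal
#' atom distance.
#'
#' @param complex a `Structure`
#' @param chains_a,chains_b protomer chain sets
#' @param cutoff maximum distance in angstrom (default 4.0)
#' @param include_his treat histidine as a donor
#' @return data.frame (res_a, res_b, atom_a, atom_b, distance), one row per
#'   bridged residue pair
#' @export
detect_salt_bridges <- function(complex, chains_a, chains_b, cutoff = 4.0,
                                include_his = FALSE) {
  stopifnot(cutoff > 0)
  donors <- if (include_his) c(SB_DONORS, SB_DONORS_HIS) else SB_DONORS
  sa <- select_atoms(complex, chains = chains_a)
  sb_ <- select_atoms(complex, chains = chains_b)
  empty <- data.frame(res_a = character(0), res_b = character(0),
                      atom_a = character(0), atom_b = character(0),
                      distance = numeric(0))
  pairs_for <- function(don, acc) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
    D <- sqrt(outer(rowSums(don[, c("x", "y", "z")]^2),
                    rowSums(acc[, c("x", "y", "z")]^2), "+") -
                2 * as.matrix(don[, c("x", "y", "z")]) %*%
                t(as.matrix(acc[, c("x", "y", "z")])))
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    data.frame(
      res_a = paste0(don$residue_name[hit[, 1]], don$residue_number[hit[, 1]],
                     ":", don$chain_id[hit[, 1]]),
      res_b = paste0(acc$residue_name[hit[, 2]], acc$residue_number[hit[, 2]],
                     ":", acc$chain_id[hit[, 2]]),
      atom_a = don$atom_name[hit[, 1]], atom_b = acc$atom_name[hit[, 2]],
      distance = D[hit], stringsAsFactors = FALSE)
  }
  res <- rbind(pairs_for(sb_atoms(sa, donors), sb_atoms(sb_, SB_ACCEPTORS)),
               pairs_for(sb_atoms(sa, SB_ACCEPTORS), sb_atoms(sb_, donors)))
  if (nrow(res) == 0) return(empty)
  # minimal distance per residue pair
  key <- paste(res$res_a, res$res_b)
  keep <- unlist(lapply(split(seq_len(nrow(res)), key),
                        function(idx) idx[which.min(res$distance[idx])]),
                 use.names = FALSE)
  out <- res[sort(keep), , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an interface as biological-scale or crystal-contact-scale
#'
#' Interfaces larger than the empirical cutoff (856 A^2 by default) are
#' unlikely to be crystal-packing artifacts. The inequality is strict: an
#' area exactly at the cutoff is called crystal-contact-scale.
#'
#' @param area interface area in A^2
#' @param cutoff cutoff in A^2 (default 856)
#' @return `"plausible-biological"` or `"crystal-contact-scale"`
#' @export
classify_interface <- function(area, cutoff = 856) {
  stopifnot(area >= 0)
  if (area > cutoff) "plausible-biological" else "crystal-contact-scale"
}
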