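#' @importFrom stats setNames sd dist rnorm
#' @importFrom utils read.csv write.csv
NULL

# canonical column order of the atom table
ATOM_COLS <- c("serial", "atom_name", "element", "residue_name", "chain_id",
               "residue_number", "insertion_code", "x", "y", "z",
               "occupancy", "b_factor", "is_hetero")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a Structure from an atom table
#'
#' A `Structure` is the package's coordinate container: an ordered heavy-atom
#' table (author residue numbering) plus optional unit cell and fractional
#' symmetry operators. Atoms are kept in file order, grouped by chain and
#' residue.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `chain_id`, `residue_number`, `insertion_code`,
#'   `x`, `y`, `z`, `occupancy`, `b_factor`, `is_hetero`.
#' @param cell optional numeric length-6 vector `(a, b, c, alpha, beta, gamma)`
#'   in angstroms and degrees.
#' @param sym_ops optional list of symmetry operators, each a list with a
#'   3x3 rotation `R` and translation `t` in fractional coordinates.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, cell = NULL, sym_ops = NULL) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("atoms with empty element symbol")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || any(!is.finite(cell)) || any(cell[1:3] <= 0))
      stop("cell must be 6 positive finite numbers (a, b, c, alpha, beta, gamma)")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, sym_ops = sym_ops),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain_id)
  cat("Structure:", nrow(a), "atoms,", length(ch), "chain(s) [",
      paste(ch, collapse = " "), "]\n")
  if (!is.null(x$cell))
    cat("  cell:", paste(sprintf("%.2f", x$cell), collapse = " "),
        "|", length(x$sym_ops), "symmetry op(s)\n")
  invisible(x)
}

#' Number of atoms in a Structure
#' @param s a `Structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as a matrix
#' @param s a `Structure`
#' @return numeric n x 3 matrix of Cartesian coordinates (angstrom)
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

three_to_one <- function(res) {
  out <- suppressWarnings(bio3d::aa321(res))
  out[is.na(out)] <- "X"
  out
}

# unique residue key (chain, number, insertion code)
residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code, sep = "|")
}

#' Per-chain one-letter sequences of polymer residues
#' @param s a `Structure`
#' @return named character vector, one sequence per chain
#' @export
chain_sequences <- function(s) {
  a <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  if (nrow(a) == 0) return(character(0))
  first <- a[!duplicated(residue_key(a)), , drop = FALSE]
  vapply(split(first, factor(first$chain_id, levels = unique(first$chain_id))),
         function(d) paste(three_to_one(d$residue_name), collapse = ""),
         character(1))
}

## ---- symmetry-operator string parsing ("x", "-y+1/2", "z-1/3") -------------

parse_symop_xyz <- function(txt) {
  parts <- strsplit(tolower(gsub("[[:space:]]", "", txt)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", txt)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        num <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sgn * num[1] / num[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t[i] <- t[i] + sgn * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator term '", term, "' in ", txt)
      }
    }
  }
  list(R = R, t = t)
}

# orthogonalization matrix (fractional -> Cartesian), PDB convention:
# a along x, b in the xy plane
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

## ---- readers ---------------------------------------------------------------

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Reads heavy atoms of the first model. Hydrogens are dropped; alternate
#' locations are resolved to the highest-occupancy conformer (ties to the
#' first). Waters are flagged hetero. Unit cell and symmetry operators are
#' populated when present (CRYST1/REMARK 290 for PDB; `_cell` and
#' `_space_group_symop`/`_symmetry_equiv` categories for mmCIF).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`
#' @return a [new_structure()] `Structure`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif",
                     pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  raw <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms parsed from ", path)

  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  element <- toupper(trimws(element))
  # fall back to the leading letter(s) of the atom name
  guess <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", at$elety))
  bad <- is.na(element) | !nzchar(element) | element %in% c("ATOM", "HETATM")
  element[bad] <- guess[bad]

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = at$elety,
    element = element,
    residue_name = toupper(at$resid),
    chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    residue_number = as.integer(at$resno),
    insertion_code = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, pmin(pmax(at$o, 0), 1)),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    is_hetero = at$type == "HETATM" | toupper(at$resid) %in% WATER_NAMES,
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)

  # drop hydrogens/deuterium
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  # resolve alternate locations: highest occupancy wins, ties to first
  if (any(nzchar(atoms$alt))) {
    key <- paste(residue_key(atoms), atoms$atom_name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      idx[which.max(atoms$occupancy[idx])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$alt <- NULL

  txt <- readLines(path, warn = FALSE)
  cs <- if (format == "pdb") parse_pdb_cell_sym(txt) else parse_cif_cell_sym(txt)
  new_structure(atoms, cell = cs$cell, sym_ops = cs$sym_ops)
}

parse_pdb_cell_sym <- function(txt) {
  cell <- NULL; ops <- NULL
  cr <- grep("^CRYST1", txt, value = TRUE)
  if (length(cr) >= 1) {
    f <- suppressWarnings(as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
      substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
    if (all(is.finite(f)) && all(f[1:3] > 0)) cell <- f
  }
  sm <- grep("^REMARK 290 +SMTRY[123]", txt, value = TRUE)
  if (length(sm) >= 3 && length(sm) %% 3 == 0) {
    ops <- lapply(seq(1, length(sm), by = 3), function(i) {
      rows <- t(vapply(sm[i:(i + 2)], function(l) {
        suppressWarnings(as.numeric(strsplit(trimws(substr(l, 20, nchar(l))),
                                             "[[:space:]]+")[[1]][1:4]))
      }, numeric(4)))
      # SMTRY rows are Cartesian; convert translation to fractional later if
      # a cell exists. Store Cartesian-rotation ops tagged accordingly.
      list(R = rows[, 1:3, drop = FALSE], t = rows[, 4], cartesian = TRUE)
    })
  }
  list(cell = cell, sym_ops = ops)
}

parse_cif_cell_sym <- function(txt) {
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "[[:space:]]"), txt, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][2]))
  }
  cell <- c(grab("_cell.length_a"), grab("_cell.length_b"),
            grab("_cell.length_c"), grab("_cell.angle_alpha"),
            grab("_cell.angle_beta"), grab("_cell.angle_gamma"))
  if (any(!is.finite(cell))) cell <- NULL

  ops <- NULL
  tag_line <- grep("_space_group_symop.operation_xyz|_symmetry_equiv_pos_as_xyz",
                   txt)
  if (length(tag_line) > 0) {
    # collect the data rows of the enclosing loop (or a single inline value)
    i <- tag_line[1]
    inline <- sub("^[^[:space:]]+[[:space:]]+", "",
                  trimws(txt[i]))
    if (nzchar(inline) && inline != trimws(txt[i])) {
      ops <- list(parse_symop_xyz(gsub("['\"]", "", inline)))
    } else {
      j <- i + 1
      # skip remaining loop tags
      while (j <= length(txt) && grepl("^_", trimws(txt[j]))) j <- j + 1
      rows <- character(0)
      while (j <= length(txt)) {
        l <- trimws(txt[j])
        if (!nzchar(l) || grepl("^(loop_|_|#|data_)", l)) break
        rows <- c(rows, l)
        j <- j + 1
      }
      xyz <- vapply(rows, function(r) {
        m <- regmatches(r, regexpr("'[^']+'|\"[^\"]+\"|[-0-9a-zA-Z/,+]+,[^ ]+", r))
        gsub("['\"]", "", m[1])
      }, character(1))
      ops <- lapply(unname(xyz), parse_symop_xyz)
    }
  }
  list(cell = cell, sym_ops = ops)
}

## ---- writers ---------------------------------------------------------------

#' Write a Structure to PDB or mmCIF
#'
#' Emits heavy-atom records in table order; cell and symmetry operators are
#' written when present (CRYST1 + REMARK 290 for PDB, `_cell` and
#' `_space_group_symop` for mmCIF).
#'
#' @param s a `Structure`
#' @param path output file path
#' @param format `"auto"`, `"pdb"` or `"mmcif"`
#' @return the path, invisibly
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif", pdb = "pdb",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  a <- s$atoms
  lines <- character(0)
  if (format == "pdb") {
    if (!is.null(s$cell)) {
      lines <- c(lines, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        s$cell[1], s$cell[2], s$cell[3], s$cell[4], s$cell[5], s$cell[6]))
      if (!is.null(s$sym_ops)) {
        O <- orth_matrix(s$cell)
        for (k in seq_along(s$sym_ops)) {
          op <- symop_cartesian(s$sym_ops[[k]], O)
          for (r in 1:3) {
            lines <- c(lines, sprintf(
              "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f %14.5f",
              r, k, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]))
          }
        }
      }
    }
    rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
    # pad atom names per PDB convention (1-char elements start in column 14)
    nm <- ifelse(nchar(a$atom_name) < 4 & nchar(a$element) == 1,
                 sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
    lines <- c(lines, sprintf(
      "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000, nm, a$residue_name, substr(a$chain_id, 1, 1),
      a$residue_number, ifelse(nzchar(a$insertion_code), a$insertion_code, " "),
      a$x, a$y, a$z, a$occupancy, a$b_factor, a$element), "END")
  } else {
    lines <- c("data_cadint", "#")
    if (!is.null(s$cell)) {
      lines <- c(lines,
                 sprintf("_cell.length_a %.4f", s$cell[1]),
                 sprintf("_cell.length_b %.4f", s$cell[2]),
                 sprintf("_cell.length_c %.4f", s$cell[3]),
                 sprintf("_cell.angle_alpha %.3f", s$cell[4]),
                 sprintf("_cell.angle_beta %.3f", s$cell[5]),
                 sprintf("_cell.angle_gamma %.3f", s$cell[6]), "#")
      if (!is.null(s$sym_ops)) {
        lines <- c(lines, "loop_", "_space_group_symop.id",
                   "_space_group_symop.operation_xyz")
        for (k in seq_along(s$sym_ops)) {
          lines <- c(lines, sprintf("%d '%s'", k,
                                    symop_to_xyz(s$sym_ops[[k]], s$cell)))
        }
        lines <- c(lines, "#")
      }
    }
    lines <- c(lines, "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                        "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                        "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
               sprintf("%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                       ifelse(a$is_hetero, "HETATM", "ATOM"), a$serial,
                       a$element, a$atom_name, a$residue_name, a$chain_id,
                       a$residue_number,
                       ifelse(nzchar(a$insertion_code), a$insertion_code, "?"),
                       a$x, a$y, a$z, a$occupancy, a$b_factor,
                       a$residue_number, a$residue_name, a$chain_id,
                       a$atom_name), "#")
  }
  writeLines(lines, path)
  invisible(path)
}

# represent a fractional symop back as an x,y,z string (rational translations)
symop_to_xyz <- function(op, cell) {
  if (isTRUE(op$cartesian)) {
    O <- orth_matrix(cell)
    op <- list(R = solve(O) %*% op$R %*% O, t = as.numeric(solve(O) %*% op$t))
  }
  axes <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    parts <- character(0)
    for (j in 1:3) {
      v <- op$R[i, j]
      if (abs(v) > 1e-9) {
        parts <- c(parts, paste0(if (v < 0) "-" else if (length(parts)) "+"
                                 else "", axes[j]))
      }
    }
    tv <- op$t[i]
    if (abs(tv) > 1e-9) {
      fr <- best_fraction(tv)
      parts <- c(parts, paste0(if (tv < 0) "-" else "+", fr))
    }
    paste(parts, collapse = "")
  }, character(1))
  paste(comps, collapse = ",")
}

best_fraction <- function(v) {
  av <- abs(v)
  for (den in c(2, 3, 4, 6, 12)) {
    num <- round(av * den)
    if (abs(av - num / den) < 1e-6) return(paste0(num, "/", den))
  }
  sprintf("%.6f", av)
}

# convert a fractional-coordinate op to Cartesian (R_c = O R O^-1)
symop_cartesian <- function(op, O) {
  if (isTRUE(op$cartesian)) return(op)
  list(R = O %*% op$R %*% solve(O), t = as.numeric(O %*% op$t),
       cartesian = TRUE)
}

## ---- selection -------------------------------------------------------------

#' Select a subset of atoms
#'
#' Filters by chain, residue-number range, atom name, and hetero policy;
#' atom order is preserved. An empty result is an error: silent empty
#' selections propagate as zero areas downstream.
#'
#' @param s a `Structure`
#' @param chains character vector of chain ids, or NULL for all
#' @param residues integer vector of residue numbers (e.g. `3:10`), or NULL
#' @param atom_names character vector (e.g. `"CA"`), or NULL
#' @param hetero `"exclude"` (default), `"include"`, or `"only"`
#' @return a `Structure` with the matching atoms
#' @export
select_atoms <- function(s, chains = NULL, residues = NULL, atom_names = NULL,
                         hetero = c("exclude", "include", "only")) {
  hetero <- match.arg(hetero)
  a <- s$atoms
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(a$chain_id))
    if (length(missing_ch) > 0)
      stop("chain(s) not present in structure: ",
           paste(missing_ch, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain_id %in% chains
  if (!is.null(residues)) keep <- keep & a$residue_number %in% residues
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  keep <- keep & switch(hetero,
                        exclude = !a$is_hetero,
                        include = TRUE,
                        only = a$is_hetero)
  if (!any(keep)) stop("selection matched no atoms")
  new_structure(a[keep, , drop = FALSE], cell = s$cell, sym_ops = s$sym_ops)
}

## ---- repeat annotation -----------------------------------------------------

#' Validate a repeat-annotation table
#'
#' EC repeats are declared as inclusive author-numbering residue ranges per
#' chain (e.g. EC1 = 3-102). Ranges on one chain must not overlap.
#'
#' @param s a `Structure`
#' @param table data.frame with columns `label`, `chain`, `start`, `end`
#' @return the validated table, class `repeat_annotation`
#' @export
assign_repeats <- function(s, table) {
  stopifnot(is.data.frame(table))
  need <- c("label", "chain", "start", "end")
  if (!all(need %in% names(table)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  table$start <- as.integer(table$start)
  table$end <- as.integer(table$end)
  if (any(table$start > table$end)) stop("annotation with start > end")
  missing_ch <- setdiff(unique(table$chain), unique(s$atoms$chain_id))
  if (length(missing_ch) > 0)
    stop("annotation references absent chain(s): ",
         paste(missing_ch, collapse = ", "))
  for (ch in unique(table$chain)) {
    d <- table[table$chain == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping repeat ranges on chain ", ch)
  }
  class(table) <- c("repeat_annotation", "data.frame")
  table
}

#' Read a repeat-annotation CSV (columns label, chain, start, end)
#' @param s a `Structure` the annotations apply to
#' @param path CSV path
#' @return validated `repeat_annotation`
#' @export
read_repeat_annotation <- function(s, path) {
  assign_repeats(s, read.csv(path, stringsAsFactors = FALSE))
}

# label each residue (vectorized over chain/residue_number);
# residues outside all ranges -> "unassigned"
repeat_of <- function(chain_id, residue_number, annotations) {
  out <- rep("unassigned", length(chain_id))
  if (is.null(annotations)) return(out)
  for (k in seq_len(nrow(annotations))) {
    hit <- chain_id == annotations$chain[k] &
      residue_number >= annotations$start[k] &
      residue_number <= annotations$end[k]
    out[hit] <- annotations$label[k]
  }
  out
}

#' Repeat label of each polymer residue
#' @param s a `Structure`
#' @param annotations a `repeat_annotation` from [assign_repeats()]
#' @return data.frame (chain, residue_number, residue_name, repeat_label)
#' @export
residue_repeats <- function(s, annotations) {
  a <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  first <- a[!duplicated(residue_key(a)), , drop = FALSE]
  data.frame(chain = first$chain_id,
             residue_number = first$residue_number,
             residue_name = first$residue_name,
             repeat_label = repeat_of(first$chain_id, first$residue_number,
                                      annotations),
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- symmetry expansion ----------------------------------------------------

#' Apply a crystallographic symmetry operator
#'
#' Transforms a copy of the structure by the `op_index`-th symmetry operator
#' plus an integer lattice shift: Cartesian positions are fractionalized,
#' rotated, translated, and orthogonalized back. Chain ids are suffixed to
#' stay unique when the copy is combined with the original.
#'
#' @param s a `Structure` with `cell` and `sym_ops`
#' @param op_index 1-based operator index
#' @param lattice_shift integer 3-vector of unit-cell translations
#' @param chain_suffix appended to every chain id (default `"_s<op_index>"`)
#' @return the transformed `Structure`
#' @export
apply_symmetry <- function(s, op_index, lattice_shift = c(0, 0, 0),
                           chain_suffix = NULL) {
  if (is.null(s$cell) || is.null(s$sym_ops) || length(s$sym_ops) == 0)
    stop("structure has no cell/symmetry information; supply a pre-assembled ",
         "two-chain file instead")
  if (op_index < 1 || op_index > length(s$sym_ops))
    stop("op_index out of range (have ", length(s$sym_ops), " operators)")
  op <- s$sym_ops[[op_index]]
  O <- orth_matrix(s$cell)
  X <- coords(s)
  if (isTRUE(op$cartesian)) {
    Xn <- t(op$R %*% t(X) + op$t)
    Xn <- sweep(Xn, 2, as.numeric(O %*% as.numeric(lattice_shift)), "+")
  } else {
    Fr <- t(solve(O) %*% t(X))
    Fr <- t(op$R %*% t(Fr) + (op$t + as.numeric(lattice_shift)))
    Xn <- t(O %*% t(Fr))
  }
  out <- s
  out$atoms$x <- Xn[, 1]; out$atoms$y <- Xn[, 2]; out$atoms$z <- Xn[, 3]
  if (is.null(chain_suffix)) chain_suffix <- paste0("_s", op_index)
  out$atoms$chain_id <- paste0(out$atoms$chain_id, chain_suffix)
  out
}

#' Combine two structures into one (e.g. protomer + symmetry mate)
#' @param a,b `Structure` objects with disjoint chain ids
#' @return combined `Structure` (cell/symmetry of `a` kept)
#' @export
combine_structures <- function(a, b) {
  if (length(intersect(unique(a$atoms$chain_id), unique(b$atoms$chain_id))) > 0)
    stop("chain ids overlap; suffix one of the structures first")
  new_structure(rbind(a$atoms, b$atoms), cell = a$cell, sym_ops = a$sym_ops)
}

## ---- span arithmetic -------------------------------------------------------

#' Count modeled polymer residues in an inclusive author-numbering span
#'
#' The residue-span arithmetic behind loop and insertion lengths (for
#' instance a disulfide loop spanning residues 66-75 counts 10 residues).
#' Insertion codes count as distinct residues.
#'
#' @param s a `Structure`
#' @param chain_id chain id
#' @param start_residue,end_residue inclusive span (author numbering)
#' @return integer count of distinct modeled residues in the span
#' @export
span_residue_count <- function(s, chain_id, start_residue, end_residue) {
  stopifnot(start_residue <= end_residue)
  a <- s$atoms[!s$atoms$is_hetero & s$atoms$chain_id == chain_id, ,
               drop = FALSE]
  if (nrow(a) == 0) stop("chain not present: ", chain_id)
  inside <- a$residue_number >= start_residue & a$residue_number <= end_residue
  length(unique(residue_key(a[inside, , drop = FALSE])))
}
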