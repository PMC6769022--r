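#' Build a validated analysis configuration
#'
#' Collects everything one end-to-end interface analysis needs: the complex
#' (one file containing both protomers, or one protomer plus a symmetry
#' operator to generate its mate), the protomer chain sets, the repeat
#' annotation table, parameter blocks, and optionally an alignment for
#' conservation mapping and repeats for an azimuthal profile.
#'
#' @param structure path to a PDB/mmCIF file
#' @param chains_a,chains_b protomer chain sets; when `symmetry_op` is given,
#'   `chains_b` defaults to the generated mate chains
#' @param annotations path to a repeat-annotation CSV or a data.frame
#' @param symmetry_op optional operator index; the partner protomer is then
#'   the symmetry mate of `chains_a` under that operator
#' @param lattice_shift integer 3-vector used with `symmetry_op`
#' @param sasa a [sasa_params()] block
#' @param interface an [interface_params()] block
#' @param azimuth logical: compute the azimuthal profile of protomer A
#' @param alignment optional path to an MSA; requires `alignment_reference`
#' @param alignment_reference id of the alignment row matching protomer A
#' @param out_dir output directory
#' @param seed integer recorded in the manifest
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(structure, chains_a, chains_b = NULL,
                            annotations = NULL, symmetry_op = NULL,
                            lattice_shift = c(0, 0, 0),
                            sasa = sasa_params(),
                            interface = interface_params(),
                            azimuth = FALSE,
                            alignment = NULL, alignment_reference = NULL,
                            out_dir, seed = 1L) {
  if (!file.exists(structure)) stop("structure file not found: ", structure)
  if (is.null(chains_b) && is.null(symmetry_op))
    stop("either chains_b or symmetry_op must be given")
  if (!is.null(alignment) && is.null(alignment_reference))
    stop("alignment requires alignment_reference")
  structure(list(structure = structure, chains_a = chains_a,
                 chains_b = chains_b, annotations = annotations,
                 symmetry_op = symmetry_op, lattice_shift = lattice_shift,
                 sasa = sasa, interface = interface, azimuth = azimuth,
                 alignment = alignment,
                 alignment_reference = alignment_reference,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the end-to-end interface report
#'
#' Deterministic given the configuration. Stages: read and annotate the
#' structure, assemble the dimer (symmetry mate if requested), buried
#' surface, total and per-repeat-pair areas, interface residues,
#' composition, salt bridges, biological-versus-crystal classification,
#' optional azimuthal profile and conservation painting. Writes
#' `report.json`, `per_residue.csv`, `pair_areas.csv`, a log with every
#' parameter echoed, and `conservation.pdb` when an alignment is supplied.
#' Any stage failure aborts with the stage name after removing partial
#' outputs.
#'
#' @param config an [analysis_config()]
#' @return the report list, invisibly; files under `config$out_dir`
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- "setup"
  outputs <- character(0)
  on_fail <- function(e) {
    unlink(outputs)
    stop("report stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "read_structure"
    s <- read_structure(config$structure)
    note("read_structure: ", config$structure, " (", n_atoms(s), " atoms)")

    stage <- "annotate"
    ann <- NULL
    if (!is.null(config$annotations)) {
      ann <- if (is.character(config$annotations))
        read_repeat_annotation(s, config$annotations)
      else assign_repeats(s, config$annotations)
      note("annotate: ", nrow(ann), " repeat range(s)")
    } else note("annotate: no repeat table supplied; labels unassigned")

    stage <- "assemble_dimer"
    if (!is.null(config$symmetry_op)) {
      mate <- apply_symmetry(select_atoms(s, chains = config$chains_a,
                                          hetero = "include"),
                             config$symmetry_op, config$lattice_shift)
      chains_b <- unique(mate$atoms$chain_id)
      s <- combine_structures(s, mate)
      if (!is.null(ann)) {
        ann_b <- ann[ann$chain %in% config$chains_a, , drop = FALSE]
        ann_b$chain <- paste0(ann_b$chain, "_s", config$symmetry_op)
        ann <- assign_repeats(s, rbind(as.data.frame(ann),
                                       as.data.frame(ann_b)))
      }
      note("assemble_dimer: symmetry op ", config$symmetry_op, ", shift (",
           paste(config$lattice_shift, collapse = " "), ") -> chains ",
           paste(chains_b, collapse = " "))
    } else {
      chains_b <- config$chains_b
      note("assemble_dimer: protomer B from chains ",
           paste(chains_b, collapse = " "))
    }

    stage <- "buried_surface"
    note("sasa params: probe ", config$sasa$probe_radius, " A, ",
         config$sasa$n_points, " points")
    b <- buried_surface(s, config$chains_a, chains_b, config$sasa, ann)

    stage <- "interface_metrics"
    p <- config$interface
    note("interface params: residue threshold ",
         p$residue_fraction_threshold, ", biological cutoff ",
         p$biological_cutoff, " A^2, salt-bridge cutoff ",
         p$salt_bridge_cutoff, " A")
    total <- interface_area(b)
    pairs <- repeat_pair_areas(b)
    ires <- interface_residues(b, p$residue_fraction_threshold)
    comp <- composition(b, p$residue_classes, per_pair = TRUE)
    sb <- detect_salt_bridges(s, config$chains_a, chains_b,
                              p$salt_bridge_cutoff)
    cls <- classify_interface(total, p$biological_cutoff)
    note("interface: total ", sprintf("%.2f", total), " A^2 -> ", cls)

    stage <- "azimuth"
    azi <- NULL
    if (isTRUE(config$azimuth)) {
      ann_a <- ann[ann$chain %in% config$chains_a, , drop = FALSE]
      azi <- azimuthal_profile(s, ann_a)
      note("azimuth: ", attr(azi, "frame"))
    }

    stage <- "conservation"
    cons_path <- NULL
    if (!is.null(config$alignment)) {
      aln <- read_alignment(config$alignment)
      mapping <- map_alignment_to_structure(aln, config$alignment_reference,
                                            s, config$chains_a[1])
      cons_path <- file.path(config$out_dir, "conservation.pdb")
      outputs <- c(outputs, cons_path)
      paint_conservation(s, config$chains_a[1], mapping, cons_path)
      note("conservation: painted ", nrow(mapping), " residue(s)")
    }

    stage <- "write_outputs"
    report <- list(
      structure = config$structure,
      chains_a = config$chains_a, chains_b = chains_b,
      parameters = list(
        probe_radius = config$sasa$probe_radius,
        n_points = config$sasa$n_points,
        residue_fraction_threshold = p$residue_fraction_threshold,
        biological_cutoff = p$biological_cutoff,
        salt_bridge_cutoff = p$salt_bridge_cutoff),
      total_area = total,
      classification = cls,
      pair_areas = pairs,
      interface_residues = ires[, c("protomer", "chain", "residue_number",
                                    "residue_name", "repeat_label",
                                    "buried_fraction")],
      composition = list(overall = as.list(comp$overall),
                         per_pair = comp$per_pair),
      salt_bridges = sb,
      azimuthal_profile = azi,
      seed = config$seed)
    json_path <- file.path(config$out_dir, "report.json")
    outputs <- c(outputs, json_path)
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE, dataframe = "rows")
    pr_path <- file.path(config$out_dir, "per_residue.csv")
    outputs <- c(outputs, pr_path)
    write.csv(as.data.frame(b), pr_path, row.names = FALSE)
    pa_path <- file.path(config$out_dir, "pair_areas.csv")
    outputs <- c(outputs, pa_path)
    write.csv(pairs, pa_path, row.names = FALSE)
    note("write_outputs: report.json, per_residue.csv, pair_areas.csv")
    writeLines(log_lines, file.path(config$out_dir, "log.txt"))
    invisible(report)
  }, error = on_fail)
}
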