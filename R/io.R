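#' Read an atomic structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d (`read.pdb`/`read.cif`). Coordinates are
#' Angstrom; author chain ids and residue numbers are preserved (including
#' negative dyad-relative numbers and insertion codes). When alternate
#' locations are present, the highest-occupancy conformer is kept, ties
#' broken by altloc identifier order, so downstream geometry is
#' single-conformer and deterministic. Hydrogens are retained if present but
#' never required.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param model model number to extract from multi-model files (default 1).
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path))
    gd_abort("gyredyn_io_error", sprintf("cannot read '%s': no such file", path))
  pdb <- tryCatch(
    switch(format,
      pdb   = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
      mmcif = suppressWarnings(bio3d::read.cif(path, verbose = FALSE))),
    error = function(e) gd_abort("gyredyn_io_error",
      sprintf("failed to parse '%s' as %s: %s", path, format, conditionMessage(e))))
  at <- pdb$atom
  if (format == "mmcif") {
    # mmCIF values may carry CIF quoting (e.g. "C1'"); strip matched quotes
    for (col in c("elety", "resid", "chain", "elesy"))
      if (!is.null(at[[col]]))
        at[[col]] <- sub("^\"(.*)\"$", "\\1", sub("^'(.*)'$", "\\1", at[[col]]))
  }
  if (is.null(at) || nrow(at) == 0L)
    gd_abort("gyredyn_empty_structure", sprintf("'%s' contains zero atoms", path))
  if (model > 1L) {
    if (is.null(pdb$xyz) || nrow(as.matrix(pdb$xyz)) < model)
      gd_abort("gyredyn_io_error", sprintf("model %d absent in '%s'", model, path))
    m <- matrix(as.matrix(pdb$xyz)[model, ], ncol = 3L, byrow = TRUE)
    at$x <- m[, 1L]; at$y <- m[, 2L]; at$z <- m[, 3L]
  }
  at <- resolve_altloc(at)
  new_structure(at, model_id = model, source_label = basename(path))
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  gd_abort("gyredyn_format_error",
           sprintf("cannot infer format from extension '.%s'", ext))
}

# Keep one conformer per (chain, resno, insert, atom name): highest occupancy,
# ties broken by altloc identifier order.
resolve_altloc <- function(at) {
  alt <- at$alt %||% rep(NA_character_, nrow(at))
  alt[is.na(alt)] <- ""
  if (!any(nzchar(alt))) return(at)
  occ <- at$o %||% rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert %||% "", at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  keep <- !duplicated(key[ord])
  at[sort(ord[keep]), , drop = FALSE]
}

#' Write a structure to PDB or mmCIF
#'
#' The PDB writer is bio3d's fixed-width v3.3 writer; mmCIF output is a
#' minimal `atom_site` loop carrying auth identifiers, coordinates,
#' occupancy and B-factor.
#'
#' @param x a `gyre_structure`.
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
  if (!inherits(x, "gyre_structure")) gd_abort("gyredyn_format_error",
    "write_structure needs a gyre_structure")
  format <- resolve_format(path, match.arg(format))
  at <- x$atoms
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(file = path, xyz = as.vector(t(coords(x))),
                       resno = at$resno, resid = at$resid, eleno = at$eleno,
                       elety = at$elety, chain = at$chain, insert = at$insert,
                       o = at$o, b = at$b, elesy = at$elesy)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) gd_abort("gyredyn_io_error", sprintf("cannot write '%s'", path))
  } else {
    write_mmcif(x, path)
  }
  invisible(path)
}

# Minimal PDBx/mmCIF atom_site writer (coordinates to 1e-6 A). Only the
# categories downstream parsers need for a coordinate model.
write_mmcif <- function(x, path) {
  at <- x$atoms
  ins <- ifelse(nzchar(at$insert), at$insert, "?")
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_",
                         if (nzchar(x$source_label)) x$source_label else "gyredyn")),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s \"%s\" . %s %s 1 %d %s %.6f %.6f %.6f %.2f %.2f %d %s %s \"%s\" %d",
            at$eleno, at$elesy, at$elety, at$resid, at$chain, at$resno, ins,
            at$x, at$y, at$z, at$o, at$b, at$resno, at$resid, at$chain,
            at$elety, x$model_id),
    "#")
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) gd_abort("gyredyn_io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Read a conformational ensemble
#'
#' Multi-model PDB is the ensemble interchange format: one file carries the
#' topology (model 1) and all frames, in identical atom order. When
#' `frames_path` differs from `topology_path`, the topology is read from the
#' first file and the frames from the second; atom counts must agree.
#'
#' @param topology_path path to the topology (multi-model PDB).
#' @param frames_path path to the frames; defaults to `topology_path`.
#' @return a [new_ensemble()] object.
#' @export
read_ensemble <- function(topology_path, frames_path = topology_path) {
  topo <- read_structure(topology_path, format = "pdb")
  pdb <- tryCatch(
    bio3d::read.pdb(frames_path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) gd_abort("gyredyn_io_error",
      sprintf("failed to parse frames '%s': %s", frames_path, conditionMessage(e))))
  xyz <- as.matrix(pdb$xyz)
  if (nrow(xyz) == 0L || ncol(xyz) == 0L)
    gd_abort("gyredyn_empty_ensemble", sprintf("'%s' has zero frames", frames_path))
  if (ncol(xyz) != 3L * n_atoms(topo))
    gd_abort("gyredyn_topology_error", sprintf(
      "frames have %d atoms but topology has %d",
      ncol(xyz) %/% 3L, n_atoms(topo)))
  new_ensemble(topo, xyz)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param x a `gyre_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  if (!inherits(x, "gyre_ensemble"))
    gd_abort("gyredyn_format_error", "write_ensemble needs a gyre_ensemble")
  at <- x$topology$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = x$xyz,
                     resno = at$resno, resid = at$resid, eleno = at$eleno,
                     elety = at$elety, chain = at$chain, insert = at$insert,
                     o = at$o, b = at$b, elesy = at$elesy)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gd_abort("gyredyn_io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}
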