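#' Atomic structure container
#'
#' A `gyre_structure` holds one conformation as an ordered atom table.
#' Columns follow PDB conventions: `eleno` (atom serial), `elety` (atom
#' name, e.g. `"N1"`, `"CA"`, `"P"`), `resid` (3-letter residue name),
#' `chain`, `resno` (author residue number; may be negative, as in
#' dyad-relative octasome numbering), `insert` (insertion code or `""`),
#' `x`, `y`, `z` (Angstrom), `o` (occupancy), `b` (B-factor, Angstrom^2)
#' and `elesy` (element symbol).
#'
#' @param atoms data frame with at least `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`; missing bookkeeping columns are filled with defaults.
#' @param model_id integer model number (1 for single-model files).
#' @param source_label free-text provenance label.
#' @return An object of class `gyre_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L, source_label = "") {
  req <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    gd_abort("gyredyn_format_error",
             paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  n <- nrow(atoms)
  if (n == 0L)
    gd_abort("gyredyn_empty_structure", "structure has zero atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    gd_abort("gyredyn_format_error", "non-finite atom coordinates")
  atoms$eleno  <- atoms$eleno  %||% seq_len(n)
  atoms$insert <- as.character(atoms$insert %||% rep("", n))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o      <- atoms$o %||% rep(1, n)
  atoms$b      <- atoms$b %||% rep(0, n)
  atoms$elesy  <- atoms$elesy %||% guess_element(atoms$elety)
  atoms$chain  <- as.character(atoms$chain)
  atoms$resno  <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms[, c("eleno", "elety", "resid", "chain", "resno",
                           "insert", "x", "y", "z", "o", "b", "elesy")],
         model_id = as.integer(model_id),
         source_label = source_label),
    class = "gyre_structure")
}

# Element symbol from a PDB atom name: leading digits stripped, first letter.
# Two-letter biology metals are not needed for the pseudo-atom fixtures.
guess_element <- function(elety) {
  sub("^([A-Za-z]).*$", "\\1", sub("^[0-9']*", "", elety))
}

#' Number of atoms in a structure
#' @param x a `gyre_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates of a structure as an n x 3 matrix
#' @param x a `gyre_structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a structure
#' @param x a `gyre_structure`.
#' @param xyz n x 3 matrix matching the atom count.
#' @return the structure with new coordinates.
#' @export
set_coords <- function(x, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(x) || ncol(xyz) != 3L)
    gd_abort("gyredyn_topology_error", "coordinate matrix does not match atom count")
  x$atoms$x <- xyz[, 1L]
  x$atoms$y <- xyz[, 2L]
  x$atoms$z <- xyz[, 3L]
  x
}

#' @export
print.gyre_structure <- function(x, ...) {
  cat(sprintf("<gyre_structure> %d atoms, %d chain(s)%s\n",
              n_atoms(x), length(unique(x$atoms$chain)),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

#' Conformational ensemble container
#'
#' A `gyre_ensemble` couples a topology (a [new_structure()] object, frame 0)
#' with a frame matrix in bio3d `xyz` layout: one row per frame, columns
#' `x1,y1,z1,x2,...` in topology atom order.
#'
#' @param topology a `gyre_structure`.
#' @param xyz numeric matrix, `n_frames` x `3*n_atoms`.
#' @param frame_labels optional character/numeric labels, one per frame.
#' @return An object of class `gyre_ensemble`.
#' @export
new_ensemble <- function(topology, xyz, frame_labels = NULL) {
  if (!inherits(topology, "gyre_structure"))
    gd_abort("gyredyn_topology_error", "topology must be a gyre_structure")
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L)
    gd_abort("gyredyn_empty_ensemble", "ensemble has zero frames")
  if (ncol(xyz) != 3L * n_atoms(topology))
    gd_abort("gyredyn_topology_error", sprintf(
      "frame width %d does not match 3 x %d topology atoms",
      ncol(xyz), n_atoms(topology)))
  if (!is.null(frame_labels) && length(frame_labels) != nrow(xyz))
    gd_abort("gyredyn_topology_error", "one frame label per frame required")
  structure(list(topology = topology, xyz = xyz, frame_labels = frame_labels),
            class = "gyre_ensemble")
}

#' Number of frames in an ensemble
#' @param x a `gyre_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Extract one frame of an ensemble as a structure
#' @param x a `gyre_ensemble`.
#' @param i frame index (1-based).
#' @return a `gyre_structure` with that frame's coordinates.
#' @export
get_frame <- function(x, i) {
  if (i < 1L || i > n_frames(x))
    gd_abort("gyredyn_topology_error", sprintf("frame %d out of range", i))
  set_coords(x$topology, matrix(x$xyz[i, ], ncol = 3L, byrow = TRUE))
}

# frame i as an n x 3 matrix without structure overhead
frame_coords <- function(x, i) matrix(x$xyz[i, ], ncol = 3L, byrow = TRUE)

#' @export
print.gyre_ensemble <- function(x, ...) {
  cat(sprintf("<gyre_ensemble> %d frames x %d atoms\n",
              n_frames(x), n_atoms(x$topology)))
  invisible(x)
}
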