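#' Parameters of a synthetic DNA superhelix
#'
#' Defaults are canonical nucleosome-scale geometry: 147 bp laid on a
#' left-handed superhelix of radius 41.9 A and pitch 25.9 A per superhelical
#' turn, 1.65 turns in total. They are test-fixture defaults, fully
#' configurable.
#'
#' @param n_bp number of base pairs (odd for automatic dyad assignment).
#' @param radius superhelix radius, Angstrom.
#' @param pitch rise per superhelical turn, Angstrom.
#' @param total_turns superhelical turns spanned by the duplex; the wrap is
#'   left-handed (negative angular progression).
#' @param sequence `"alternating"` (strand 1 = A,T,A,T,...) or an explicit
#'   A/C/G/T string of length `n_bp` for strand 1.
#' @param twist_per_bp double-helical twist of the local base-pair frame,
#'   degrees per bp.
#' @return a `superhelix_params` list.
#' @export
superhelix_params <- function(n_bp = 147L, radius = 41.9, pitch = 25.9,
                              total_turns = 1.65, sequence = "alternating",
                              twist_per_bp = 360 / 10.5) {
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 3L)
    gd_abort("gyredyn_param_error", "n_bp must be an integer >= 3")
  if (!is.finite(radius) || radius <= 0)
    gd_abort("gyredyn_param_error", "radius must be > 0")
  if (!is.finite(pitch) || pitch < 0)
    gd_abort("gyredyn_param_error", "pitch must be >= 0")
  if (!is.finite(total_turns) || total_turns == 0)
    gd_abort("gyredyn_param_error", "total_turns must be non-zero")
  if (identical(sequence, "alternating")) {
    seq1 <- rep_len(c("A", "T"), n_bp)
  } else {
    seq1 <- strsplit(toupper(sequence), "")[[1]]
    if (length(seq1) != n_bp || !all(seq1 %in% c("A", "C", "G", "T")))
      gd_abort("gyredyn_param_error",
               "sequence must be an A/C/G/T string of length n_bp")
  }
  structure(list(n_bp = n_bp, radius = radius, pitch = pitch,
                 total_turns = total_turns, seq1 = seq1,
                 twist_per_bp = twist_per_bp),
            class = "superhelix_params")
}

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")
PURINES <- c("DA", "DG", "A", "G")
PYRIMIDINES <- c("DC", "DT", "C", "T")

#' Generate a DNA duplex laid on a superhelix, with ground truth
#'
#' Each base pair contributes pseudo-atoms on an idealized local frame
#' centred on the parametric superhelix: two C1' atoms at +/-5.2 A along the
#' base-pair long axis, the purine N1 and pyrimidine N3 2.8 A apart across
#' the pair centre, and backbone P atoms at +/-8.9 A (absent at each
#' strand's 5' terminus). The local frame twists by `twist_per_bp` about the
#' superhelical tangent, so the fixture has helical character without
#' claiming chemical realism. Strand 1 is chain I, strand 2 chain J; author
#' residue numbers are dyad-relative (-h..h on chain I, the partner of I:i
#' being J:-i), mimicking the numbering of deposited octasome models.
#'
#' Watson-Crick detection criteria are satisfied by construction, so
#' [detect_base_pairs()] on the output must recover exactly the returned
#' ground-truth pairing.
#'
#' @param params a [superhelix_params()] object.
#' @return a `gyre_superhelix`: list with `structure` (the atoms), `duplex`
#'   (ground-truth [build_duplex()] result), `params`, and `meta` (per-pair
#'   centres and frame vectors; superhelix axis is +z).
#' @export
make_superhelix_duplex <- function(params = superhelix_params()) {
  if (!inherits(params, "superhelix_params"))
    gd_abort("gyredyn_param_error", "params must come from superhelix_params()")
  n <- params$n_bp
  if (n %% 2L == 0L)
    gd_abort("gyredyn_dyad_error",
             "even n_bp has no automatic dyad; use an odd length")
  h <- (n - 1L) %/% 2L
  p <- seq_len(n)
  u <- (p - 1) / (n - 1)
  phi <- -2 * pi * params$total_turns * u          # left-handed wrap
  zax <- params$pitch * params$total_turns * (u - 0.5)
  centre <- cbind(params$radius * cos(phi), params$radius * sin(phi), zax)
  # orthonormal local frame {radial, e2, tangent} at each bp
  dphi <- -2 * pi * params$total_turns
  tangent <- cbind(-params$radius * sin(phi) * dphi,
                   params$radius * cos(phi) * dphi,
                   rep(params$pitch * params$total_turns, n))
  tangent <- tangent / sqrt(rowSums(tangent^2))
  radial <- cbind(cos(phi), sin(phi), rep(0, n))
  e2 <- cbind(tangent[, 2L] * radial[, 3L] - tangent[, 3L] * radial[, 2L],
              tangent[, 3L] * radial[, 1L] - tangent[, 1L] * radial[, 3L],
              tangent[, 1L] * radial[, 2L] - tangent[, 2L] * radial[, 1L])
  e2 <- e2 / sqrt(rowSums(e2^2))
  psi <- (p - 1) * params$twist_per_bp * pi / 180
  axis_long <- cos(psi) * radial + sin(psi) * e2   # bp long axis

  seq1 <- params$seq1
  seq2 <- unname(COMPLEMENT[seq1])
  purine1 <- seq1 %in% c("A", "G")                 # purine on strand 1?
  s <- ifelse(purine1, 1, -1)
  resno1 <- p - 1L - h
  resno2 <- -resno1

  # one row per atom; build per-role coordinate blocks then interleave
  rows <- list()
  add <- function(elety, chain, resno, resid, xyz, bp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      elety = elety, chain = chain, resno = resno, resid = resid,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], bp = bp,
      stringsAsFactors = FALSE)
  }
  has_p1 <- p > 1L        # strand 1 runs 5'->3' with bp order
  has_p2 <- p < n         # strand 2's 5' end is the last bp
  add("P",   "I", resno1[has_p1], paste0("D", seq1)[has_p1],
      centre[has_p1, , drop = FALSE] + 8.9 * axis_long[has_p1, , drop = FALSE],
      p[has_p1])
  add("C1'", "I", resno1, paste0("D", seq1), centre + 5.2 * axis_long, p)
  add("N1",  ifelse(purine1, "I", "J"),
      ifelse(purine1, resno1, resno2),
      paste0("D", ifelse(purine1, seq1, seq2)),
      centre + 1.4 * s * axis_long, p)
  add("N3",  ifelse(purine1, "J", "I"),
      ifelse(purine1, resno2, resno1),
      paste0("D", ifelse(purine1, seq2, seq1)),
      centre - 1.4 * s * axis_long, p)
  add("C1'", "J", resno2, paste0("D", seq2), centre - 5.2 * axis_long, p)
  add("P",   "J", resno2[has_p2], paste0("D", seq2)[has_p2],
      centre[has_p2, , drop = FALSE] - 8.9 * axis_long[has_p2, , drop = FALSE],
      p[has_p2])
  at <- do.call(rbind, rows)
  # order atoms: chain I by resno then chain J by resno (file-like layout)
  at <- at[order(at$chain, at$resno, at$elety), , drop = FALSE]
  bp_of_row <- at$bp
  at$bp <- NULL
  str <- new_structure(at, source_label = "synthetic superhelix")

  pairs <- data.frame(
    index_from_dyad = resno1,
    chain1 = "I", resnum1 = resno1, resname1 = paste0("D", seq1),
    chain2 = "J", resnum2 = resno2, resname2 = paste0("D", seq2),
    purine_side = ifelse(purine1, "strand1", "strand2"),
    stringsAsFactors = FALSE)
  duplex <- duplex_from_pairs(str, pairs, dyad_position = h + 1L)

  meta <- list(centre = centre, tangent = tangent, radial = radial,
               axis_long = axis_long, axis = c(0, 0, 1),
               bp_of_row = bp_of_row, params = params)
  structure(list(structure = str, duplex = duplex, params = params,
                 meta = meta),
            class = "gyre_superhelix")
}

#' @export
print.gyre_superhelix <- function(x, ...) {
  cat(sprintf("<gyre_superhelix> %d bp, radius %.1f A, %.2f turns\n",
              x$params$n_bp, x$params$radius, x$params$total_turns))
  invisible(x)
}

# atom row indices of all atoms belonging to base pair p (both residues)
pair_atom_rows <- function(sh, p) {
  which(sh$meta$bp_of_row == p)
}

#' Impose a clamshell/gapping deformation on a synthetic superhelix
#'
#' Two deformation modes. *Gyre translation*: all base pairs with
#' `index_from_dyad > split` are rigidly translated by `delta_z` Angstrom
#' along the superhelix axis (+z), emulating gyre gapping. *Arm rotation*:
#' all pairs strictly beyond `hinge` (away from the dyad) are rigidly
#' rotated by `phi` degrees about the radial axis through that hinge pair's
#' centre, emulating arm bending about a hinge. Ground truth in `$meta` is
#' updated.
#'
#' @param sh a `gyre_superhelix`.
#' @param delta_z gyre translation, Angstrom (mode 1).
#' @param split dyad-relative index separating the moved gyre (default 0).
#' @param hinge dyad-relative hinge index (mode 2).
#' @param phi arm rotation, degrees (mode 2).
#' @return the deformed `gyre_superhelix`.
#' @export
open_clamshell <- function(sh, delta_z = NULL, split = 0L,
                           hinge = NULL, phi = NULL) {
  stopifnot(inherits(sh, "gyre_superhelix"))
  idx <- sh$duplex$pairs$index_from_dyad
  xyz <- coords(sh$structure)
  if (!is.null(delta_z)) {
    moved_bp <- which(idx > split)
    rows <- which(sh$meta$bp_of_row %in% moved_bp)
    xyz[rows, 3L] <- xyz[rows, 3L] + delta_z
    sh$meta$centre[moved_bp, 3L] <- sh$meta$centre[moved_bp, 3L] + delta_z
    sh$meta$deformation <- c(sh$meta$deformation,
                             list(list(kind = "gyre-translation",
                                       delta_z = delta_z, split = split)))
  }
  if (!is.null(hinge)) {
    if (is.null(phi)) gd_abort("gyredyn_param_error", "arm rotation needs phi")
    hp <- match(hinge, idx)
    if (is.na(hp))
      gd_abort("gyredyn_address_error",
               sprintf("hinge index %d outside the duplex", hinge))
    moved_bp <- if (hinge >= 0) which(idx > hinge) else which(idx < hinge)
    rows <- which(sh$meta$bp_of_row %in% moved_bp)
    R <- rotation_about(sh$meta$radial[hp, ], phi)
    org <- sh$meta$centre[hp, ]
    xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2L, org) %*% t(R),
                         2L, org, `+`)
    sh$meta$centre[moved_bp, ] <-
      sweep(sweep(sh$meta$centre[moved_bp, , drop = FALSE], 2L, org) %*% t(R),
            2L, org, `+`)
    sh$meta$deformation <- c(sh$meta$deformation,
                             list(list(kind = "arm-rotation",
                                       hinge = hinge, phi = phi)))
  }
  sh$structure <- set_coords(sh$structure, xyz)
  sh$duplex$structure <- sh$structure
  sh
}

#' Gaussian positional-noise ensemble around one structure
#'
#' @param structure a `gyre_structure`.
#' @param sigma isotropic per-coordinate standard deviation, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed; identical seed gives a bit-identical ensemble.
#' @return a `gyre_ensemble`.
#' @export
gaussian_ensemble <- function(structure, sigma, n_frames, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0)
    gd_abort("gyredyn_param_error", "sigma must be >= 0")
  if (n_frames < 1L) gd_abort("gyredyn_param_error", "n_frames must be >= 1")
  base <- as.vector(t(coords(structure)))
  xyz <- matrix(base, nrow = n_frames, ncol = length(base), byrow = TRUE)
  if (sigma > 0) {
    set.seed(as.integer(seed))
    xyz <- xyz + matrix(stats::rnorm(n_frames * length(base), 0, sigma),
                        nrow = n_frames)
  }
  new_ensemble(structure, xyz)
}

#' Clamshell-opening ensemble (oscillating or Gaussian gyre translation)
#'
#' Frame `t` translates the gyre beyond `split` along the superhelix axis by
#' `d_t`: for `waveform = "sine"`, `d_t = amplitude * sin(2*pi*t/period)`;
#' for `waveform = "gaussian"`, `d_t ~ N(mean, sd)`. Optional isotropic
#' jitter is added on top. The imposed displacement series is recorded in
#' `attr(, "imposed")`.
#'
#' @param sh a `gyre_superhelix`.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param amplitude sine amplitude, Angstrom.
#' @param period sine period in frames.
#' @param waveform `"sine"` or `"gaussian"`.
#' @param mean,sd Gaussian waveform parameters, Angstrom.
#' @param split dyad-relative index separating the moved gyre.
#' @param jitter_sigma isotropic positional jitter, Angstrom.
#' @return a `gyre_ensemble` with attribute `imposed` (the `d_t` series).
#' @export
clamshell_ensemble <- function(sh, n_frames, seed = 1L, amplitude = 3,
                               period = n_frames, waveform = c("sine", "gaussian"),
                               mean = 0, sd = 1, split = 0L, jitter_sigma = 0) {
  stopifnot(inherits(sh, "gyre_superhelix"))
  waveform <- match.arg(waveform)
  set.seed(as.integer(seed))
  tt <- seq_len(n_frames)
  d <- switch(waveform,
    sine = amplitude * sin(2 * pi * tt / period),
    gaussian = stats::rnorm(n_frames, mean, sd))
  idx <- sh$duplex$pairs$index_from_dyad
  rows <- which(sh$meta$bp_of_row %in% which(idx > split))
  base <- as.vector(t(coords(sh$structure)))
  xyz <- matrix(base, nrow = n_frames, ncol = length(base), byrow = TRUE)
  zcols <- rows * 3L
  xyz[, zcols] <- xyz[, zcols] + d
  if (jitter_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma),
                        nrow = n_frames)
  ens <- new_ensemble(sh$structure, xyz)
  attr(ens, "imposed") <- d
  ens
}

#' Arm-bending ensemble about two DNA hinges
#'
#' Frame `t` rotates each DNA arm beyond its hinge by
#' `amplitude_deg * sin(2*pi*t/period)` about the radial axis through the
#' hinge pair's centre (both arms in phase), then adds isotropic Gaussian
#' jitter. The imposed hinge indices are recorded in `attr(, "hinges")`.
#'
#' @param sh a `gyre_superhelix`.
#' @param hinge_minus,hinge_plus dyad-relative hinge indices (negative and
#'   positive arm).
#' @param amplitude_deg bending amplitude, degrees.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param jitter_sigma isotropic positional jitter, Angstrom.
#' @param period oscillation period in frames.
#' @return a `gyre_ensemble` with attribute `hinges = c(minus, plus)`.
#' @export
hinge_mode_ensemble <- function(sh, hinge_minus = -46L, hinge_plus = 60L,
                                amplitude_deg = 15, n_frames = 500L, seed = 1L,
                                jitter_sigma = 0.2, period = n_frames) {
  stopifnot(inherits(sh, "gyre_superhelix"))
  if (amplitude_deg < 0)
    gd_abort("gyredyn_param_error", "amplitude must be >= 0")
  idx <- sh$duplex$pairs$index_from_dyad
  hm <- match(hinge_minus, idx)
  hp <- match(hinge_plus, idx)
  if (is.na(hm) || is.na(hp))
    gd_abort("gyredyn_address_error", "hinge index outside the duplex")
  arm_minus <- which(sh$meta$bp_of_row %in% which(idx < hinge_minus))
  arm_plus  <- which(sh$meta$bp_of_row %in% which(idx > hinge_plus))
  base <- coords(sh$structure)
  set.seed(as.integer(seed))
  xyz <- matrix(0, nrow = n_frames, ncol = 3L * nrow(base))
  for (fi in seq_len(n_frames)) {
    phi <- amplitude_deg * sin(2 * pi * fi / period)
    fr <- base
    for (arm in list(list(rows = arm_minus, p = hm),
                     list(rows = arm_plus, p = hp))) {
      if (!length(arm$rows)) next
      R <- rotation_about(sh$meta$radial[arm$p, ], phi)
      org <- sh$meta$centre[arm$p, ]
      fr[arm$rows, ] <- sweep(
        sweep(fr[arm$rows, , drop = FALSE], 2L, org) %*% t(R), 2L, org, `+`)
    }
    xyz[fi, ] <- as.vector(t(fr))
  }
  if (jitter_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma),
                        nrow = n_frames)
  ens <- new_ensemble(sh$structure, xyz)
  attr(ens, "hinges") <- c(hinge_minus, hinge_plus)
  ens
}

#' Synthetic RDH-network fixture with planted hydrogen-bond distances
#'
#' Builds the minimal heavy-atom scaffold of an Arg/Asp/His four-helix-
#' bundle interface (Asp OD1/OD2 and Arg NH2 on `chain_a`, His ND1/NE2 on
#' `chain_b`) with the three audited donor-acceptor distances planted
#' exactly: His ND1 - Asp OD1, His NE2 - Asp OD2, Arg NH2 - Asp OD1.
#'
#' @param interface preset name, see [rdh_contacts()].
#' @param chain_a,chain_b chain ids of the two bundle chains.
#' @param distances length-3 numeric, Angstrom, in the contact order above.
#' @return a `gyre_structure`.
#' @export
make_rdh_fixture <- function(interface = c("CENP-A", "H3", "H4"),
                             chain_a = "A", chain_b = "B",
                             distances = c(2.6, 2.7, 2.9)) {
  interface <- match.arg(interface)
  res <- switch(interface,
    "CENP-A" = c(arg = 118L, asp = 125L, his = 115L),
    "H3"     = c(arg = 116L, asp = 123L, his = 113L),
    "H4"     = c(arg = 78L,  asp = 85L,  his = 75L))
  at <- data.frame(
    elety = c("OD1", "OD2", "ND1", "NE2", "NH2"),
    resid = c("ASP", "ASP", "HIS", "HIS", "ARG"),
    chain = c(chain_a, chain_a, chain_b, chain_b, chain_a),
    resno = c(res[["asp"]], res[["asp"]], res[["his"]], res[["his"]],
              res[["arg"]]),
    x = c(0, 3, 0, 3, 0),
    y = c(0, 0, 0, 0, -distances[3L]),
    z = c(0, 0, distances[1L], distances[2L], 0),
    stringsAsFactors = FALSE)
  new_structure(at, source_label = "synthetic RDH fixture")
}

#' Ideal alpha-helix C-alpha trace
#'
#' @param n_res number of residues; the helical phase is centred on the
#'   midpoint so the fitted principal axis deviates from the geometric axis
#'   only along the mid-phase sine direction (and the deviation shrinks as
#'   the trace lengthens).
#' @param rise rise per residue, Angstrom.
#' @param twist_deg rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param chain chain id.
#' @param origin first-residue axis point.
#' @param axis helix axis direction (need not be unit).
#' @param resno_start first residue number.
#' @return a `gyre_structure` of CA pseudo-atoms (residue name ALA).
#' @export
make_ideal_helix <- function(n_res = 18L, rise = 1.5, twist_deg = 100,
                             radius = 2.3, chain = "A", origin = c(0, 0, 0),
                             axis = c(0, 0, 1), resno_start = 1L) {
  if (n_res < 2L) gd_abort("gyredyn_param_error", "n_res must be >= 2")
  k <- unit(axis)
  ref <- if (abs(k[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(cross3(k, ref))
  v <- cross3(k, u)
  i <- seq_len(n_res) - 1L
  # phase centred on the midpoint: the axial-cosine covariance then vanishes
  # by symmetry and the principal-axis tilt stays in the sine direction
  ang <- (i - (n_res - 1) / 2) * twist_deg * pi / 180
  pos <- outer(i * rise, k) + radius * (outer(cos(ang), u) + outer(sin(ang), v))
  pos <- sweep(pos, 2L, origin, `+`)
  new_structure(data.frame(
    elety = "CA", resid = "ALA", chain = chain,
    resno = resno_start + i, x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    stringsAsFactors = FALSE), source_label = "ideal helix")
}

#' Synthetic four-helix-bundle pair with an imposed probe rotation
#'
#' Builds two pseudo-bundles of four ideal helices each. The two anchor
#' helices (chains A, B, axes along z) are identical between the bundles;
#' the two probe helices (chains C, D, axes perpendicular to z) of bundle B
#' are rotated by `rotation_deg` about the anchor (z) axis. Optional
#' isotropic Gaussian noise is added to every atom of both bundles.
#' Because the probe axes are perpendicular to the rotation axis,
#' [bundle_rotation()] on the noiseless pair returns exactly
#' `min(rotation_deg, 180 - rotation_deg)`.
#'
#' @param rotation_deg imposed probe rotation about the anchor axis,
#'   degrees in `[0, 180]`.
#' @param noise_sigma isotropic positional noise, Angstrom.
#' @param seed RNG seed for the noise.
#' @return list with structures `a` and `b`, `anchor` (selection text),
#'   `probe` (list: `chain`, `resno` range) and `imposed_deg`.
#' @export
make_bundle_pair <- function(rotation_deg, noise_sigma = 0, seed = 1L) {
  if (rotation_deg < 0 || rotation_deg > 180)
    gd_abort("gyredyn_param_error", "rotation_deg must be in [0, 180]")
  n <- 18L
  helices <- list(
    make_ideal_helix(n, chain = "A", origin = c(4.5, 0, -13),  axis = c(0, 0, 1)),
    make_ideal_helix(n, chain = "B", origin = c(-4.5, 1, 13),  axis = c(0, 0, -1)),
    make_ideal_helix(n, chain = "C", origin = c(-13, 6, 3),    axis = c(1, 0, 0)),
    make_ideal_helix(n, chain = "D", origin = c(13, -6, 5),    axis = c(-1, 0, 0)))
  at <- do.call(rbind, lapply(helices, function(s) s$atoms))
  at$eleno <- seq_len(nrow(at))
  a <- new_structure(at, source_label = "bundle A")
  b <- a
  b$source_label <- "bundle B"
  probe_rows <- b$atoms$chain %in% c("C", "D")
  R <- rotation_about(c(0, 0, 1), rotation_deg)
  xyz <- coords(b)
  xyz[probe_rows, ] <- xyz[probe_rows, , drop = FALSE] %*% t(R)
  b <- set_coords(b, xyz)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    a <- set_coords(a, coords(a) + matrix(stats::rnorm(3L * n_atoms(a), 0, noise_sigma), ncol = 3L))
    b <- set_coords(b, coords(b) + matrix(stats::rnorm(3L * n_atoms(b), 0, noise_sigma), ncol = 3L))
  }
  list(a = a, b = b,
       anchor = "chain A or chain B",
       probe = list(chain = "C", resno = c(1L, n)),
       imposed_deg = rotation_deg)
}
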