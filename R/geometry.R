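#' Gyre-opening ("clamshell") angle
#'
#' The interior angle, in degrees, at the dyad vertex formed by the three
#' reference points of the base pairs at `-offset`, `0` and `+offset` from
#' the dyad. The operational reference point is the purine N1 atom
#' (`mode = "N1-purine"`, the default); `mode = "bp-center"` uses the
#' midpoint of the two C1' atoms instead.
#'
#' @param duplex a `gyre_duplex`.
#' @param offset dyad-relative arm offset in bp (default 39, half-way
#'   between dyad and DNA ends of a 147-bp wrap).
#' @param mode reference point: `"N1-purine"` or `"bp-center"`.
#' @param xyz optional coordinate override (n x 3), for per-frame use.
#' @return angle in degrees, in (0, 180].
#' @export
gyre_angle <- function(duplex, offset = 39L, mode = c("N1-purine", "bp-center"),
                       xyz = NULL) {
  mode <- match.arg(mode)
  pt <- gyre_point_fun(mode)
  vertex_angle(pt(duplex, -offset, xyz), pt(duplex, 0L, xyz),
               pt(duplex, offset, xyz))
}

#' Gyre distance
#'
#' Euclidean distance, in Angstrom, between the reference points of the base
#' pairs at `-offset` and `+offset` from the dyad.
#'
#' @inheritParams gyre_angle
#' @return distance in Angstrom.
#' @export
gyre_distance <- function(duplex, offset = 39L,
                          mode = c("N1-purine", "bp-center"), xyz = NULL) {
  mode <- match.arg(mode)
  pt <- gyre_point_fun(mode)
  vnorm(pt(duplex, offset, xyz) - pt(duplex, -offset, xyz))
}

gyre_point_fun <- function(mode) {
  switch(mode, "N1-purine" = purine_n1, "bp-center" = bp_center)
}

#' Gyre angle and distance together
#'
#' @inheritParams gyre_angle
#' @return one-row data frame with `theta_deg`, `distance_A`, `offset`,
#'   `dyad_index` (always 0) and `mode`.
#' @export
gyre_metrics <- function(duplex, offset = 39L,
                         mode = c("N1-purine", "bp-center"), xyz = NULL) {
  mode <- match.arg(mode)
  data.frame(theta_deg = gyre_angle(duplex, offset, mode, xyz),
             distance_A = gyre_distance(duplex, offset, mode, xyz),
             offset = offset, dyad_index = 0L, mode = mode)
}

# resolve a base-pair address: plain number = dyad-relative index,
# list(chain=, resnum=) = author residue address
resolve_bp <- function(duplex, address) {
  if (is.numeric(address) && length(address) == 1L) {
    r <- match(address, duplex$pairs$index_from_dyad)
    if (is.na(r))
      gd_abort("gyredyn_address_error",
               sprintf("no base pair at dyad-relative index %s", address))
    return(duplex$pairs$index_from_dyad[r])
  }
  if (is.list(address) && !is.null(address$chain) && !is.null(address$resnum)) {
    p <- duplex$pairs
    hit <- which((p$chain1 == address$chain & p$resnum1 == address$resnum) |
                 (p$chain2 == address$chain & p$resnum2 == address$resnum))
    if (length(hit) != 1L)
      gd_abort("gyredyn_address_error", sprintf(
        "address %s:%s matches %d base pairs", address$chain, address$resnum,
        length(hit)))
    return(p$index_from_dyad[hit])
  }
  gd_abort("gyredyn_address_error",
           "base-pair address must be a dyad index or list(chain=, resnum=)")
}

#' Distance between two base pairs
#'
#' Both dyad-relative indices (plain numbers) and author residue addresses
#' (`list(chain =, resnum =)`) are accepted, so measurements stated in
#' either convention of deposited models can be reproduced without guessing
#' which one a label uses.
#'
#' @param duplex a `gyre_duplex`.
#' @param address_a,address_b base-pair addresses.
#' @param mode reference point, as in [gyre_angle()].
#' @param xyz optional coordinate override.
#' @return distance in Angstrom.
#' @export
bp_distance <- function(duplex, address_a, address_b,
                        mode = c("N1-purine", "bp-center"), xyz = NULL) {
  mode <- match.arg(mode)
  pt <- gyre_point_fun(mode)
  ia <- resolve_bp(duplex, address_a)
  ib <- resolve_bp(duplex, address_b)
  vnorm(pt(duplex, ia, xyz) - pt(duplex, ib, xyz))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R x + t` over the mobile selection against the reference selection.
#' Reflections are excluded by determinant correction, as required for
#' chiral biomolecules.
#'
#' @param mobile,reference `gyre_structure` objects (or n x 3 matrices).
#' @param sel_mobile,sel_reference optional selection expressions (see
#'   [select_atoms()]) restricting the fit; counts must agree and
#'   correspondence is positional.
#' @return list of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (3-vector) and `rmsd` (Angstrom, over the fitted
#'   selection).
#' @export
superpose <- function(mobile, reference, sel_mobile = NULL, sel_reference = NULL) {
  X <- fit_coords(mobile, sel_mobile)
  Y <- fit_coords(reference, sel_reference)
  if (nrow(X) != nrow(Y))
    gd_abort("gyredyn_topology_error", sprintf(
      "selection sizes differ: %d mobile vs %d reference atoms",
      nrow(X), nrow(Y)))
  if (nrow(X) < 3L)
    gd_abort("gyredyn_degenerate_geometry", "superposition needs >= 3 atoms")
  kabsch_fit(X, Y)
}

fit_coords <- function(x, sel) {
  if (inherits(x, "gyre_structure")) {
    if (!is.null(sel)) x <- select_atoms(x, sel)
    coords(x)
  } else as.matrix(x)
}

kabsch_fit <- function(X, Y) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  s <- svd(crossprod(Xc, Yc))          # 3x3
  if (s$d[2L] < 1e-8 * max(s$d[1L], 1e-12))
    gd_abort("gyredyn_degenerate_geometry",
             "selection is (near-)collinear; rotation is not determined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.vector(my - R %*% mx)
  fitted <- sweep(Xc %*% t(R), 2L, my, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A, rmsd %.4f A\n",
              ang, vnorm(x$translation), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure or coordinate matrix
#'
#' @param x a `gyre_structure` or n x 3 matrix.
#' @param transform a `rigid_transform` from [superpose()].
#' @return the transformed object, same kind as the input.
#' @export
apply_transform <- function(x, transform) {
  tf <- function(m) sweep(m %*% t(transform$rotation), 2L,
                          transform$translation, `+`)
  if (inherits(x, "gyre_structure")) set_coords(x, tf(coords(x))) else tf(as.matrix(x))
}

#' Best-fit helix axis
#'
#' The axis is the principal direction of the centred coordinates of the
#' selected trace atoms, oriented from the first towards the last residue
#' of the range (N to C for a protein helix).
#'
#' @param structure a `gyre_structure`.
#' @param resno_range length-2 integer vector (inclusive residue range).
#' @param chain optional chain id restricting the selection.
#' @param atom_name trace atom name (default `"CA"`).
#' @return list of class `helix_axis`: `direction` (unit 3-vector),
#'   `centroid` (3-vector, Angstrom) and `n_atoms`.
#' @export
helix_axis <- function(structure, resno_range, chain = NULL, atom_name = "CA") {
  sel <- sprintf("resnum %d:%d and name %s",
                 as.integer(resno_range[1L]), as.integer(resno_range[2L]),
                 atom_name)
  if (!is.null(chain)) sel <- sprintf("chain %s and (%s)", chain, sel)
  sub <- select_atoms(structure, sel)
  sub$atoms <- sub$atoms[order(sub$atoms$resno), , drop = FALSE]
  X <- coords(sub)
  if (nrow(X) < 4L)
    gd_abort("gyredyn_degenerate_geometry",
             sprintf("helix axis needs >= 4 atoms, got %d", nrow(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  s <- svd(Xc, nu = 0L, nv = 1L)
  if (s$d[1L] < 1e-9)
    gd_abort("gyredyn_degenerate_geometry", "zero coordinate spread")
  dir <- as.vector(s$v)
  # orient from first to last residue of the range
  span <- X[nrow(X), ] - X[1L, ]
  if (sum(dir * span) < 0) dir <- -dir
  out <- list(direction = dir, centroid = ctr, n_atoms = nrow(X))
  class(out) <- "helix_axis"
  out
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("<helix_axis> direction (%.3f, %.3f, %.3f), %d atoms\n",
              x$direction[1L], x$direction[2L], x$direction[3L], x$n_atoms))
  invisible(x)
}

#' Four-helix-bundle rotation between two structures
#'
#' Superposes structure A onto structure B via the anchor selections, then
#' measures the angle between the probe helix axes. The default is the
#' acute line-line angle in `[0, 90]` degrees (orientation-free, matching
#' how an overlay divergence is read off a figure); `signed = TRUE`
#' additionally folds in the sense of rotation about the anchor axis and
#' returns a value in `(-180, 180]`.
#'
#' @param structure_a,structure_b `gyre_structure` objects.
#' @param anchor_a,anchor_b anchor selection expressions (superposable,
#'   equal atom counts).
#' @param probe_a,probe_b probe helix specs: `list(chain =, resno = c(a, b))`
#'   with optional `atom` (default `"CA"`).
#' @param signed return the signed angle about the anchor axis instead of
#'   the line-line angle.
#' @return rotation angle in degrees.
#' @export
bundle_rotation <- function(structure_a, anchor_a, probe_a,
                            structure_b, anchor_b, probe_b, signed = FALSE) {
  tf <- superpose(structure_a, structure_b, anchor_a, anchor_b)
  a_fit <- apply_transform(structure_a, tf)
  axis_of <- function(str, probe) {
    helix_axis(str, probe$resno, chain = probe$chain,
               atom_name = probe$atom %||% "CA")
  }
  da <- axis_of(a_fit, probe_a)$direction
  db <- axis_of(structure_b, probe_b)$direction
  line_angle <- atan2(vnorm(cross3(da, db)), abs(sum(da * db))) * 180 / pi
  if (!signed) return(line_angle)
  # sense of rotation about the anchor axis (principal axis of the anchor)
  anchor_dir <- {
    A <- fit_coords(structure_b, anchor_b)
    sv <- svd(sweep(A, 2L, colMeans(A)), nu = 0L, nv = 1L)
    as.vector(sv$v)
  }
  pa <- unit(da - sum(da * anchor_dir) * anchor_dir)
  pb <- unit(db - sum(db * anchor_dir) * anchor_dir)
  atan2(sum(cross3(pa, pb) * anchor_dir), sum(pa * pb)) * 180 / pi
}

#' Donor-acceptor distances for a hydrogen-bond contact list
#'
#' Distance-only auditing (no angular or energetic scoring): for each
#' (donor, acceptor) heavy-atom address pair, the Euclidean distance is
#' returned in input order.
#'
#' @param structure a `gyre_structure`.
#' @param contacts data frame with columns `chain1`, `resnum1`, `atom1`,
#'   `chain2`, `resnum2`, `atom2` (e.g. from [rdh_contacts()]).
#' @return numeric vector of distances, Angstrom (length 0 for an empty
#'   contact list).
#' @export
hbond_distances <- function(structure, contacts) {
  if (is.null(contacts) || nrow(contacts) == 0L) return(numeric(0))
  at <- structure$atoms
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  r1 <- match(paste(contacts$chain1, contacts$resnum1, contacts$atom1, sep = "\r"), key)
  r2 <- match(paste(contacts$chain2, contacts$resnum2, contacts$atom2, sep = "\r"), key)
  bad <- which(is.na(r1) | is.na(r2))
  if (length(bad))
    gd_abort("gyredyn_address_error", paste(
      "unresolved contact atom(s):",
      paste(sprintf("%s:%s %s / %s:%s %s",
                    contacts$chain1[bad], contacts$resnum1[bad], contacts$atom1[bad],
                    contacts$chain2[bad], contacts$resnum2[bad], contacts$atom2[bad]),
            collapse = "; ")))
  sqrt((at$x[r1] - at$x[r2])^2 + (at$y[r1] - at$y[r2])^2 + (at$z[r1] - at$z[r2])^2)
}

#' Preset RDH-network contact list for a four-helix bundle
#'
#' The Arg/Asp/His triad stabilizing homotypic four-helix bundles: arginine
#' and aspartate on one chain, histidine on the facing chain. Presets cover
#' the three interfaces of nucleosome-like particles: CENP-A/CENP-A
#' (Arg118/Asp125/His115), H3/H3 (Arg116/Asp123/His113) and H4/H4
#' (Arg78/Asp85/His75). Three distances are audited per interface
#' direction: His ND1 to Asp OD1, His NE2 to Asp OD2 (cross-chain) and
#' Arg NH2 to Asp OD1 (intra-chain salt-bridge arm).
#'
#' @param interface `"CENP-A"`, `"H3"` or `"H4"`.
#' @param chain_a,chain_b the two chain ids forming the bundle; with
#'   `both_directions = TRUE` (default) the symmetric contacts
#'   (swapping the chains) are appended.
#' @param both_directions audit both symmetric copies of the interface.
#' @return contact data frame for [hbond_distances()].
#' @export
rdh_contacts <- function(interface = c("CENP-A", "H3", "H4"),
                         chain_a, chain_b, both_directions = TRUE) {
  interface <- match.arg(interface)
  res <- switch(interface,
    "CENP-A" = c(arg = 118L, asp = 125L, his = 115L),
    "H3"     = c(arg = 116L, asp = 123L, his = 113L),
    "H4"     = c(arg = 78L,  asp = 85L,  his = 75L))
  one_dir <- function(ca, cb) data.frame(
    chain1 = c(cb, cb, ca),
    resnum1 = c(res[["his"]], res[["his"]], res[["arg"]]),
    atom1 = c("ND1", "NE2", "NH2"),
    chain2 = ca,
    resnum2 = c(res[["asp"]], res[["asp"]], res[["asp"]]),
    atom2 = c("OD1", "OD2", "OD1"),
    stringsAsFactors = FALSE)
  out <- one_dir(chain_a, chain_b)
  if (both_directions && !identical(chain_a, chain_b))
    out <- rbind(out, one_dir(chain_b, chain_a))
  out
}
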