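#' Iteratively align an ensemble to its mean structure
#'
#' Standard essential-dynamics preprocessing: every frame is rigid-body
#' fitted (on the fit selection) to the running mean structure, the mean is
#' recomputed, and the cycle repeats until the mean moves by less than
#' `tol` Angstrom (RMS over fitted atoms) or `max_iter` cycles. All atoms
#' are transformed; the fit is computed on the selection only. If the
#' iteration does not converge a warning is raised and the best result is
#' returned with attribute `converged = FALSE`.
#'
#' @param ensemble a `gyre_ensemble`.
#' @param selection fit selection expression (default: all atoms).
#' @param tol convergence threshold on the mean-structure shift, Angstrom.
#' @param max_iter iteration cap.
#' @return the aligned `gyre_ensemble` (attribute `converged`).
#' @export
align_ensemble <- function(ensemble, selection = NULL, tol = 1e-6,
                           max_iter = 100L) {
  stopifnot(inherits(ensemble, "gyre_ensemble"))
  na <- n_atoms(ensemble$topology)
  sel_idx <- if (is.null(selection)) seq_len(na) else
    which(selection_mask(ensemble$topology$atoms, selection))
  if (!length(sel_idx))
    gd_abort("gyredyn_empty_selection", "alignment selection matches no atoms")
  nf <- n_frames(ensemble)
  frames <- lapply(seq_len(nf), function(i) frame_coords(ensemble, i))
  ref <- frames[[1L]][sel_idx, , drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nf)) {
      tf <- kabsch_fit(frames[[i]][sel_idx, , drop = FALSE], ref)
      frames[[i]] <- apply_transform(frames[[i]], tf)
    }
    new_ref <- Reduce(`+`, lapply(frames, function(f) f[sel_idx, , drop = FALSE])) / nf
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ensemble alignment did not converge within ", max_iter,
            " iterations; returning best result", call. = FALSE)
  out <- ensemble
  out$xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  attr(out, "converged") <- converged
  attr(out, "aligned") <- TRUE
  out
}

#' Per-residue RMSF and B-factor profile
#'
#' RMSF of a particle is the root of the time-mean squared displacement
#' from its time-mean position, computed on an aligned ensemble. Residue
#' aggregation follows `atom_policy`: `"CA"` (protein trace atom), `"P"`
#' (DNA backbone phosphate) or `"heavy-mean"` (RMS over all the residue's
#' atoms). B-factors use the isotropic crystallographic relation
#' `B = (8*pi^2/3) * RMSF^2`.
#'
#' @param ensemble an aligned `gyre_ensemble` with at least 2 frames.
#' @param atom_policy `"CA"`, `"P"` or `"heavy-mean"`.
#' @return data frame with `chain`, `resno`, `rmsf` (Angstrom), `b_factor`
#'   (Angstrom^2) and attribute `atom_policy`.
#' @export
rmsf_profile <- function(ensemble, atom_policy = c("CA", "P", "heavy-mean")) {
  atom_policy <- match.arg(atom_policy)
  if (n_frames(ensemble) < 2L)
    gd_abort("gyredyn_insufficient_frames",
             "RMSF needs at least 2 frames")
  at <- ensemble$topology$atoms
  keep <- switch(atom_policy,
    "CA" = at$elety == "CA",
    "P" = at$elety == "P",
    "heavy-mean" = !(at$elesy %in% "H"))
  if (!any(keep))
    gd_abort("gyredyn_empty_selection",
             sprintf("no atoms match policy '%s'", atom_policy))
  idx <- which(keep)
  cols <- rep(idx * 3L, each = 3L) + c(-2L, -1L, 0L)
  X <- ensemble$xyz[, cols, drop = FALSE]
  msd3 <- colMeans(sweep(X, 2L, colMeans(X))^2)          # per coordinate
  msd_atom <- msd3[seq(1L, length(msd3), 3L)] +
              msd3[seq(2L, length(msd3), 3L)] +
              msd3[seq(3L, length(msd3), 3L)]
  grp <- paste(at$chain[idx], at$resno[idx], sep = "\r")
  msd_res <- tapply(msd_atom, grp, mean)
  ord <- match(unique(grp), names(msd_res))
  key <- unique(grp)
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    rmsf = sqrt(as.vector(msd_res[ord])),
    stringsAsFactors = FALSE)
  out$b_factor <- (8 * pi^2 / 3) * out$rmsf^2
  attr(out, "atom_policy") <- atom_policy
  out
}

#' Evaluate a geometric metric on every frame
#'
#' The duplex is resolved once on the topology; per frame only coordinates
#' change, so evaluation is a lookup plus vector arithmetic. `metric` may
#' also be a function `(duplex, xyz) -> number` for custom observables.
#'
#' @param ensemble a `gyre_ensemble`.
#' @param duplex the `gyre_duplex` resolved on the ensemble topology.
#' @param metric `"gyre_angle"`, `"gyre_distance"`, `"bp_distance"` or a
#'   function.
#' @param ... passed on to the metric (`offset`, `mode`, addresses, ...).
#' @return numeric vector, one value per frame, with attributes
#'   `metric_name` and `units`.
#' @export
metric_series <- function(ensemble, duplex, metric = "gyre_angle", ...) {
  stopifnot(inherits(ensemble, "gyre_ensemble"))
  fun <- if (is.function(metric)) metric else switch(metric,
    gyre_angle = gyre_angle,
    gyre_distance = gyre_distance,
    bp_distance = bp_distance,
    gd_abort("gyredyn_param_error", sprintf("unknown metric '%s'", metric)))
  nf <- n_frames(ensemble)
  vals <- numeric(nf)
  for (i in seq_len(nf)) {
    vals[i] <- tryCatch(fun(duplex, ..., xyz = frame_coords(ensemble, i)),
      error = function(e) gd_abort("gyredyn_metric_error", sprintf(
        "metric failed on frame %d: %s", i, conditionMessage(e))))
  }
  attr(vals, "metric_name") <- if (is.function(metric)) "custom" else metric
  attr(vals, "units") <- if (identical(metric, "gyre_angle")) "degrees" else "Angstrom"
  vals
}

#' Probability density of a per-frame metric series
#'
#' Normalized histogram (probabilities summing to 1) with mean and standard
#' deviation, the summary behind distribution plots of per-frame opening
#' angles/distances.
#'
#' @param series numeric vector (>= 10 values).
#' @param n_bins number of equal-width bins.
#' @return list of class `metric_density`: `bin_centers`, `probability`,
#'   `mean`, `std`, `n`.
#' @export
metric_density <- function(series, n_bins = 72L) {
  x <- as.numeric(series)
  if (length(x) < 10L)
    gd_abort("gyredyn_param_error",
             "density needs at least 10 values")
  if (diff(range(x)) == 0) {
    out <- list(bin_centers = x[1L], probability = 1, mean = x[1L], std = 0,
                n = length(x))
  } else {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    out <- list(bin_centers = h$mids, probability = h$counts / sum(h$counts),
                mean = mean(x), std = stats::sd(x), n = length(x))
  }
  class(out) <- "metric_density"
  out
}

#' @export
print.metric_density <- function(x, ...) {
  cat(sprintf("<metric_density> n = %d, mean = %.3f, sd = %.3f, %d bins\n",
              x$n, x$mean, x$std, length(x$bin_centers)))
  invisible(x)
}

#' Cartesian principal component analysis of an aligned ensemble
#'
#' Eigen-decomposition of the covariance of the centred Cartesian
#' coordinates of the selection, unweighted by default (a mass-weighting
#' vector may be supplied). Computed via SVD of the centred frame matrix,
#' so eigenvalues are exact sample-covariance eigenvalues (divisor
#' `n_frames - 1`), returned in descending order with orthonormal
#' eigenvectors.
#'
#' @param ensemble an aligned `gyre_ensemble` with > 1 frame.
#' @param selection selection expression (default: protein CA plus DNA P
#'   atoms, the standard reduced atom set).
#' @param n_modes number of modes to keep (default: all).
#' @param weights optional per-atom mass weights (length = selected atoms).
#' @return list of class `mode_set`: `eigenvalues` (Angstrom^2, all of
#'   them), `vectors` (3n x n_modes, unit columns), `mean_coords`,
#'   `atoms` (the selected atom table), `total_variance`.
#' @export
pca_modes <- function(ensemble, selection = "name CA or name P",
                      n_modes = NULL, weights = NULL) {
  stopifnot(inherits(ensemble, "gyre_ensemble"))
  if (n_frames(ensemble) < 2L)
    gd_abort("gyredyn_insufficient_frames", "PCA needs more than 1 frame")
  sub <- if (is.null(selection)) ensemble else select_atoms(ensemble, selection)
  X <- sub$xyz
  if (!is.null(weights)) {
    if (length(weights) != nrow(sub$topology$atoms))
      gd_abort("gyredyn_param_error", "one weight per selected atom required")
    X <- sweep(X, 2L, rep(sqrt(weights), each = 3L), `*`)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  k_all <- min(nrow(Xc) - 1L, ncol(Xc))
  s <- svd(Xc, nu = 0L, nv = k_all)
  evals <- s$d[seq_len(k_all)]^2 / (nrow(Xc) - 1L)
  k <- min(n_modes %||% k_all, k_all)
  out <- list(eigenvalues = evals,
              vectors = s$v[, seq_len(k), drop = FALSE],
              mean_coords = mu,
              atoms = sub$topology$atoms,
              total_variance = sum(Xc^2) / (nrow(Xc) - 1L),
              n_modes = k)
  class(out) <- "mode_set"
  out
}

#' @export
print.mode_set <- function(x, ...) {
  fr <- x$eigenvalues[1L] / x$total_variance
  cat(sprintf("<mode_set> %d modes kept, mode 1 carries %.1f%% of variance\n",
              x$n_modes, 100 * fr))
  invisible(x)
}

#' Per-base-pair amplitude profile of a PCA mode
#'
#' For each base pair of the duplex, the mean over its atoms present in the
#' mode's selection of the norm of the mode's per-atom 3-vector.
#'
#' @param modes a `mode_set`.
#' @param duplex the `gyre_duplex` on the same topology.
#' @param mode mode number (default 1).
#' @return data frame `index_from_dyad`, `amplitude` (bp without selected
#'   atoms are dropped).
#' @export
mode_bp_amplitude <- function(modes, duplex, mode = 1L) {
  v <- modes$vectors[, mode]
  at <- modes$atoms
  anorm <- sqrt(v[seq(1L, length(v), 3L)]^2 +
                v[seq(2L, length(v), 3L)]^2 +
                v[seq(3L, length(v), 3L)]^2)
  p <- duplex$pairs
  key <- paste(at$chain, at$resno, sep = "\r")
  amp <- vapply(seq_len(nrow(p)), function(r) {
    rows <- which(key %in% c(paste(p$chain1[r], p$resnum1[r], sep = "\r"),
                             paste(p$chain2[r], p$resnum2[r], sep = "\r")))
    if (!length(rows)) NA_real_ else mean(anorm[rows])
  }, numeric(1))
  out <- data.frame(index_from_dyad = p$index_from_dyad, amplitude = amp)
  out[!is.na(out$amplitude), , drop = FALSE]
}

#' Locate DNA hinge base pairs from the dominant PCA mode
#'
#' A hinge separates the rigid core from an oscillating arm. The per-bp
#' amplitude profile of the first eigenvector is thresholded at `k` times
#' the median amplitude of the core (`|index| <= core_halfwidth`); on each
#' arm, scanning outwards from the dyad, the contiguous above-threshold run
#' that reaches the arm's end is located (an isolated noise spike cannot
#' trigger it) and the hinge is the pivot base pair just inside that run.
#' If an arm never sustains the threshold, the result for that arm is
#' `NA` (explicit no-hinge).
#'
#' @param modes a `mode_set` covering the duplex's DNA atoms.
#' @param duplex the `gyre_duplex`.
#' @param k threshold multiplier over the median core amplitude.
#' @param core_halfwidth half-width of the core window, bp.
#' @return list with `minus` and `plus` (hinge indices or `NA`), `k`,
#'   `threshold` and the amplitude `profile`.
#' @export
hinge_positions <- function(modes, duplex, k = 2, core_halfwidth = 20L) {
  prof <- mode_bp_amplitude(modes, duplex, 1L)
  if (!nrow(prof))
    gd_abort("gyredyn_param_error", "mode has no DNA coverage on the duplex")
  core <- prof$amplitude[abs(prof$index_from_dyad) <= core_halfwidth]
  if (!length(core))
    gd_abort("gyredyn_param_error", "no base pairs inside the core window")
  thr <- k * stats::median(core)
  arm_hinge <- function(side) {
    arm <- prof[sign(prof$index_from_dyad) == side, , drop = FALSE]
    arm <- arm[order(abs(arm$index_from_dyad)), , drop = FALSE]  # dyad outwards
    above <- arm$amplitude > thr
    if (!length(above) || !above[length(above)]) return(NA_integer_)
    run_start <- length(above)
    while (run_start > 1L && above[run_start - 1L]) run_start <- run_start - 1L
    # the pivot: the last base pair inside the rigid core, about which the
    # above-threshold arm swings
    if (run_start > 1L) arm$index_from_dyad[run_start - 1L]
    else prof$index_from_dyad[which.min(abs(prof$index_from_dyad))]
  }
  list(minus = arm_hinge(-1), plus = arm_hinge(1),
       k = k, threshold = thr, profile = prof)
}

#' End-to-end DNA hinge detection on an ensemble
#'
#' Convenience pipeline: align the ensemble on the rigid DNA core
#' (backbone P atoms with `|index| <= core_halfwidth`), run one-mode PCA on
#' all DNA P atoms, and locate the hinges.
#'
#' @param ensemble a `gyre_ensemble`.
#' @param duplex the `gyre_duplex` on the ensemble topology.
#' @param k,core_halfwidth passed to [hinge_positions()].
#' @return as [hinge_positions()].
#' @export
detect_dna_hinges <- function(ensemble, duplex, k = 2, core_halfwidth = 20L) {
  p <- duplex$pairs
  core <- p[abs(p$index_from_dyad) <= core_halfwidth, , drop = FALSE]
  core_sel <- sprintf("name P and (chain %s and resnum %d:%d or chain %s and resnum %d:%d)",
                      core$chain1[1L], min(core$resnum1), max(core$resnum1),
                      core$chain2[1L], min(core$resnum2), max(core$resnum2))
  aligned <- align_ensemble(ensemble, core_sel)
  modes <- pca_modes(aligned, selection = "name P", n_modes = 1L)
  hinge_positions(modes, duplex, k = k, core_halfwidth = core_halfwidth)
}

#' Export a PCA mode as porcupine data
#'
#' Writes (i) a CSV with one row per selected atom (identifiers, mean
#' position, scaled displacement vector and its magnitude) and (ii) a
#' two-model PDB at `mean - scale*mode` and `mean + scale*mode`, from which
#' arrow renderings are made.
#'
#' @param modes a `mode_set`.
#' @param scale Angstrom of displacement per unit eigenvector component.
#' @param csv_path,pdb_path output paths (either may be `NULL` to skip).
#' @param mode mode number (default 1).
#' @return invisible list of the data frame and written paths.
#' @export
porcupine_export <- function(modes, scale, csv_path = NULL, pdb_path = NULL,
                             mode = 1L) {
  v <- modes$vectors[, mode] * scale
  at <- modes$atoms
  mu <- matrix(modes$mean_coords, ncol = 3L, byrow = TRUE)
  dv <- matrix(v, ncol = 3L, byrow = TRUE)
  df <- data.frame(eleno = at$eleno, elety = at$elety, chain = at$chain,
                   resno = at$resno,
                   x = mu[, 1L], y = mu[, 2L], z = mu[, 3L],
                   dx = dv[, 1L], dy = dv[, 2L], dz = dv[, 3L],
                   magnitude = sqrt(rowSums(dv^2)))
  if (!is.null(csv_path)) {
    ok <- tryCatch({ utils::write.csv(df, csv_path, row.names = FALSE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) gd_abort("gyredyn_io_error", sprintf("cannot write '%s'", csv_path))
  }
  if (!is.null(pdb_path)) {
    topo <- ensemble_topology_from_atoms(at)
    ens <- new_ensemble(topo, rbind(modes$mean_coords - v,
                                    modes$mean_coords + v))
    write_ensemble(ens, pdb_path)
  }
  invisible(list(table = df, csv = csv_path, pdb = pdb_path))
}

ensemble_topology_from_atoms <- function(at) {
  at$x <- at$x %||% 0; at$y <- at$y %||% 0; at$z <- at$z %||% 0
  new_structure(at)
}
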