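test_that("alignment removes rigid-body motion exactly", {
  s <- make_superhelix_duplex(superhelix_params(n_bp = 21))$structure
  # identical frames stay put
  ens0 <- gaussian_ensemble(s, 0, 4, seed = 1)
  al0 <- align_ensemble(ens0)
  expect_lt(max(abs(al0$xyz - ens0$xyz)), 1e-9)
  expect_true(attr(al0, "converged"))
  # one structure under random rigid motions collapses to a single frame
  frames <- t(vapply(1:6, function(k) {
    as.vector(t(coords(apply_rigid(s, random_rigid_motion(k)))))
  }, numeric(3L * n_atoms(s))))
  al <- align_ensemble(new_ensemble(s, frames))
  spread <- apply(al$xyz, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-6)
})

test_that("alignment never increases total positional variance", {
  s <- make_superhelix_duplex(superhelix_params(n_bp = 21))$structure
  ens <- gaussian_ensemble(s, 0.8, 60, seed = 3)
  al <- align_ensemble(ens)
  tv <- function(x) sum(sweep(x$xyz, 2, colMeans(x$xyz))^2)
  expect_lte(tv(al), tv(ens))
})

test_that("RMSF is zero for identical frames and needs two frames", {
  s <- make_superhelix_duplex(superhelix_params(n_bp = 21))$structure
  ens0 <- gaussian_ensemble(s, 0, 5, seed = 1)
  pr <- rmsf_profile(ens0, "P")
  expect_true(all(pr$rmsf == 0))
  expect_true(all(pr$b_factor == 0))
  expect_error(rmsf_profile(gaussian_ensemble(s, 0.1, 1, seed = 1), "P"),
               class = "gyredyn_insufficient_frames")
})

test_that("RMSF recovers the isotropic-noise closed form sqrt(3)*sigma", {
  s <- make_superhelix_duplex(superhelix_params(n_bp = 31))$structure
  ens <- align_ensemble(gaussian_ensemble(s, 0.5, 1500, seed = 21))
  pr <- rmsf_profile(ens, "heavy-mean")
  expect_true(all(abs(pr$rmsf - sqrt(3) * 0.5) / (sqrt(3) * 0.5) < 0.05))
  # B-factor conversion is exact: B = (8 pi^2 / 3) rmsf^2
  expect_identical(pr$b_factor, (8 * pi^2 / 3) * pr$rmsf^2)
  expect_equal((8 * pi^2 / 3) * 1^2, 26.3189, tolerance = 1e-4)
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
  s <- make_superhelix_duplex(superhelix_params(n_bp = 21))$structure
  ens <- gaussian_ensemble(s, 0.4, 80, seed = 5)
  mo <- random_rigid_motion(99)
  moved <- ens
  moved$xyz <- t(apply(ens$xyz, 1, function(v) {
    as.vector(t(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% t(mo$R), 2,
                      mo$t, `+`)))
  }))
  p1 <- rmsf_profile(align_ensemble(ens), "P")
  p2 <- rmsf_profile(align_ensemble(moved), "P")
  expect_lt(max(abs(p1$rmsf - p2$rmsf)), 1e-6)
})

test_that("metric series reproduce per-frame values and imposed periods", {
  sh <- make_superhelix_duplex(superhelix_params(n_bp = 81))
  # static ensemble: constant series equal to the single-structure value
  ens0 <- gaussian_ensemble(sh$structure, 0, 12, seed = 1)
  ser0 <- metric_series(ens0, sh$duplex, "gyre_angle", offset = 30L)
  expect_equal(as.numeric(ser0),
               rep(gyre_angle(sh$duplex, 30L), 12))
  # two-frame ensemble against independently computed frame values
  moved <- open_clamshell(sh, delta_z = 4)
  two <- new_ensemble(sh$structure,
                      rbind(as.vector(t(coords(sh$structure))),
                            as.vector(t(coords(moved$structure)))))
  ser2 <- metric_series(two, sh$duplex, "gyre_distance", offset = 30L)
  expect_equal(as.numeric(ser2),
               c(gyre_distance(sh$duplex, 30L), gyre_distance(moved$duplex, 30L)))
  # sinusoidal clamshell: zero-crossing count of the centred series gives
  # the imposed period
  ens <- clamshell_ensemble(sh, n_frames = 240, seed = 2, amplitude = 4,
                            period = 60)
  ser <- metric_series(ens, sh$duplex, "gyre_distance", offset = 30L)
  centred <- as.numeric(ser) - mean(ser)
  crossings <- sum(diff(sign(centred)) != 0)
  expect_lte(abs(crossings - 2 * 240 / 60), 1)
  # per-frame failures name the frame
  bad <- new_ensemble(sh$structure, rbind(two$xyz, NaN * two$xyz[1, ]))
  expect_error(metric_series(bad, sh$duplex, "gyre_angle", offset = 30L),
               "frame 3", class = "gyredyn_metric_error")
})

test_that("densities normalize and recover Gaussian sample moments", {
  cst <- metric_density(rep(5, 50))
  expect_equal(cst$probability, 1)
  expect_equal(cst$std, 0)
  set.seed(123)
  x <- rnorm(10000, 28, 1)
  d <- metric_density(x, n_bins = 72)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
  expect_lt(abs(d$mean - 28), 0.05)
  expect_lt(abs(d$std - 1), 0.05)
  expect_error(metric_density(1:5), class = "gyredyn_param_error")
})

test_that("density of a Gaussian clamshell series recovers the imposed mean angle", {
  sh <- default_superhelix()
  mu_dz <- 3
  ens <- clamshell_ensemble(sh, n_frames = 400, seed = 8,
                            waveform = "gaussian", mean = mu_dz, sd = 0.5)
  ser <- metric_series(ens, sh$duplex, "gyre_angle")
  d <- metric_density(ser, n_bins = 40)
  # oracle: angle of the statically opened structure at the mean displacement
  target <- gyre_angle(open_clamshell(sh, delta_z = mu_dz)$duplex)
  expect_lt(abs(d$mean - target), 3 * d$std / sqrt(d$n) + 1e-3)
})

test_that("PCA isolates an imposed displacement mode", {
  sh <- make_superhelix_duplex(superhelix_params(n_bp = 41))
  s <- sh$structure
  base <- as.vector(t(coords(s)))
  set.seed(31)
  mode <- rnorm(length(base))
  mode <- mode / sqrt(sum(mode^2))
  amp <- rnorm(400, 0, 3)
  xyz <- matrix(base, 400, length(base), byrow = TRUE) +
    outer(amp, mode) + matrix(rnorm(400 * length(base), 0, 0.01), 400)
  modes <- pca_modes(new_ensemble(s, xyz), selection = NULL)
  expect_gte(modes$eigenvalues[1] / sum(modes$eigenvalues), 0.99)
  expect_gte(abs(sum(modes$vectors[, 1] * mode)), 0.99)
})

test_that("PCA spectra satisfy conservation, orthonormality and sampling bounds", {
  s <- make_ideal_helix(50)
  ens <- gaussian_ensemble(s, 1, 3000, seed = 17)
  modes <- pca_modes(ens, selection = NULL)
  # eigenvalue sum equals the trace of the covariance
  expect_equal(sum(modes$eigenvalues), modes$total_variance,
               tolerance = 1e-10)
  G <- crossprod(modes$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)
  # isotropic noise: spectrum flat within the Marchenko-Pastur edges
  q <- 150 / 3000
  expect_lt(max(modes$eigenvalues), (1 + sqrt(q))^2 * 1.1)
  expect_gt(min(modes$eigenvalues), (1 - sqrt(q))^2 * 0.9)
  expect_error(pca_modes(gaussian_ensemble(s, 1, 1, seed = 1), NULL),
               class = "gyredyn_insufficient_frames")
})

test_that("hinge detection recovers imposed hinges and reports no-hinge", {
  sh <- default_superhelix()
  # symmetric hinges at +/-40
  ens <- hinge_mode_ensemble(sh, -40L, 40L, amplitude_deg = 12,
                             n_frames = 160, seed = 2, jitter_sigma = 0.15)
  hp <- detect_dna_hinges(ens, sh$duplex)
  expect_lte(abs(hp$minus - (-40)), 1)
  expect_lte(abs(hp$plus - 40), 1)
  # fully rigid ensemble: explicit no-hinge on both arms
  rigid <- gaussian_ensemble(sh$structure, 0, 8, seed = 1)
  hr <- detect_dna_hinges(rigid, sh$duplex)
  expect_true(is.na(hr$minus) && is.na(hr$plus))
})

test_that("doubling the arm amplitude quadruples the leading eigenvalue", {
  sh <- make_superhelix_duplex(superhelix_params(n_bp = 147))
  ev1 <- function(amp) {
    ens <- hinge_mode_ensemble(sh, -46L, 60L, amplitude_deg = amp,
                               n_frames = 120, seed = 6, jitter_sigma = 0.05)
    al <- align_ensemble(ens, "name P and resnum -20:20")
    pca_modes(al, "name P", n_modes = 1)$eigenvalues[1]
  }
  r <- ev1(10) / ev1(5)
  expect_gt(r, 4 * 0.8)
  expect_lt(r, 4 * 1.2)
})

test_that("porcupine export round-trips the scaled mode vectors", {
  sh <- make_superhelix_duplex(superhelix_params(n_bp = 21))
  ens <- align_ensemble(gaussian_ensemble(sh$structure, 0.3, 40, seed = 12))
  modes <- pca_modes(ens, "name P")
  fcsv <- withr::local_tempfile(fileext = ".csv")
  fpdb <- withr::local_tempfile(fileext = ".pdb")
  out <- porcupine_export(modes, scale = 5, csv_path = fcsv, pdb_path = fpdb)
  tab <- read.csv(fcsv)
  expect_equal(as.matrix(tab[, c("dx", "dy", "dz")]),
               matrix(modes$vectors[, 1] * 5, ncol = 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(tab$magnitude, sqrt(tab$dx^2 + tab$dy^2 + tab$dz^2))
  # the two written models differ by 2 * scale * mode
  arrows <- read_ensemble(fpdb)
  expect_equal(n_frames(arrows), 2L)
  diffs <- arrows$xyz[2, ] - arrows$xyz[1, ]
  expect_lt(max(abs(diffs - 2 * 5 * modes$vectors[, 1])), 2e-3)
})

test_that("a hand-built unit mode displaces one atom by the scale", {
  s <- make_ideal_helix(5)
  v <- numeric(15)
  v[3] <- 1  # z of atom 1
  modes <- list(eigenvalues = 1, vectors = matrix(v, ncol = 1),
                mean_coords = as.vector(t(coords(s))), atoms = s$atoms,
                total_variance = 1, n_modes = 1L)
  class(modes) <- "mode_set"
  out <- porcupine_export(modes, scale = 5)
  expect_equal(out$table$magnitude, c(5, 0, 0, 0, 0))
  modes$vectors <- matrix(0, 15, 1)
  out0 <- porcupine_export(modes, scale = 7)
  expect_true(all(out0$table$magnitude == 0))
})
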