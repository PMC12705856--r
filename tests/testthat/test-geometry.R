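# direct construction of a tiny duplex-like object for point-geometry cases
toy_duplex <- function(pts) {
  # pts: named list index -> N1 coordinate
  idx <- as.integer(names(pts))
  at <- do.call(rbind, lapply(seq_along(idx), function(k) data.frame(
    elety = c("N1", "C1'", "C1'"),
    resid = c("DA", "DA", "DT"),
    chain = c("I", "I", "J"),
    resno = idx[k],
    x = pts[[k]][1] + c(0, -5, 5), y = pts[[k]][2], z = pts[[k]][3],
    stringsAsFactors = FALSE)))
  s <- new_structure(at)
  pairs <- data.frame(index_from_dyad = idx,
                      chain1 = "I", resnum1 = idx, resname1 = "DA",
                      chain2 = "J", resnum2 = idx, resname2 = "DT",
                      purine_side = "strand1", stringsAsFactors = FALSE)
  gyredyn:::duplex_from_pairs(s, pairs, dyad_position = which(idx == 0L))
}

test_that("gyre angle reproduces hand-computable vertex geometries", {
  collinear <- toy_duplex(list(`-39` = c(-2, 0, 0), `0` = c(0, 0, 0),
                               `39` = c(2, 0, 0)))
  expect_equal(gyre_angle(collinear), 180)
  ortho <- toy_duplex(list(`-39` = c(1, 0, 0), `0` = c(0, 0, 0),
                           `39` = c(0, 1, 0)))
  expect_equal(gyre_angle(ortho), 90)
  # degenerate zero-length arm
  degen <- toy_duplex(list(`-39` = c(0, 0, 0), `0` = c(0, 0, 0),
                           `39` = c(1, 0, 0)))
  expect_error(gyre_angle(degen), class = "gyredyn_degenerate_geometry")
})

test_that("gyre distance is the N1-N1 Euclidean distance", {
  d345 <- toy_duplex(list(`-39` = c(0, 0, 0), `0` = c(1, 1, 1),
                          `39` = c(3, 4, 0)))
  expect_equal(gyre_distance(d345), 5)
})

test_that("gyre metrics equal the parametric oracle on the default superhelix", {
  sh <- default_superhelix()
  expect_equal(gyre_angle(sh$duplex), oracle_gyre_angle(sh), tolerance = 1e-12)
  expect_equal(gyre_distance(sh$duplex), oracle_gyre_distance(sh),
               tolerance = 1e-12)
  m <- gyre_metrics(sh$duplex)
  expect_equal(m$theta_deg, oracle_gyre_angle(sh))
  expect_equal(m$dyad_index, 0L)
  expect_true(m$theta_deg > 0 && m$theta_deg <= 180 && m$distance_A > 0)
})

test_that("strand relabelling leaves the gyre distance unchanged", {
  sh <- make_superhelix_duplex(superhelix_params(n_bp = 81))
  d1 <- gyre_distance(sh$duplex)
  swapped <- sh$duplex
  p <- swapped$pairs
  swapped$pairs <- data.frame(
    index_from_dyad = p$index_from_dyad,
    chain1 = p$chain2, resnum1 = p$resnum2, resname1 = p$resname2,
    chain2 = p$chain1, resnum2 = p$resnum1, resname2 = p$resname1,
    purine_side = ifelse(p$purine_side == "strand1", "strand2", "strand1"),
    stringsAsFactors = FALSE)
  swapped <- gyredyn:::duplex_from_pairs(swapped$structure, swapped$pairs,
                                         swapped$dyad_position)
  expect_equal(gyre_distance(swapped), d1)
})

test_that("translating one gyre changes the distance as the oracle predicts", {
  sh <- default_superhelix()
  moved <- open_clamshell(sh, delta_z = 5)
  expect_equal(gyre_distance(moved$duplex), oracle_gyre_distance(moved),
               tolerance = 1e-12)
  expect_gt(gyre_distance(moved$duplex), gyre_distance(sh$duplex))
})

test_that("base-pair distances honour both addressing modes and both points", {
  sh <- default_superhelix()
  expect_equal(bp_distance(sh$duplex, 17L, 17L), 0)
  # author address equals the dyad-relative address it maps to
  expect_equal(bp_distance(sh$duplex, list(chain = "I", resnum = -36L), 40L),
               bp_distance(sh$duplex, -36L, 40L))
  # N1 vs bp-center modes differ by the oracle-computed reference offset
  p <- sh$duplex$pairs
  n1 <- function(i) oracle_n1(sh, i)
  ctr <- function(i) {
    at <- sh$structure$atoms
    r <- which(p$index_from_dyad == i)
    a <- at[at$chain == p$chain1[r] & at$resno == p$resnum1[r] & at$elety == "C1'", ]
    b <- at[at$chain == p$chain2[r] & at$resno == p$resnum2[r] & at$elety == "C1'", ]
    (c(a$x, a$y, a$z) + c(b$x, b$y, b$z)) / 2
  }
  expect_equal(bp_distance(sh$duplex, -36L, 40L, mode = "N1-purine"),
               sqrt(sum((n1(-36) - n1(40))^2)))
  expect_equal(bp_distance(sh$duplex, -36L, 40L, mode = "bp-center"),
               sqrt(sum((ctr(-36) - ctr(40))^2)))
  expect_error(bp_distance(sh$duplex, 500L, 0L), class = "gyredyn_address_error")
  expect_error(bp_distance(sh$duplex, list(chain = "Q", resnum = 1L), 0L),
               class = "gyredyn_address_error")
})

test_that("toy pair centres 7 A apart give a 7 A bp-center distance", {
  dup <- toy_duplex(list(`0` = c(0, 0, 0), `1` = c(0, 0, 7)))
  expect_equal(bp_distance(dup, 0L, 1L, mode = "bp-center"), 7)
})

test_that("superposition recovers constructed rigid motions", {
  s <- make_ideal_helix(20)
  tf0 <- superpose(s, s)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tf0$rmsd, 0, tolerance = 1e-12)

  R30 <- gyredyn:::rotation_about(c(0, 0, 1), 30)
  moved <- set_coords(s, sweep(coords(s) %*% t(R30), 2, c(1, 2, 3), `+`))
  tf <- superpose(moved, s)
  ang <- acos((sum(diag(tf$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)
  expect_lt(tf$rmsd, 1e-9)
  expect_lt(max(abs(coords(apply_transform(moved, tf)) - coords(s))), 1e-9)
})

test_that("superposition rmsd matches the bio3d fit on noisy data and is minimal", {
  set.seed(42)
  X <- matrix(rnorm(600, sd = 8), ncol = 3)            # 200 atoms
  Y <- X + matrix(rnorm(600, sd = 0.2), ncol = 3)
  motion <- random_rigid_motion(7)
  Ym <- sweep(Y %*% t(motion$R), 2, motion$t, `+`)
  tf <- superpose(Ym, X)
  # independent oracle: bio3d's least-squares fit
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(X)), as.vector(t(Ym))))
  rmsd_oracle <- sqrt(mean(colSums(matrix((as.vector(fitted) -
                                           as.vector(t(X)))^2, nrow = 3))))
  expect_equal(tf$rmsd, rmsd_oracle, tolerance = 1e-6)
  # no rotational perturbation lowers the rmsd
  fitted_xyz <- apply_transform(Ym, tf)
  ctr <- colMeans(fitted_xyz)
  for (k in 1:100) {
    set.seed(k)
    P <- gyredyn:::rotation_about(rnorm(3), runif(1, 0.01, 2))
    pert <- sweep(sweep(fitted_xyz, 2, ctr) %*% t(P), 2, ctr, `+`)
    expect_gte(sqrt(mean(rowSums((pert - X)^2))), tf$rmsd)
  }
})

test_that("superposition rejects mismatched and degenerate selections", {
  s1 <- make_ideal_helix(10)
  s2 <- make_ideal_helix(11)
  expect_error(superpose(s1, s2), class = "gyredyn_topology_error")
  line <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3), ncol = 3, byrow = TRUE)
  expect_error(superpose(line, line), class = "gyredyn_degenerate_geometry")
})

test_that("helix axes are recovered with the N-to-C orientation convention", {
  h <- make_ideal_helix(100)
  ax <- helix_axis(h, c(1, 100))
  expect_equal(ax$n_atoms, 100L)
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-3)
  # reversed residue order flips the reported direction
  rev_h <- h
  rev_h$atoms$resno <- rev(rev_h$atoms$resno)
  ax_rev <- helix_axis(rev_h, c(1, 100))
  expect_lt(max(abs(ax_rev$direction + ax$direction)), 1e-12)
  expect_error(helix_axis(h, c(1, 3)), class = "gyredyn_degenerate_geometry")
})

test_that("bundle rotation recovers imposed rotations and their line-angle fold", {
  same <- make_bundle_pair(0)
  expect_equal(bundle_rotation(same$a, same$anchor, same$probe,
                               same$a, same$anchor, same$probe), 0)
  b46 <- make_bundle_pair(46)
  expect_equal(bundle_rotation(b46$a, b46$anchor, b46$probe,
                               b46$b, b46$anchor, b46$probe), 46,
               tolerance = 1e-9)
  b120 <- make_bundle_pair(120)
  expect_equal(bundle_rotation(b120$a, b120$anchor, b120$probe,
                               b120$b, b120$anchor, b120$probe), 60,
               tolerance = 1e-9)
  # symmetric in its two structures
  expect_equal(bundle_rotation(b46$b, b46$anchor, b46$probe,
                               b46$a, b46$anchor, b46$probe), 46,
               tolerance = 1e-9)
  # signed variant reports the sense about the anchor axis
  signed <- bundle_rotation(b46$a, b46$anchor, b46$probe,
                            b46$b, b46$anchor, b46$probe, signed = TRUE)
  expect_equal(abs(signed), 46, tolerance = 0.1)
})

test_that("hydrogen-bond distances resolve presets and planted fixtures", {
  # two atoms 2.8 A apart
  s <- new_structure(data.frame(
    elety = c("ND1", "OD1"), resid = c("HIS", "ASP"), chain = c("B", "A"),
    resno = c(75L, 85L), x = c(0, 0), y = c(0, 0), z = c(0, 2.8),
    stringsAsFactors = FALSE))
  contacts <- data.frame(chain1 = "B", resnum1 = 75L, atom1 = "ND1",
                         chain2 = "A", resnum2 = 85L, atom2 = "OD1")
  expect_equal(hbond_distances(s, contacts), 2.8)
  expect_identical(hbond_distances(s, contacts[0, ]), numeric(0))
  # preset RDH list on a fixture with planted distances
  fx <- make_rdh_fixture("H4", "A", "B", distances = c(2.6, 2.7, 2.9))
  d <- hbond_distances(fx, rdh_contacts("H4", "A", "B", both_directions = FALSE))
  expect_equal(d, c(2.6, 2.7, 2.9))
  expect_true(all(d >= 2.6 & d <= 2.9))
  expect_error(
    hbond_distances(fx, data.frame(chain1 = "A", resnum1 = 1L, atom1 = "XX",
                                   chain2 = "B", resnum2 = 2L, atom2 = "YY")),
    class = "gyredyn_address_error")
})

test_that("all geometric metrics are rigid-motion invariant", {
  sh <- default_superhelix()
  th0 <- gyre_angle(sh$duplex)
  d0 <- gyre_distance(sh$duplex)
  b0 <- bp_distance(sh$duplex, -36L, 40L)
  fx <- make_rdh_fixture("CENP-A", "A", "B")
  h0 <- hbond_distances(fx, rdh_contacts("CENP-A", "A", "B",
                                         both_directions = FALSE))
  for (seed in 1:10) {
    mo <- random_rigid_motion(seed)
    shm <- sh
    shm$structure <- apply_rigid(sh$structure, mo)
    shm$duplex$structure <- shm$structure
    expect_lt(abs(gyre_angle(shm$duplex) - th0), 1e-9)
    expect_lt(abs(gyre_distance(shm$duplex) - d0), 1e-9)
    expect_lt(abs(bp_distance(shm$duplex, -36L, 40L) - b0), 1e-9)
    expect_lt(max(abs(hbond_distances(apply_rigid(fx, mo),
                                      rdh_contacts("CENP-A", "A", "B",
                                                   both_directions = FALSE)) - h0)),
              1e-9)
  }
})
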