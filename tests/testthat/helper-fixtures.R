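# Shared fixtures and independent oracles.

# Default superhelix, built once per test file.
fixture_env <- new.env(parent = emptyenv())

default_superhelix <- function() {
  if (is.null(fixture_env$sh)) fixture_env$sh <- make_superhelix_duplex()
  fixture_env$sh
}

# Brute-force reference point: purine N1 of pair `index`, located by direct
# data-frame subsetting of the atom table against the ground-truth pairing
# (no package lookup tables, no purine_n1).
oracle_n1 <- function(sh, index) {
  p <- sh$duplex$pairs
  r <- which(p$index_from_dyad == index)
  ch <- if (p$purine_side[r] == "strand1") p$chain1[r] else p$chain2[r]
  rn <- if (p$purine_side[r] == "strand1") p$resnum1[r] else p$resnum2[r]
  at <- sh$structure$atoms
  row <- at[at$chain == ch & at$resno == rn & at$elety == "N1", ]
  stopifnot(nrow(row) == 1L)
  c(row$x, row$y, row$z)
}

# Independent vector-arithmetic oracles (acos form, distinct from the
# package's atan2 implementation).
oracle_gyre_angle <- function(sh, offset = 39L) {
  a <- oracle_n1(sh, -offset)
  b <- oracle_n1(sh, 0L)
  c <- oracle_n1(sh, offset)
  u <- a - b
  w <- c - b
  acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
}

oracle_gyre_distance <- function(sh, offset = 39L) {
  d <- oracle_n1(sh, offset) - oracle_n1(sh, -offset)
  sqrt(sum(d^2))
}

# Random proper rotation (QR with determinant correction) and translation.
random_rigid_motion <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  list(R = Q, t = runif(3L, -50, 50))
}

apply_rigid <- function(structure, motion) {
  set_coords(structure, sweep(coords(structure) %*% t(motion$R), 2L,
                              motion$t, `+`))
}
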