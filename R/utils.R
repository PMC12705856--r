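# Internal helpers shared across modules.

# Signal a classed error so callers (and tests) can dispatch on failure kind
# rather than on message text.
gd_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gyredyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) gd_abort("gyredyn_degenerate_geometry", "zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Interior angle (degrees) at vertex b of the triangle a-b-c. atan2 of the
# cross/dot pair is better conditioned than acos near 0 and 180 degrees.
vertex_angle <- function(a, b, c) {
  u <- a - b
  w <- c - b
  nu <- vnorm(u)
  nw <- vnorm(w)
  if (nu < 1e-9 || nw < 1e-9)
    gd_abort("gyredyn_degenerate_geometry",
             "angle undefined: zero-length arm at the vertex")
  atan2(vnorm(cross3(u, w)), sum(u * w)) * 180 / pi
}

# Rotation matrix for angle `deg` (degrees) about unit axis `axis`
# (Rodrigues form).
rotation_about <- function(axis, deg) {
  k <- unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
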