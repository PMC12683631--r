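# Small 3-vector helpers shared by the detectors and generators.
# All positions are plain numeric length-3 vectors in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vdist <- function(a, b) vnorm(a - b)

## Angle a-b-c at vertex b, in degrees.
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

## Rotation matrix for angle `deg` (degrees) about unit axis `ax`
## (Rodrigues' formula).
rotation_about <- function(ax, deg) {
  ax <- vunit(ax)
  th <- deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## An arbitrary unit vector orthogonal to u.
orthonormal_to <- function(u) {
  u <- vunit(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(ref - sum(ref * u) * u)
}

deg_cos <- function(deg) cos(deg * pi / 180)
deg_sin <- function(deg) sin(deg * pi / 180)
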