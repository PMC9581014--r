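# Low-level vector geometry: torsion angles (IUPAC sign convention),
# internal-coordinate atom placement (NeRF), and Kabsch superposition.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  y <- sum(.cross(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, sum(n1 * n2)) * 180 / pi
}

# Wrap degrees into (-180, 180].
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# Wrap-aware angular difference a - b in (-180, 180].
angle_diff <- function(a, b) wrap_angle(a - b)

# Circular mean of angles in degrees.
.circ_mean <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

# Place atom X given three placed atoms a-b-c such that |c-X| = len,
# angle(b, c, X) = ang (degrees) and torsion(a, b, c, X) = tor (degrees).
.place_atom <- function(a, b, c, len, ang, tor) {
  th <- ang * pi / 180
  ch <- tor * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  d <- c(-len * cos(th), len * sin(th) * cos(ch), len * sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Least-squares rigid superposition (Kabsch): returns the transform that
# moves point set P (n x 3) onto Q. Apply with .kabsch_apply.
.kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

.kabsch_apply <- function(fit, X) {
  sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, fit$cq, "+")
}
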