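# Internal vector geometry. All row-wise helpers act on n x 3 matrices.

.rowv <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
.vnorm <- function(m) sqrt(rowSums(.rowv(m)^2))
.vunit <- function(m) { m <- .rowv(m); m / .vnorm(m) }
.vdot <- function(a, b) rowSums(.rowv(a) * .rowv(b))
.vcross <- function(a, b) {
  a <- .rowv(a); b <- .rowv(b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Signed dihedral angle (degrees, right-hand/IUPAC convention), vectorized
# over rows of the four position matrices.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- .rowv(p2) - .rowv(p1)
  b2 <- .rowv(p3) - .rowv(p2)
  b3 <- .rowv(p4) - .rowv(p3)
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(.vunit(b2), n1)
  atan2(.vdot(m1, n2), .vdot(n1, n2)) * 180 / pi
}

.angle3 <- function(a, b, c) {
  u <- .vunit(.rowv(a) - .rowv(b))
  v <- .vunit(.rowv(c) - .rowv(b))
  acos(pmin(1, pmax(-1, .vdot(u, v)))) * 180 / pi
}

# NeRF placement: position of atom d bonded to c with bond length `bond`,
# angle(b,c,d) and torsion(a,b,c,d) in degrees. Scalar (single triplet).
.place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- as.numeric(.vunit(c - b))
  n <- as.numeric(.vunit(.vcross(b - a, bc)))
  m <- as.numeric(.vcross(n, bc))
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Hydroxyl hydrogen directed toward an acceptor: H lies in the (Cant, O, A)
# plane at `ang` degrees from the O->Cant direction, on the acceptor side.
# Vectorized over rows; used to realize a chosen hydrogen-bond network.
.place_h_toward <- function(O, Cant, A, bond = 0.097, ang = 108) {
  O <- .rowv(O); Cant <- .rowv(Cant); A <- .rowv(A)
  chat <- .vunit(Cant - O)
  avec <- .vunit(A - O)
  d <- avec - .vdot(avec, chat) * chat
  dn <- .vnorm(d)
  # degenerate (acceptor collinear with antecedent): pick any perpendicular
  bad <- dn < 1e-8
  if (any(bad)) {
    alt <- .vcross(chat[bad, , drop = FALSE],
                   matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE))
    alt2 <- .vcross(chat[bad, , drop = FALSE],
                    matrix(rep(c(0, 1, 0), sum(bad)), ncol = 3, byrow = TRUE))
    use2 <- .vnorm(alt) < 1e-8
    alt[use2, ] <- alt2[use2, ]
    d[bad, ] <- alt
    dn[bad] <- .vnorm(alt)
  }
  d <- d / dn
  a <- ang * pi / 180
  O + bond * (cos(a) * chat + sin(a) * d)
}

# Axis-angle rotation matrix (Rodrigues), axis-times-angle parameterization.
.rotmat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.rotz <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Run code with a local RNG state so generators are pure in (params, seed).
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
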