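# Low-level 3D vector helpers shared by the chain model, the survey and the
# synthetic generator. All coordinates are in Angstrom, all angles in degrees
# unless a name says otherwise.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# wrap an angle (deg) into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# smallest signed difference a - b on the circle, in (-180, 180]
angle_diff <- function(a, b) wrap_angle(a - b)

#' Signed dihedral angle defined by four points
#'
#' Returns the torsion angle of the plane (p1, p2, p3) against the plane
#' (p2, p3, p4), using the IUPAC sign convention: looking down the p2 -> p3
#' axis, a clockwise rotation of the far bond is positive. 0 degrees is the
#' eclipsed arrangement, 180 the anti arrangement.
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates in Angstrom.
#' @param labels optional character(4) used in error messages.
#' @return angle in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4, labels = c("p1", "p2", "p3", "p4")) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  # collinearity tolerance: cross-product norm below 1e-8 A^2
  if (vnorm(n1) < 1e-8) {
    stop(sprintf("degenerate geometry: atoms %s, %s, %s are collinear",
                 labels[1L], labels[2L], labels[3L]), call. = FALSE)
  }
  if (vnorm(n2) < 1e-8) {
    stop(sprintf("degenerate geometry: atoms %s, %s, %s are collinear",
                 labels[2L], labels[3L], labels[4L]), call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * (b2 / vnorm(b2)))
  wrap_angle(atan2(y, x) / DEG)
}

#' Bond angle at the middle point
#'
#' @param p1,p2,p3 numeric(3); the angle is measured at p2.
#' @param labels optional character(3) for error messages.
#' @return angle in degrees, in [0, 180].
#' @export
measure_angle <- function(p1, p2, p3, labels = c("p1", "p2", "p3")) {
  a <- p1 - p2
  b <- p3 - p2
  if (vnorm(a) < 1e-8 || vnorm(b) < 1e-8) {
    stop(sprintf("degenerate geometry: coincident atoms among %s, %s, %s",
                 labels[1L], labels[2L], labels[3L]), call. = FALSE)
  }
  # collinear triples (cross-product norm < 1e-8) are declared degenerate:
  # a bridge angle measured on a straight line carries no information
  if (vnorm(vcross(a, b)) < 1e-8) {
    stop(sprintf("degenerate geometry: atoms %s, %s, %s are collinear",
                 labels[1L], labels[2L], labels[3L]), call. = FALSE)
  }
  cosang <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(min(1, max(-1, cosang))) / DEG
}

# NeRF-style placement: position atom D bonded to c with bond length r,
# angle ang = angle(D, c, b) and torsion tor = dihedral(a, b, c, D), degrees.
place_atom <- function(a, b, c, r, ang, tor) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- ang * DEG
  tor <- tor * DEG
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# The two remaining tetrahedral substituent directions at a center with two
# substituent unit vectors b1, b2 already fixed. Both returned directions make
# the angle `ang` (deg) with b1 and with b2; they are placed symmetrically
# about the (b1, b2) plane. Deterministic order: first direction on the
# +cross(b1, b2) side.
tetrahedral_pair <- function(b1, b2, ang = 109.47122) {
  cv <- cos(ang * DEG)
  s <- b1 + b2
  omega <- sum(b1 * b2) # cos of angle between existing substituents
  alpha <- cv / (1 + omega)
  base <- alpha * s
  h2 <- 1 - sum(base * base)
  if (h2 < 0) {
    stop("infeasible tetrahedral placement: existing substituents too close",
         call. = FALSE)
  }
  v <- unitv(vcross(b1, b2))
  list(base + sqrt(h2) * v, base - sqrt(h2) * v)
}

# random rigid transform (rotation + translation), used by property tests
# and by the trajectory writer to avoid frames sitting on top of each other
random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  list(R = rot, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(coords, tf) {
  sweep(coords %*% t(tf$R), 2L, -tf$t)
}

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `target`.
#'
#' @param mobile,target n x 3 matrices with matched rows, n >= 3.
#' @return list with rotation matrix `R`, translation `t` (apply as
#'   `x %*% t(R) + t`), and `rmsd` after superposition.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || nrow(mobile) < 3L) {
    stop("kabsch needs >= 3 paired points", call. = FALSE)
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(target, 2L, ct)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  list(R = rot, t = as.numeric(ct - cm %*% t(rot)), rmsd = rmsd)
}

# Place a point at prescribed distances from anchor points, keeping clear of
# `avoid` points. Closed-form trilateration is used for 3 anchors; 1-2 anchors
# leave rotational freedom which is resolved by maximizing the minimum
# distance to `avoid`. Used to position Mg2+ and monovalent ions in
# synthetic frames and fixtures.
place_at_distances <- function(anchors, dists, avoid = NULL, n_probe = 72L,
                               best_effort = FALSE) {
  anchors <- as.matrix(anchors)
  k <- nrow(anchors)
  stopifnot(k >= 1L, length(dists) == k)
  score <- function(p) {
    if (is.null(avoid) || nrow(avoid) == 0L) return(0)
    min(sqrt(rowSums(sweep(as.matrix(avoid), 2L, p)^2)))
  }
  # vectorized min-distance of every candidate row to the avoid set
  score_all <- function(cand) {
    if (is.null(avoid) || nrow(avoid) == 0L) return(rep(0, nrow(cand)))
    a <- as.matrix(avoid)
    d2 <- outer(rowSums(cand^2), rep(1, nrow(a))) +
      outer(rep(1, nrow(cand)), rowSums(a^2)) - 2 * cand %*% t(a)
    sqrt(pmax(0, apply(d2, 1L, min)))
  }
  if (k == 1L) {
    # sphere: probe directions, keep the farthest from avoid set
    dirs <- probe_directions(n_probe)
    cand <- sweep(dirs * dists[1L], 2L, -anchors[1L, ])
    return(cand[which.max(score_all(cand)), ])
  }
  if (k == 2L) {
    cand <- circle_points(anchors[1L, ], dists[1L], anchors[2L, ],
                          dists[2L], n_probe, best_effort)
    return(cand[which.max(score_all(cand)), ])
  }
  # k >= 3: trilateration on the first three anchors, then pick the solution
  # scoring best against `avoid` (and closest to any remaining anchors)
  p1 <- anchors[1L, ]; p2 <- anchors[2L, ]; p3 <- anchors[3L, ]
  ex <- unitv(p2 - p1)
  i <- sum(ex * (p3 - p1))
  ey <- unitv(p3 - p1 - i * ex)
  ez <- vcross(ex, ey)
  d <- vnorm(p2 - p1)
  j <- sum(ey * (p3 - p1))
  x <- (dists[1L]^2 - dists[2L]^2 + d^2) / (2 * d)
  y <- (dists[1L]^2 - dists[3L]^2 + i^2 + j^2) / (2 * j) - (i / j) * x
  z2 <- dists[1L]^2 - x^2 - y^2
  if (z2 < -1e-9 && !best_effort) {
    stop("infeasible placement: spheres do not intersect", call. = FALSE)
  }
  z <- sqrt(max(0, z2))
  cands <- rbind(p1 + x * ex + y * ey + z * ez,
                 p1 + x * ex + y * ey - z * ez)
  best <- which.max(apply(cands, 1L, score))
  cands[best, ]
}

# points at distance da from a and db from b (the two-sphere intersection
# circle), sampled at n angles; with best_effort, an infeasible pair yields
# the least-squares compromise on the anchor axis
circle_points <- function(a, da, b, db, n = 72L, best_effort = FALSE) {
  ab <- b - a; dab <- vnorm(ab); u <- ab / dab
  x <- (dab^2 + da^2 - db^2) / (2 * dab)
  r2 <- da^2 - x^2
  if (r2 < 0) {
    if (!best_effort) {
      stop("infeasible placement: spheres do not intersect", call. = FALSE)
    }
    return(matrix(a + u * dab * da / (da + db), nrow = 1L))
  }
  centre <- a + x * u
  e1 <- unitv(orthogonal_to(u))
  e2 <- vcross(u, e1)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- sqrt(r2)
  sweep(outer(cos(th), r * e1) + outer(sin(th), r * e2), 2L, -centre)
}

orthogonal_to <- function(u) {
  v <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v - sum(v * u) * u
}

# deterministic quasi-uniform directions on the unit sphere (Fibonacci lattice)
probe_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
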