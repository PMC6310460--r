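# Chain representation, dihedral/angle primitives, embedding round trips.

test_that("dihedral angle reproduces eclipsed, anti and rotated arrangements", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(measure_dihedral(p1, p2, p3, c(1, 0, 0)), 0)
  expect_equal(measure_dihedral(p1, p2, p3, c(-1, 0, 0)), 180)
  # rotation-matrix oracle: rotate the eclipsed p4 about the p2->p3 axis by
  # a known angle and expect exactly that dihedral back
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  rodrigues <- function(v, k, th) {
    th <- th * pi / 180
    v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                    k[3] * v[1] - k[1] * v[3],
                    k[1] * v[2] - k[2] * v[1]) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  for (th in c(-90, -60, -30, 30, 60, 90)) {
    p4 <- rodrigues(c(1, 0, 0), axis, th)
    expect_equal(measure_dihedral(p1, p2, p3, p4), th, tolerance = 1e-10)
  }
})

test_that("dihedral flips sign under reflection and errors on collinearity", {
  set.seed(101)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(12), 4, 3)
    d1 <- measure_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    refl <- pts
    refl[, 3] <- -refl[, 3] # mirror through the xy plane
    d2 <- measure_dihedral(refl[1, ], refl[2, ], refl[3, ], refl[4, ])
    if (abs(abs(d1) - 180) > 1e-6) {
      expect_equal(d2, -d1, tolerance = 1e-9)
    }
  }
  expect_error(
    measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0),
                     labels = c("PA", "O3A", "PB", "O3B")),
    "PA.*collinear")
})

test_that("phosphate_chain validates completeness and bond plausibility", {
  ch <- embed_chain(chain_spec(5.0, 125))
  expect_true(ch$complete)
  expect_length(ch$flags, 0)
  # re-validate with checking on
  ch2 <- phosphate_chain(ch$coords, check = TRUE)
  expect_length(ch2$flags, 0)
  # stretch one bond beyond plausibility -> flagged, not dropped
  bad <- ch$coords
  bad["O1G", ] <- bad["PG", ] + (bad["O1G", ] - bad["PG", ]) * 2
  flagged <- phosphate_chain(bad, check = TRUE)
  expect_match(flagged$flags, "PG-O1G", all = FALSE)
  # incomplete chain: descriptor computation names the missing atoms
  inc <- phosphate_chain(ch$coords[setdiff(rownames(ch$coords),
                                           c("O3G", "PG")), ])
  expect_false(inc$complete)
  expect_error(compute_descriptors(inc), "missing.*PG")
})

test_that("descriptors are invariant under rigid motion", {
  set.seed(7)
  ch <- embed_chain(chain_spec(4.8, 130))
  d0 <- compute_descriptors(ch)
  for (i in 1:25) {
    tf <- triphos:::random_rigid_transform()
    moved <- phosphate_chain(triphos:::apply_rigid(ch$coords, tf),
                             check = FALSE)
    d1 <- compute_descriptors(moved)
    expect_equal(d1$d_PA_PG, d0$d_PA_PG, tolerance = 1e-9)
    expect_equal(d1$theta_bridge, d0$theta_bridge, tolerance = 1e-9)
    expect_equal(d1$psi_ab, d0$psi_ab, tolerance = 1e-9)
    expect_equal(d1$psi_bg, d0$psi_bg, tolerance = 1e-9)
    expect_equal(d1$psi_ag, d0$psi_ag, tolerance = 1e-9)
  }
})

test_that("embed/measure round trip reproduces targeted descriptors", {
  set.seed(11)
  for (i in 1:40) {
    sp <- random_chain_spec()
    ch <- embed_chain(sp)
    de <- compute_descriptors(ch)
    expect_equal(de$d_PA_PG, sp$d_PA_PG, tolerance = 1e-6)
    expect_equal(de$theta_bridge, sp$theta_bridge, tolerance = 1e-6)
    expect_lt(abs(triphos:::angle_diff(de$psi_ab, sp$psi_ab)), 1e-6)
    expect_lt(abs(triphos:::angle_diff(de$psi_bg, sp$psi_bg)), 1e-6)
    expect_lt(abs(triphos:::angle_diff(de$psi_ag, sp$psi_ag)), 1e-6)
  }
})

test_that("distance-only embedding hits the requested distance", {
  for (d in c(4.3, 4.91, 5.4)) {
    ch <- embed_chain(chain_spec(d, 122))
    expect_equal(compute_descriptors(ch)$d_PA_PG, d, tolerance = 1e-6)
  }
})

test_that("two embeddings of one spec differ only by a rigid transform", {
  sp <- chain_spec(5.1, 128, psi_ab = 40, psi_bg = 15, psi_ag = 55)
  a <- embed_chain(sp)$coords
  set.seed(3)
  tf <- triphos:::random_rigid_transform()
  b <- triphos:::apply_rigid(embed_chain(sp)$coords, tf)
  fit <- kabsch(b[rownames(a), ], a)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("infeasible specs raise an infeasible-geometry error", {
  # beyond the fully extended chain
  expect_error(embed_chain(chain_spec(9.5, 130)), "infeasible")
  # unreachable dihedral combination at a short distance
  expect_error(embed_chain(chain_spec(5.75, 112, psi_ab = 0, psi_bg = 0,
                                      psi_ag = 90)),
               "infeasible")
})

test_that("collinear bridge angle is a degenerate-geometry error", {
  ch <- embed_chain(chain_spec(5.0, 125))
  co <- ch$coords
  # put PB on the O3B->PG axis
  co["PB", ] <- co["O3B", ] + (co["O3B", ] - co["PG", ])
  expect_error(compute_descriptors(phosphate_chain(co, check = FALSE)),
               "collinear")
})
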