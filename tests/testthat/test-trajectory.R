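# Mg coordination classification, ion site assignment, occupancy,
# segmentation, moving averages, pair tracking.

test_that("Mg coordination modes classify by oxygen proximity", {
  bg <- chain_with_mg(mode = "bg")
  expect_equal(classify_mg_coordination(bg), "BETA_GAMMA")
  abg <- chain_with_mg(d = 4.3, theta = 128, mode = "abg")
  # tridentate placement on a generic embedding may exceed the cutoff;
  # build it from the generator instead for a guaranteed tridentate frame
  tr <- generate_trajectory(trajectory_config(
    segments = list(segment_plan("ALPHA_BETA_GAMMA", 12L, cation = "K")),
    seed = 5))
  expect_true(all(vapply(tr$frames, classify_mg_coordination,
                         character(1)) == "ALPHA_BETA_GAMMA"))
  far <- chain_with_mg(mode = "none")
  expect_equal(classify_mg_coordination(far), "OTHER")
  no_mg <- embed_chain(chain_spec(5, 122))
  expect_error(classify_mg_coordination(no_mg), "missing ion")
})

test_that("ion site assignment follows the binding-distance rules", {
  ch <- embed_chain(chain_spec(4.9, 122))
  co <- ch$coords
  put <- function(anchors, dists, avoid = co[c("O1A", "O2A"), ]) {
    triphos:::place_at_distances(co[anchors, , drop = FALSE], dists,
                                 avoid = avoid, best_effort = TRUE)
  }
  k_bg <- put(c("O2B", "O1G"), c(2.6, 2.6))
  g_only <- co["O3G", ] + 3.0 *
    triphos:::unitv(co["O3G", ] - colMeans(co[c("PA", "PB"), ]))
  far <- colMeans(co) + c(0, 0, 12)
  ions <- data.frame(id = c("K1", "K2", "K3"), species = "K",
                     x = c(k_bg[1], g_only[1], far[1]),
                     y = c(k_bg[2], g_only[2], far[2]),
                     z = c(k_bg[3], g_only[3], far[3]))
  rec <- assign_ion_sites(ch, ions, frame = 1L)
  expect_equal(rec$site, c("BG", "G", "unbound"))
  expect_true(all(rec$r_A >= 0 & rec$r_B >= 0 & rec$r_G >= 0))
  expect_equal(rec$R_BG[1], (rec$r_B[1] + rec$r_G[1]) / 2)
  # unbound implies beyond the species binding distance everywhere
  expect_gt(min(rec$r_A[3], rec$r_B[3], rec$r_G[3]), 3.2)
  # unknown species is a configuration error
  expect_error(assign_ion_sites(ch, data.frame(id = "X", species = "Cs",
                                               x = 0, y = 0, z = 0)),
               "no binding distance")
})

test_that("Na+ in the AG position assigns AG with the shorter R", {
  tr <- generate_trajectory(trajectory_config(
    segments = list(segment_plan("BETA_GAMMA_CURLED", 60L, cation = "Na")),
    ions = list(ion_plan("Na", "AG", bound_fraction = 1)),
    seed = 9))
  recs <- do.call(rbind, lapply(seq_along(tr$frames), function(t)
    assign_ion_sites(tr$frames[[t]], tr$ions[[t]], frame = t)))
  bound <- tr$truth$bound[, 1]
  expect_equal(recs$site == "AG", bound)
  expect_true(all(recs$R_AG[recs$site == "AG"] < 2.5))
})

test_that("site assignment agrees with the brute-force distance enumerator", {
  tr <- generate_trajectory(trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 25L, cation = "K"),
                    segment_plan("ALPHA_BETA_GAMMA", 25L, cation = "K")),
    ions = list(ion_plan("K", "BG", 0.7), ion_plan("K", "AG", 0.4),
                ion_plan("K", "G", 0.5)),
    seed = 13))
  for (t in seq_along(tr$frames)) {
    rec <- assign_ion_sites(tr$frames[[t]], tr$ions[[t]], frame = t)
    for (i in seq_len(nrow(rec))) {
      pos <- as.numeric(tr$ions[[t]][i, c("x", "y", "z")])
      expect_identical(rec$site[i],
                       brute_force_site(tr$frames[[t]], pos, 3.2))
    }
  }
})

test_that("assignments are stable under ion reordering and rigid motion", {
  tr <- small_test_trajectory()
  ch <- tr$frames[[5]]
  ions <- rbind(tr$ions[[5]],
                data.frame(id = "K9", species = "K", x = 20, y = 0, z = 0))
  a <- assign_ion_sites(ch, ions)
  b <- assign_ion_sites(ch, ions[rev(seq_len(nrow(ions))), ])
  expect_equal(a$site, rev(b$site))
  tf <- triphos:::random_rigid_transform()
  co2 <- triphos:::apply_rigid(ch$coords, tf)
  ion_xyz <- triphos:::apply_rigid(as.matrix(ions[, c("x", "y", "z")]), tf)
  ions2 <- ions
  ions2[, c("x", "y", "z")] <- ion_xyz
  c_ <- assign_ion_sites(phosphate_chain(co2, check = FALSE), ions2)
  expect_equal(c_$site, a$site)
  expect_equal(c_$r_G, a$r_G, tolerance = 1e-9)
})

test_that("occupancy is the mean per-frame count", {
  expect_equal(occupancy(c(1, 1, 0, 1))$occupancy, 0.75)
  expect_equal(occupancy(c(0, 0, 0))$occupancy, 0)
  expect_error(occupancy(numeric(0)), "empty")
})

test_that("segment_trajectory merges short runs into the longer flank", {
  s <- segment_trajectory(strsplit("AAABBBAAA", "")[[1]], min_dwell = 2)
  expect_equal(nrow(s), 3L)
  expect_equal(s$state, c("A", "B", "A"))
  s2 <- segment_trajectory(strsplit("AAABAAA", "")[[1]], min_dwell = 2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$length, 7L)
  # tie between flanks goes to the preceding segment
  s3 <- segment_trajectory(strsplit("AABCC", "")[[1]], min_dwell = 2)
  expect_equal(s3$state, c("A", "C"))
  expect_equal(s3$length, c(3L, 2L))
  # segments partition the series
  expect_equal(sum(s3$length), 5L)
})

test_that("segmentation recovers generator switch times exactly", {
  tr <- generate_trajectory(trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 50L, cation = "K"),
                    segment_plan("ALPHA_BETA_GAMMA", 60L, cation = "K"),
                    segment_plan("BETA_GAMMA", 40L, cation = "K")),
    seed = 21))
  an <- analyze_frames(tr$frames)
  segs <- segment_trajectory(an$states, min_dwell = 10)
  expect_equal(segs$start, tr$truth$segment_start)
  expect_equal(segs$end, tr$truth$segment_end)
})

test_that("detect_curled relabels below the threshold with a strict rule", {
  segs <- data.frame(start = c(1L, 101L), end = c(100L, 200L),
                     state = "BETA_GAMMA", length = 100L)
  # segment means: the NH4+ curled regime (4.56) and the no-cation regime
  d <- c(rep(4.56, 100), rep(5.46, 100))
  out <- detect_curled(segs, d)
  expect_equal(out$state, c("BETA_GAMMA_CURLED", "BETA_GAMMA"))
  # exactly at the threshold stays plain beta-gamma
  tied <- detect_curled(data.frame(start = 1L, end = 10L,
                                   state = "BETA_GAMMA", length = 10L),
                        rep(4.65, 10))
  expect_equal(tied$state, "BETA_GAMMA")
})

test_that("moving_average shrinks at edges and preserves constants", {
  expect_equal(moving_average(rep(3, 10), window = 5), rep(3, 10))
  x <- c(0, 0, 6, 0, 0)
  expect_equal(moving_average(x, window = 3), c(0, 2, 2, 2, 0))
  expect_equal(moving_average(x, window = 1), x)
  # window in time units with known spacing
  expect_equal(moving_average(x, window = 150, dt = 50), c(0, 2, 2, 2, 0))
  expect_error(moving_average(x, window = 10, dt = 50), "window")
})

test_that("track_pair_distance reports per-frame distances and H-bond stats", {
  tr <- small_test_trajectory()
  pd <- track_pair_distance(tr$frames, "PA", "PG")
  expect_equal(length(pd$dist), length(tr$frames))
  expect_equal(pd$dist, tr$truth$d, tolerance = 1e-6)
  same <- track_pair_distance(tr$frames, "PA", "PA")
  expect_equal(same$mean, 0)
  expect_error(track_pair_distance(tr$frames, "PA", "XX"),
               "XX missing in frame 1")
  # fixed-distance fixture
  fr <- list(list(coords = rbind(A = c(0, 0, 0), B = c(4.7, 0, 0))),
             list(coords = rbind(A = c(1, 1, 1), B = c(1, 1, 5.7))))
  pd2 <- track_pair_distance(fr, "A", "B")
  expect_equal(pd2$mean, 4.7)
  expect_equal(pd2$sd, 0)
  expect_equal(pd2$hbond_fraction, 0)
})

test_that("ions_near_chain counts within the proximity radius", {
  ch <- embed_chain(chain_spec(5, 122))
  near <- ch$coords["O1G", ] + c(0, 0, 2)
  far <- colMeans(ch$coords) + c(0, 0, 15)
  ions <- data.frame(id = c("a", "b"), species = "K",
                     x = c(near[1], far[1]), y = c(near[2], far[2]),
                     z = c(near[3], far[3]))
  expect_equal(ions_near_chain(ch, ions, radius = 4), 1L)
  expect_equal(ions_near_chain(ch, ions[0, ], radius = 4), 0L)
})
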