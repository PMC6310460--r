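# Generator determinism, configuration validation, ground-truth recovery,
# file round trips.

test_that("generation is deterministic given the seed", {
  tc <- trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 30L, cation = "K")),
    ions = list(ion_plan("K", "BG", bound_fraction = 0.5)),
    seed = 77)
  a <- generate_trajectory(tc)
  b <- generate_trajectory(tc)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ions, b$ions)
  expect_identical(a$truth, b$truth)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.pdb"); p2 <- file.path(dir, "b.pdb")
  write_trajectory_pdb(a, p1)
  write_trajectory_pdb(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("invalid configurations are rejected", {
  expect_error(ion_plan("K", "BG", bound_fraction = 1.2), "bound_fraction")
  expect_error(segment_plan("BETA_GAMMA", 0), "frames > 0")
  expect_error(trajectory_config(list(segment_plan("BETA_GAMMA", 10)),
                                 phi = 1), "phi")
  expect_error(segment_plan("BETA_GAMMA_CURLED", 10, cation = "K"),
               "no reference statistics")
})

test_that("a zero-SD single-segment config gives identical frames", {
  tc <- trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 8L, cation = "K",
                                 d_sd = 0, theta_sd = 0)),
    seed = 2)
  tr <- generate_trajectory(tc)
  expect_equal(tr$truth$d, rep(4.91, 8), tolerance = 1e-5)
  expect_equal(tr$truth$theta, rep(122.0, 8))
  d <- vapply(tr$frames, function(f)
    compute_descriptors(f)$d_PA_PG, numeric(1))
  expect_equal(d, rep(4.91, 8), tolerance = 1e-6)
})

test_that("trajectory PDB files round-trip through the reader", {
  tr <- small_test_trajectory()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "traj.pdb")
  write_trajectory_pdb(tr, p)
  expect_true(file.exists(paste0(p, ".json")))
  back <- read_trajectory_pdb(p)
  expect_length(back$frames, length(tr$frames))
  for (t in c(1L, 20L, length(tr$frames))) {
    a <- tr$frames[[t]]$coords
    b <- back$frames[[t]]$coords[rownames(a), ]
    expect_equal(unname(b), unname(a), tolerance = 1e-3) # PDB: 3 decimals
    expect_equal(back$ions[[t]]$species, tr$ions[[t]]$species)
  }
  # re-analysis of the file matches the in-memory analysis
  an_mem <- analyze_frames(tr$frames)
  an_file <- analyze_frames(back$frames)
  expect_equal(an_file$states, an_mem$states)
})

test_that("the generator recovers its own ground truth", {
  tc <- trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 150L, cation = "NH4",
                                 d_mean = 4.85, d_sd = 0.22),
                    segment_plan("ALPHA_BETA_GAMMA", 150L, cation = "NH4")),
    ions = list(ion_plan("NH4", "BG", bound_fraction = 0.72)),
    seed = 31)
  tr <- generate_trajectory(tc)
  an <- analyze_frames(tr$frames)
  segs <- segment_trajectory(an$states, min_dwell = 10)
  expect_equal(segs$start, tr$truth$segment_start)
  # segment means within 2 standard errors (AR(1)-corrected)
  phi <- tr$truth$phi
  for (i in 1:2) {
    idx <- segs$start[i]:segs$end[i]
    m <- mean(an$descriptors$d_PA_PG[idx])
    se <- stats::sd(an$descriptors$d_PA_PG[idx]) / sqrt(length(idx)) *
      sqrt((1 + phi) / (1 - phi))
    truth_mean <- c(4.85, 4.22)[i]
    expect_lt(abs(m - truth_mean), 2 * se + 1e-8)
  }
  # occupancy within 0.02 of the realized truth
  recs <- do.call(rbind, lapply(seq_along(tr$frames), function(t)
    assign_ion_sites(tr$frames[[t]], tr$ions[[t]], frame = t)))
  occ <- occupancy(recs, "BG", frames = seq_along(tr$frames))$occupancy
  expect_lt(abs(occ - mean(tr$truth$bound[, 1])), 0.02 + 1e-9)
})

test_that("an impossible descriptor plan is a configuration error", {
  tc <- trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 50L, cation = "K",
                                 d_mean = 6.4, d_sd = 0.05)),
    seed = 1)
  expect_error(generate_trajectory(tc), "config error")
})

test_that("fixture files satisfy their own specs on re-measurement", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fx.pdb")
  out <- generate_fixture_structure(
    fixture_spec("ATP", chain_spec(5.2, 130),
                 cation = list(species = "K", dist_alpha = 2.9,
                               dist_gamma = 2.7)), p)
  at <- attr(out, "atoms")
  # placements respect their stated distances after embedding
  nz <- as.numeric(at[at$atom == "NZ", c("x", "y", "z")])
  o1b <- as.numeric(at[at$atom == "O1B", c("x", "y", "z")])
  expect_equal(sqrt(sum((nz - o1b)^2)), 2.8, tolerance = 1e-6)
  rec <- measure_structure(screen_structure(p)$candidates[[1]])
  expect_equal(rec$descriptors$d_PA_PG, 5.2, tolerance = 1e-3)
  expect_equal(rec$occupant$dist_alpha, 2.9, tolerance = 1e-3)
})
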