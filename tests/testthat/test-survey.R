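# Structure readers, ligand atlas, screening, measurement, superposition.

test_that("the ligand atlas maps every supported chemical ID consistently", {
  atlas <- ligand_atlas()
  ntp <- c("ATP", "GTP", "ANP", "GNP", "ACP", "GCP", "AGS", "ASP", "GSP")
  for (lig in ntp) {
    m <- atlas[atlas$ligand == lig, ]
    expect_setequal(m$label, c("PA", "PB", "PG", "O1A", "O2A", "O3A",
                               "O1B", "O2B", "O3B", "O1G", "O2G", "O3G",
                               "O5'"))
  }
  # substitutions land on the slot they replace and are flagged
  expect_true(atlas$mimic[atlas$ligand == "ANP" & atlas$atom == "N3B"])
  expect_equal(atlas$label[atlas$ligand == "ANP" & atlas$atom == "N3B"], "O3B")
  expect_equal(atlas$label[atlas$ligand == "GSP" & atlas$atom == "S1G"], "O1G")
  expect_equal(atlas$label[atlas$ligand == "ACP" & atlas$atom == "C3B"], "O3B")
  # products lack the gamma group
  expect_false("PG" %in% atlas$label[atlas$ligand == "GDP"])
})

test_that("the PDB reader round-trips generated fixtures", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "atp.pdb")
  fs <- fixture_spec("ATP", chain_spec(5.0, 125),
                     cation = list(species = "K", dist_alpha = 2.8,
                                   dist_gamma = 2.7))
  generate_fixture_structure(fs, p)
  df <- read_structure(p)
  expect_true(all(c("PA", "PB", "PG", "O3B") %in% df$atom))
  expect_true("MG" %in% df$resname)
  expect_true(any(df$resname == "LYS" & df$atom == "NZ"))
  pa <- df[df$atom == "PA", ]
  expect_equal(nrow(pa), 1L)
  expect_error(read_structure(file.path(dir, "nope.pdb")), "not found")
})

test_that("the mmCIF reader parses atoms and resolves altlocs", {
  df <- read_structure(test_path("mini_atoms.cif"))
  # highest-occupancy altloc wins
  cb <- df[df$atom == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$altloc, "B")
  expect_true("O5'" %in% df$atom)
  expect_equal(df$resname[df$atom == "MG"], "MG")
  expect_equal(sum(df$record == "HETATM"), 3L)
})

test_that("screening applies the Mg and Lys criteria with logged reasons", {
  dir <- withr::local_tempdir()
  # all criteria met
  ok <- file.path(dir, "ok.pdb")
  generate_fixture_structure(
    fixture_spec("ATP", chain_spec(5.0, 125)), ok)
  scr <- screen_structure(ok)
  expect_length(scr$candidates, 1L)
  expect_equal(nrow(scr$exclusions), 0L)
  # no Mg
  nomg <- file.path(dir, "nomg.pdb")
  generate_fixture_structure(
    fixture_spec("ATP", chain_spec(5.0, 125), mg = FALSE), nomg)
  scr2 <- screen_structure(nomg)
  expect_length(scr2$candidates, 0L)
  expect_match(scr2$exclusions$reason, "no Mg")
  # no Lys nearby
  nolys <- file.path(dir, "nolys.pdb")
  generate_fixture_structure(
    fixture_spec("ATP", chain_spec(5.0, 125), lys_nz_dist = NA), nolys)
  scr3 <- screen_structure(nolys)
  expect_length(scr3$candidates, 0L)
  expect_match(scr3$exclusions$reason, "no Lys")
  # NDP without gamma mimic
  gdp <- file.path(dir, "gdp.pdb")
  generate_fixture_structure(
    fixture_spec("GDP", chain_spec(5.0, 125)), gdp)
  scr4 <- screen_structure(gdp)
  expect_length(scr4$candidates, 0L)
  expect_match(scr4$exclusions$reason, "without gamma")
  # every excluded instance carries exactly one reason
  expect_equal(nrow(scr4$exclusions), 1L)
  # screening is idempotent
  scr_again <- screen_structure(ok)
  expect_equal(length(scr_again$candidates), 1L)
  expect_identical(scr_again$candidates[[1]]$coords,
                   scr$candidates[[1]]$coords)
})

test_that("transition-state fixtures classify and measure with mimic proxies", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ts.pdb")
  generate_fixture_structure(
    fixture_spec("GDP", chain_spec(5.4, 136.3), moiety = "ALF",
                 cation = list(species = "K", dist_alpha = 2.8,
                               dist_gamma = 2.6)), p)
  scr <- screen_structure(p)
  expect_length(scr$candidates, 1L)
  expect_equal(scr$candidates[[1]]$class, "transition_state")
  rec <- measure_structure(scr$candidates[[1]])
  expect_equal(rec$descriptors$d_PA_PG, 5.4, tolerance = 1e-3)
  expect_equal(rec$descriptors$theta_bridge, 136.3, tolerance = 0.05)
  expect_true(rec$descriptors$mimic)
  expect_equal(rec$occupant$species, "K")
  expect_equal(rec$occupant$dist_alpha, 2.8, tolerance = 1e-3)
  expect_equal(rec$occupant$dist_gamma, 2.6, tolerance = 1e-3)
  expect_true(rec$lys_contact)
})

test_that("a water in the AG position is reported as the occupant", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "era.pdb")
  generate_fixture_structure(
    fixture_spec("GNP", chain_spec(5.1, 129.2), water = TRUE), p)
  rec <- measure_structure(screen_structure(p)$candidates[[1]])
  expect_equal(rec$occupant$species, "water")
  expect_lt(rec$occupant$dist_gamma, 3.5)
})

test_that("survey_table mirrors the record fields", {
  dir <- withr::local_tempdir()
  paths <- table3_standins(dir)
  recs <- lapply(paths, function(p)
    measure_structure(screen_structure(p)$candidates[[1]]))
  tab <- survey_table(recs)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$ag_occupant, c("K", "Na"))
  expect_true(all(c("d_PA_PG", "theta_bridge", "dist_alpha", "dist_gamma",
                    "class") %in% names(tab)))
})

test_that("P-loop superposition is exact for rigid copies and matches a grid oracle", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ref.pdb")
  generate_fixture_structure(fixture_spec("ATP", chain_spec(5.0, 125)), p)
  ref <- read_structure(p)
  fit0 <- superpose_ploops(ref, ref, 25, 25)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  # randomly rotated copy: RMSD below 1e-6
  set.seed(4)
  tf <- triphos:::random_rigid_transform()
  mob <- ref
  mob[, c("x", "y", "z")] <-
    triphos:::apply_rigid(as.matrix(ref[, c("x", "y", "z")]), tf)
  fit1 <- superpose_ploops(mob, ref, 25, 25)
  expect_lt(fit1$rmsd, 1e-6)
  expect_error(superpose_ploops(ref, ref, 99, 99), "fewer than 3")
  # brute-force rotation-grid oracle on 4 points
  set.seed(8)
  a <- matrix(stats::rnorm(12), 4, 3)
  b <- a %*% t(tf$R) + matrix(stats::rnorm(12, sd = 0.1), 4, 3)
  opt <- kabsch(a, b)
  rot_rmsd <- function(angles) {
    cx <- cos(angles[1]); sx <- sin(angles[1])
    cy <- cos(angles[2]); sy <- sin(angles[2])
    cz <- cos(angles[3]); sz <- sin(angles[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    r <- rz %*% ry %*% rx
    am <- sweep(a, 2, colMeans(a)); bm <- sweep(b, 2, colMeans(b))
    sqrt(mean(rowSums((am %*% t(r) - bm)^2)))
  }
  grid <- as.matrix(expand.grid(seq(-pi, pi, length.out = 13),
                                seq(-pi / 2, pi / 2, length.out = 7),
                                seq(-pi, pi, length.out = 13)))
  vals <- apply(grid, 1, rot_rmsd)
  refine <- stats::optim(grid[which.min(vals), ], rot_rmsd,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(opt$rmsd, refine$value, tolerance = 1e-4)
})

test_that("collect_overlay_sets splits records by analog class", {
  expect_length(collect_overlay_sets(list()), 0L)
  dir <- withr::local_tempdir()
  paths <- table3_standins(dir)
  recs <- lapply(paths, function(p)
    measure_structure(screen_structure(p)$candidates[[1]]))
  ov <- collect_overlay_sets(recs)
  expect_setequal(names(ov), c("transition_state", "non_hydrolyzable"))
  expect_equal(nrow(ov$transition_state), 2L)
  expect_true(any(abs(ov$transition_state$d - 5.4) < 0.01 &
                    abs(ov$transition_state$theta - 136.3) < 0.1))
  expect_true(any(abs(ov$non_hydrolyzable$d - 5.1) < 0.01 &
                    abs(ov$non_hydrolyzable$theta - 124.5) < 0.1))
})
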