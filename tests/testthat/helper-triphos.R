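# Shared helpers: random feasible chain specs via the forward torsion map,
# brute-force oracles, and small fixture builders. Everything is generated
# in code; no binary fixtures.

# random feasible spec: sample torsions, embed, measure -> descriptors
random_chain_spec <- function() {
  base <- chain_spec(5, 120)
  co <- triphos:::embed_internal(stats::runif(1, 108, 155),
                                 stats::runif(1, -180, 180),
                                 stats::runif(1, -180, 180),
                                 stats::runif(1, -180, 180),
                                 stats::runif(1, -180, 180), base)
  de <- compute_descriptors(phosphate_chain(co, check = FALSE))
  chain_spec(de$d_PA_PG, de$theta_bridge, de$psi_ab, de$psi_bg, de$psi_ag)
}

# a complete chain with Mg placed for a given coordination mode
chain_with_mg <- function(d = 4.9, theta = 122, mode = c("bg", "abg", "none"),
                          mg_dist = 2.0) {
  mode <- match.arg(mode)
  ch <- embed_chain(chain_spec(d, theta))
  co <- ch$coords
  mg <- switch(mode,
    bg = triphos:::place_at_distances(co[c("O1B", "O2G"), ],
                                      rep(mg_dist, 2L),
                                      avoid = co[c("O1A", "O2A"), ],
                                      best_effort = TRUE),
    abg = triphos:::place_mg_tridentate(co, mg_dist),
    none = colMeans(co) + c(0, 0, 9))
  phosphate_chain(rbind(co, Mg = mg), check = FALSE)
}

# brute-force site assignment by exhaustive distance enumeration, written
# independently of assign_ion_sites
brute_force_site <- function(chain, pos, bd) {
  co <- chain$coords
  dist_to <- function(labels) {
    labels <- intersect(labels, rownames(co))
    min(vapply(labels, function(l) sqrt(sum((co[l, ] - pos)^2)), numeric(1)))
  }
  rA <- dist_to(c("O5'", "O1A", "O2A", "O3A"))
  rB <- dist_to(c("O3A", "O1B", "O2B", "O3B"))
  rG <- dist_to(c("O3B", "O1G", "O2G", "O3G"))
  in_ag <- rA <= bd && rG <= bd
  in_bg <- rB <= bd && rG <= bd
  if (in_ag && in_bg) {
    if ((rA + rG) / 2 < (rB + rG) / 2) "AG" else "BG"
  } else if (in_bg) "BG" else if (in_ag) "AG"
  else if (rG <= bd) "G" else "unbound"
}

# small deterministic trajectory used by several tests
small_test_trajectory <- function(seed = 42L) {
  generate_trajectory(trajectory_config(
    segments = list(segment_plan("BETA_GAMMA", 40L, cation = "K"),
                    segment_plan("ALPHA_BETA_GAMMA", 40L, cation = "K")),
    ions = list(ion_plan("K", "BG", bound_fraction = 0.8)),
    seed = seed))
}

table3_standins <- function(dir) {
  specs <- list(
    `2gj8` = fixture_spec("GDP", chain_spec(5.4, 136.3), moiety = "ALF",
                          cation = list(species = "K", dist_alpha = 2.8,
                                        dist_gamma = 2.6)),
    `2x2e` = fixture_spec("GDP", chain_spec(5.3, 131.2), moiety = "ALF",
                          cation = list(species = "NA", dist_alpha = 4.0,
                                        dist_gamma = 2.5)),
    `3ew9` = fixture_spec("ANP", chain_spec(5.1, 124.5),
                          cation = list(species = "K", dist_alpha = 6.2,
                                        dist_gamma = 3.3)))
  paths <- character(0)
  for (nm in names(specs)) {
    p <- file.path(dir, paste0(nm, "_synthetic.pdb"))
    generate_fixture_structure(specs[[nm]], p)
    paths[nm] <- p
  }
  paths
}
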