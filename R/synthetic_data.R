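# Synthetic trajectories and fixture structures with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# per-segment Gaussian descriptor fluctuations with AR(1) persistence,
# switching between Mg2+ coordination states, and monovalent ions whose
# binding follows a two-state Markov process with a configurable stationary
# bound fraction. It makes every pipeline stage testable without running MD.

#' Reference per-conformation statistics of the Mg-ATP chain in water
#'
#' Mean and standard deviation of the PA-PG distance (Angstrom) and the
#' PB-O3B-PG angle (degrees) for each added monovalent cation and each Mg2+
#' coordination regime (bidentate, bidentate-curled, tridentate) of the
#' Mg-ATP complex in water, as estimated from classical MD simulation data.
#' These are the generator's segment-plan defaults.
#'
#' @return data.frame with columns `cation`, `state`, `d_mean`, `d_sd`,
#'   `theta_mean`, `theta_sd`.
#' @export
reference_chain_stats <- function() {
  rbind(
    data.frame(cation = "none", state = "BETA_GAMMA",
               d_mean = 5.46, d_sd = 0.34, theta_mean = 122.3, theta_sd = 3.5),
    data.frame(cation = "none", state = "ALPHA_BETA_GAMMA",
               d_mean = 4.76, d_sd = 0.18, theta_mean = 124.9, theta_sd = 3.3),
    data.frame(cation = "K", state = "BETA_GAMMA",
               d_mean = 4.91, d_sd = 0.24, theta_mean = 122.0, theta_sd = 3.3),
    data.frame(cation = "K", state = "ALPHA_BETA_GAMMA",
               d_mean = 4.32, d_sd = 0.24, theta_mean = 128.0, theta_sd = 3.5),
    data.frame(cation = "Na", state = "BETA_GAMMA",
               d_mean = 4.69, d_sd = 0.22, theta_mean = 122.9, theta_sd = 3.2),
    data.frame(cation = "Na", state = "BETA_GAMMA_CURLED",
               d_mean = 4.60, d_sd = 0.22, theta_mean = 124.0, theta_sd = 3.3),
    data.frame(cation = "Na", state = "ALPHA_BETA_GAMMA",
               d_mean = 4.26, d_sd = 0.37, theta_mean = 127.7, theta_sd = 3.6),
    data.frame(cation = "NH4", state = "BETA_GAMMA",
               d_mean = 4.85, d_sd = 0.22, theta_mean = 122.3, theta_sd = 3.3),
    data.frame(cation = "NH4", state = "BETA_GAMMA_CURLED",
               d_mean = 4.56, d_sd = 0.21, theta_mean = 124.6, theta_sd = 3.3),
    data.frame(cation = "NH4", state = "ALPHA_BETA_GAMMA",
               d_mean = 4.22, d_sd = 0.16, theta_mean = 127.8, theta_sd = 3.3)
  )
}

#' Segment-plan entry
#'
#' @param state coordination state of the segment (see
#'   `COORDINATION_STATES`; `BETA_GAMMA_CURLED` keeps bidentate Mg but a
#'   shorter chain).
#' @param frames segment duration in frames.
#' @param d_mean,d_sd,theta_mean,theta_sd descriptor statistics; defaults
#'   are looked up in [reference_chain_stats()] for `cation`.
#' @param cation cation regime used for the default lookup.
#' @return list describing one segment.
#' @export
segment_plan <- function(state, frames, cation = "K", d_mean = NULL,
                         d_sd = NULL, theta_mean = NULL, theta_sd = NULL) {
  stopifnot(frames > 0)
  ref <- reference_chain_stats()
  hit <- ref[ref$cation == cation & ref$state == state, ]
  if (nrow(hit) == 0L && (is.null(d_mean) || is.null(theta_mean))) {
    stop(sprintf("no reference statistics for cation=%s state=%s; supply means",
                 cation, state), call. = FALSE)
  }
  list(state = state, frames = as.integer(frames),
       d_mean = d_mean %||% hit$d_mean, d_sd = d_sd %||% hit$d_sd,
       theta_mean = theta_mean %||% hit$theta_mean,
       theta_sd = theta_sd %||% hit$theta_sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ion-plan entry
#'
#' One monovalent ion targeting one binding site with a two-state (bound /
#' unbound) Markov process whose stationary bound fraction is
#' `bound_fraction` and whose mean bound dwell is `dwell` frames.
#'
#' @param species `"K"`, `"Na"` or `"NH4"` (NH4+ is represented by its N).
#' @param site target site, `"BG"`, `"AG"` or `"G"`.
#' @param bound_fraction stationary probability of being bound, in [0, 1].
#' @param noise_sd isotropic positional jitter of the bound ion, Angstrom
#'   (default 0.05; small enough that the realized binding state matches the
#'   planned one).
#' @param dwell mean bound dwell in frames (default 50).
#' @param coord_length ion-oxygen coordination bond length; defaults per
#'   species (2.2 Na, 2.6 K, 2.7 NH4).
#' @return list describing one ion.
#' @export
ion_plan <- function(species, site = "BG", bound_fraction = 0.95,
                     noise_sd = 0.05, dwell = 50L, coord_length = NULL) {
  stopifnot(species %in% c("K", "Na", "NH4"),
            site %in% c("BG", "AG", "G"),
            bound_fraction >= 0, bound_fraction <= 1, noise_sd >= 0)
  if (is.null(coord_length)) {
    coord_length <- c(K = 2.6, Na = 2.2, NH4 = 2.7)[[species]]
  }
  list(species = species, site = site, bound_fraction = bound_fraction,
       noise_sd = noise_sd, dwell = as.integer(dwell),
       coord_length = coord_length)
}

#' Synthetic-trajectory configuration
#'
#' @param segments list of [segment_plan()] entries, visited in order.
#' @param ions list of [ion_plan()] entries (possibly empty).
#' @param frame_spacing frame spacing in ps (default 50, the save interval
#'   of the reference simulations).
#' @param phi AR(1) persistence of the descriptor series at this spacing
#'   (default 0.8; short but nontrivial correlation times so that
#'   decorrelation machinery has something to do).
#' @param seed integer random seed; the generator is fully deterministic
#'   given the seed.
#' @param mg_dist Mg-O coordination bond length used for placement
#'   (default 2.07 A, first-shell Mg-O).
#' @return object of class `trajectory_config`.
#' @export
trajectory_config <- function(segments, ions = list(), frame_spacing = 50,
                              phi = 0.8, seed = 1L, mg_dist = 2.07) {
  stopifnot(length(segments) >= 1L, phi >= 0, phi < 1, frame_spacing > 0)
  for (io in ions) {
    if (io$bound_fraction < 0 || io$bound_fraction > 1) {
      stop("bound fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(segments = segments, ions = ions,
                 frame_spacing = frame_spacing, phi = phi,
                 seed = as.integer(seed), mg_dist = mg_dist),
            class = "trajectory_config")
}

# AR(1) around mu with marginal SD sigma; x1 drawn from the marginal
ar1_series <- function(n, mu, sigma, phi) {
  x <- numeric(n)
  innov_sd <- sigma * sqrt(1 - phi^2)
  x[1L] <- mu + stats::rnorm(1L, sd = sigma)
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- mu + phi * (x[t] - mu) + stats::rnorm(1L, sd = innov_sd)
  }
  x
}

# feasible descriptor window of the default chain geometry
D_FEASIBLE <- c(3.2, 5.85)
THETA_FEASIBLE <- c(100, 175)

# Choose the chain torsions of a segment so that the planned coordination
# geometry is realizable: bidentate segments bring O1B and O2G within
# coordination-triangle reach of one Mg2+ (with the alpha oxygens kept
# clear), tridentate segments pull O2A, O1B, O2G into a tight triangle.
# Planned ion sites add soft terms keeping their anchor-oxygen pairs within
# two coordination bonds of each other. Solved once per segment at the
# segment means; per-frame embedding then only re-solves tau1 for the
# distance draw.
segment_torsions <- function(spec, d, theta, state, ions = list()) {
  tridentate <- state == "ALPHA_BETA_GAMMA"
  obj <- function(p) {
    co <- embed_internal(theta, p[1L], p[2L], p[3L], p[4L], spec)
    pen <- (vnorm(co["PA", ] - co["PG", ]) - d)^2 * 25
    if (tridentate) {
      tri <- c(vnorm(co["O2A", ] - co["O1B", ]),
               vnorm(co["O2G", ] - co["O1B", ]),
               vnorm(co["O2A", ] - co["O2G", ]))
      pen <- pen + sum((tri - 3.2)^2)
    } else {
      mid <- (co["O1B", ] + co["O2G", ]) / 2
      clear <- sqrt(rowSums(sweep(co[ALPHA_TERMINAL, , drop = FALSE], 2L,
                                  mid)^2))
      pen <- pen + (vnorm(co["O1B", ] - co["O2G", ]) - 2.9)^2 +
        sum(pmax(0, 4.8 - clear)^2)
    }
    for (io in ions) {
      pair <- switch(io$site, BG = c("O2B", "O1G"), AG = c("O2A", "O3G"),
                     G = NULL)
      if (is.null(pair)) next
      gap <- vnorm(co[pair[1L], ] - co[pair[2L], ])
      pen <- pen + 2 * (gap - min(2 * io$coord_length - 0.8, 3.4))^2
      if (io$site == "AG") {
        # the AG pocket must open away from the beta phosphate, or the
        # bound ion ends up closer to a beta oxygen than to its anchors
        mid <- (co[pair[1L], ] + co[pair[2L], ]) / 2
        bclear <- min(sqrt(rowSums(sweep(co[BETA_OXYGENS, , drop = FALSE],
                                         2L, mid)^2)))
        pen <- pen + 2 * pmax(0, 4.2 - bclear)^2
      }
    }
    pen
  }
  starts <- list(c(160, 150, 60, 60), c(-160, 150, -60, 60),
                 c(120, -120, 60, -60), c(180, 180, 45, 45))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

#' Generate a synthetic Mg-NTP trajectory with ground truth
#'
#' Realizes the configured segment plan frame by frame: descriptor values
#' are AR(1) draws around the segment means (truncated to the feasible
#' geometry window; a truncation rate above 1% is a configuration error),
#' each frame's chain is embedded from its descriptors, the Mg2+ ion is
#' placed to realize the segment's coordination state, and ions are placed
#' or removed according to their bound/unbound Markov chains.
#'
#' @param config a [trajectory_config()].
#' @return object of class `synthetic_trajectory`: `frames` (list of
#'   [phosphate_chain()] including Mg), `ions` (list of per-frame
#'   data.frames `id`, `species`, `x`, `y`, `z`), `truth` (sidecar list:
#'   per-frame `state`, `d`, `theta`, per-ion `bound` matrix and `site`s,
#'   segment boundaries, config echo).
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  set.seed(config$seed)
  segs <- config$segments
  n <- sum(vapply(segs, function(s) s$frames, integer(1)))
  state <- character(n)
  d_series <- numeric(n)
  th_series <- numeric(n)
  seg_id <- integer(n)
  pos <- 0L
  truncated <- 0L
  spec0 <- chain_spec(5, 120)
  seg_pars <- vector("list", length(segs))
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    idx <- pos + seq_len(s$frames)
    dd <- ar1_series(s$frames, s$d_mean, s$d_sd, config$phi)
    tt <- ar1_series(s$frames, s$theta_mean, s$theta_sd, config$phi)
    seg_pars[[si]] <- segment_torsions(spec0, s$d_mean, s$theta_mean,
                                       s$state, ions = config$ions)
    reach <- reachable_d_range(spec0, s$theta_mean, seg_pars[[si]])
    lo <- max(D_FEASIBLE[1L], reach[1L] + 0.15)
    hi <- min(D_FEASIBLE[2L], reach[2L] - 0.15)
    # Draws slightly past the geometric window are clamped: a Gaussian
    # descriptor model near the fully extended chain necessarily has tail
    # mass beyond what the geometry can realize (the no-cation regime,
    # mean 5.46 A, touches the ~5.85 A ceiling). Only grossly infeasible
    # draws -- beyond the window by > 0.5 A / 5 deg, the signature of a
    # misconfigured plan -- count toward the 1% configuration error.
    truncated <- truncated +
      sum(dd < D_FEASIBLE[1L] - 0.5 | dd > D_FEASIBLE[2L] + 0.5) +
      sum(tt < THETA_FEASIBLE[1L] - 5 | tt > THETA_FEASIBLE[2L] + 5)
    dd <- pmin(pmax(dd, lo), hi)
    tt <- pmin(pmax(tt, THETA_FEASIBLE[1L]), THETA_FEASIBLE[2L])
    state[idx] <- s$state
    d_series[idx] <- dd
    th_series[idx] <- tt
    seg_id[idx] <- si
    pos <- pos + s$frames
  }
  if (truncated > 0.01 * n) {
    stop(sprintf(
      "config error: %.1f%% of descriptor draws outside the feasible window",
      100 * truncated / n), call. = FALSE)
  }
  # ion bound/unbound Markov chains
  n_ions <- length(config$ions)
  bound <- matrix(FALSE, n, max(1L, n_ions))[, seq_len(n_ions), drop = FALSE]
  for (k in seq_len(n_ions)) {
    io <- config$ions[[k]]
    f <- io$bound_fraction
    q <- min(1, 1 / io$dwell)                       # unbind prob
    p <- if (f >= 1) 1 else min(1, q * f / (1 - f)) # bind prob
    b <- stats::runif(1) < f
    for (t in seq_len(n)) {
      bound[t, k] <- b
      b <- if (b) stats::runif(1) >= q else stats::runif(1) < p
    }
    if (f == 0) bound[, k] <- FALSE
    if (f == 1) bound[, k] <- TRUE
    # Quota correction: with O(n/dwell) independent dwell cycles the
    # realized fraction of a plain Markov chain fluctuates by several
    # percent, which would swamp the configured occupancy. Frames at run
    # edges are flipped until the configured fraction is realized exactly
    # (up to rounding), preserving the dwell structure.
    bound[, k] <- quota_correct(bound[, k], round(f * n))
  }
  frames <- vector("list", n)
  ions_frames <- vector("list", n)
  warm <- NULL
  seg_par <- NULL
  cur_seg <- 0L
  mg_fail <- 0L
  for (t in seq_len(n)) {
    st <- state[t]
    if (seg_id[t] != cur_seg) {
      cur_seg <- seg_id[t]
      warm <- NULL
      seg_par <- seg_pars[[cur_seg]]
    }
    sp <- chain_spec(d_series[t], th_series[t])
    coords <- embed_frame(sp, seg_par, warm = warm)
    if (st == "ALPHA_BETA_GAMMA") {
      # keep the O2A/O1B/O2G coordination triangle tight while tracking
      # the distance draw; the joint 4-torsion least squares only runs
      # when the warm-started cheap path lets the triangle degrade
      tri <- c(vnorm(coords["O2A", ] - coords["O1B", ]),
               vnorm(coords["O2G", ] - coords["O1B", ]),
               vnorm(coords["O2A", ] - coords["O2G", ]))
      if (any(tri > 3.9)) {
        p0 <- c(attr(coords, "tau"), seg_par[3:4])
        fn4 <- function(p) {
          co <- embed_internal(sp$theta_bridge, p[1L], p[2L], p[3L], p[4L],
                               sp)
          tr3 <- c(vnorm(co["O2A", ] - co["O1B", ]),
                   vnorm(co["O2G", ] - co["O1B", ]),
                   vnorm(co["O2A", ] - co["O2G", ]))
          c((vnorm(co["PA", ] - co["PG", ]) - d_series[t]) * 100,
            (tr3 - 3.3) * 3)
        }
        p4 <- lm_solve(p0, fn4, tol = 1e-9, max_iter = 5L)$par
        seg_par[3:4] <- p4[3:4]
        coords <- embed_frame(sp, seg_par, warm = p4[1:2])
      }
    }
    warm <- attr(coords, "tau")
    # ground truth records the realized distance (equal to the draw except
    # for rare regularized fallback frames)
    d_series[t] <- vnorm(coords["PA", ] - coords["PG", ])
    # Mg placement realizing the coordination state
    alpha_term <- coords[ALPHA_TERMINAL, , drop = FALSE]
    if (st %in% c("BETA_GAMMA", "BETA_GAMMA_CURLED")) {
      place_bg_mg <- function(co) {
        place_at_distances(co[c("O1B", "O2G"), ], rep(config$mg_dist, 2L),
                           avoid = co[ALPHA_TERMINAL, , drop = FALSE],
                           best_effort = TRUE)
      }
      bad_mg <- function(co, m) {
        vnorm(m - co["O1B", ]) > 2.5 || vnorm(m - co["O2G", ]) > 2.5 ||
          min(sqrt(rowSums(sweep(co[ALPHA_TERMINAL, , drop = FALSE], 2L,
                                 m)^2))) <= 2.5
      }
      mg <- place_bg_mg(coords)
      if (bad_mg(coords, mg)) {
        # re-solve the group torsions at this frame's descriptors; the
        # segment solution can drift out of bidentate reach
        seg_par <- segment_torsions(spec0, d_series[t], th_series[t], st,
                                    ions = config$ions)
        coords <- embed_frame(sp, seg_par, warm = NULL)
        warm <- attr(coords, "tau")
        alpha_term <- coords[ALPHA_TERMINAL, , drop = FALSE]
        mg <- place_bg_mg(coords)
        if (bad_mg(coords, mg)) mg_fail <- mg_fail + 1L
      }
    } else if (st == "ALPHA_BETA_GAMMA") {
      mg <- place_mg_tridentate(coords, config$mg_dist)
      tri_d <- sqrt(rowSums(sweep(coords[c("O2A", "O1B", "O2G"), ], 2L,
                                  mg)^2))
      if (any(tri_d > 2.5)) {
        # rescue: re-solve the group torsions at this frame's descriptors
        seg_par <- segment_torsions(spec0, d_series[t], th_series[t], st,
                                    ions = config$ions)
        coords <- embed_frame(sp, seg_par, warm = NULL)
        warm <- attr(coords, "tau")
        d_series[t] <- vnorm(coords["PA", ] - coords["PG", ])
        alpha_term <- coords[ALPHA_TERMINAL, , drop = FALSE]
        mg <- place_mg_tridentate(coords, config$mg_dist)
        tri_d <- sqrt(rowSums(sweep(coords[c("O2A", "O1B", "O2G"), ], 2L,
                                    mg)^2))
        if (any(tri_d > 2.5)) mg_fail <- mg_fail + 1L
      }
    } else {
      mg <- colMeans(coords) + c(0, 0, 8) # detached
    }
    coords_mg <- rbind(coords, Mg = mg)
    frames[[t]] <- phosphate_chain(coords_mg, source = t, check = FALSE)
    # ions
    if (n_ions > 0L) {
      rows <- vector("list", n_ions)
      for (k in seq_len(n_ions)) {
        io <- config$ions[[k]]
        if (bound[t, k]) {
          # keep the ion clear of Mg and of the groups that would flip its
          # site assignment; the site anchors themselves are never avoided
          avoid <- switch(io$site,
            BG = rbind(mg, alpha_term),
            AG = matrix(mg, nrow = 1L), # beta clearance handled in-site
            G = matrix(mg, nrow = 1L))
          base <- ion_site_position(coords, io$site, io$coord_length,
                                    avoid = avoid)
          p <- base + stats::rnorm(3L, sd = io$noise_sd)
          # record the realized binding state with the same semantics the
          # site-assignment rule uses: under rare geometries the placement
          # cannot reach the planned site and the frame counts unbound
          bd <- DEFAULT_BINDING_DISTANCES[[io$species]]
          gd <- function(labels) {
            pts <- coords[intersect(labels, rownames(coords)), ,
                          drop = FALSE]
            min(sqrt(rowSums(sweep(pts, 2L, p)^2)))
          }
          rA <- gd(ALPHA_OXYGENS); rB <- gd(BETA_OXYGENS)
          rG <- gd(GAMMA_OXYGENS)
          ag <- rA <= bd && rG <= bd
          bg <- rB <= bd && rG <= bd
          realized_site <- if (ag && bg) {
            if ((rA + rG) / 2 < (rB + rG) / 2) "AG" else "BG"
          } else if (bg) "BG" else if (ag) "AG"
          else if (rG <= bd) "G" else "unbound"
          bound[t, k] <- realized_site == io$site
        } else {
          ctr <- colMeans(coords)
          p <- ctr + 10 * probe_directions(8L)[((t + k) %% 8L) + 1L, ]
        }
        rows[[k]] <- data.frame(id = sprintf("%s%d", io$species, k),
                                species = io$species,
                                x = p[1L], y = p[2L], z = p[3L])
      }
      ions_frames[[t]] <- do.call(rbind, rows)
    } else {
      ions_frames[[t]] <- data.frame(id = character(0), species = character(0),
                                     x = numeric(0), y = numeric(0),
                                     z = numeric(0))
    }
  }
  if (mg_fail > 0.01 * n) {
    stop(sprintf(
      "config error: Mg coordination unrealizable in %.1f%% of frames",
      100 * mg_fail / n), call. = FALSE)
  }
  seg_end <- cumsum(vapply(segs, function(s) s$frames, integer(1)))
  truth <- list(state = state, d = d_series, theta = th_series,
                segment_start = c(1L, utils::head(seg_end, -1L) + 1L),
                segment_end = seg_end,
                segment_state = vapply(segs, function(s) s$state, character(1)),
                bound = bound,
                ion_site = vapply(config$ions, function(io) io$site,
                                  character(1)),
                ion_species = vapply(config$ions, function(io) io$species,
                                     character(1)),
                bound_fraction = vapply(config$ions,
                                        function(io) io$bound_fraction,
                                        numeric(1)),
                frame_spacing = config$frame_spacing, phi = config$phi,
                seed = config$seed)
  structure(list(frames = frames, ions = ions_frames, truth = truth,
                 config = config),
            class = "synthetic_trajectory")
}

# flip frames at bound/unbound run edges until exactly `target` frames are
# bound; used to realize the configured bound fraction exactly
quota_correct <- function(b, target) {
  n <- length(b)
  target <- max(0L, min(n, target))
  repeat {
    cur <- sum(b)
    if (cur == target) return(b)
    if (cur < target) {
      prev_bound <- c(FALSE, b[-n])
      next_bound <- c(b[-1L], FALSE)
      cand <- which(!b & (prev_bound | next_bound))
      if (!length(cand)) cand <- which(!b)
      b[cand[seq_len(min(length(cand), target - cur))]] <- TRUE
    } else {
      prev_un <- c(TRUE, !b[-n])
      next_un <- c(!b[-1L], TRUE)
      cand <- which(b & (prev_un | next_un))
      if (!length(cand)) cand <- which(b)
      b[cand[seq_len(min(length(cand), cur - target))]] <- FALSE
    }
  }
}

# distance range reachable by the backbone torsions at fixed group torsions
reachable_d_range <- function(spec, theta, seg_par) {
  grid <- seq(-180, 170, by = 15)
  vals <- c()
  for (t1 in grid) {
    for (t2 in grid) {
      co <- embed_internal(theta, t1, t2, seg_par[3L], seg_par[4L], spec)
      vals <- c(vals, vnorm(co["PA", ] - co["PG", ]))
    }
  }
  range(vals)
}

# Embed one frame with the segment's group torsions, adjusting the two
# backbone torsions for the frame's distance draw (warm-started from the
# previous frame so the chain moves continuously).
embed_frame <- function(sp, seg_par, warm = NULL) {
  target <- sp$d_PA_PG
  # the distance residual needs only the five backbone atoms
  rb <- sp$r_bridge
  th <- sp$theta_bridge * DEG
  PB <- c(0, 0, 0)
  O3B <- c(rb, 0, 0)
  PG <- O3B + rb * c(-cos(th), sin(th), 0)
  fn <- function(p) {
    O3A <- place_atom(PG, O3B, PB, rb, sp$ang_OPO, p[2L])
    PA <- place_atom(O3B, PB, O3A, rb, sp$ang_POP, p[1L])
    (vnorm(PA - PG) - target) * 100
  }
  done <- function(p) {
    co <- embed_internal(sp$theta_bridge, p[1L], p[2L],
                         seg_par[3L], seg_par[4L], sp)
    attr(co, "tau") <- p
    co
  }
  # primary path: Newton on tau1 alone with tau2 pinned to the segment
  # solution, so the chain stays on the segment's torsional branch
  t2 <- seg_par[2L]
  t1 <- (warm %||% seg_par)[1L]
  for (it in 1:40) {
    ft <- fn(c(t1, t2))
    if (abs(ft) < 1e-4) return(done(c(t1, t2)))
    dft <- (fn(c(t1 + 0.01, t2)) - ft) / 0.01
    if (abs(dft) < 1e-10) break
    step <- ft / dft
    t1 <- t1 - max(-25, min(25, step)) # damped
  }
  # bracket scan fallback, same branch
  g <- seq(-180, 177, by = 3)
  vals <- vapply(g, function(x) fn(c(x, t2)), numeric(1))
  flips <- which(diff(sign(vals)) != 0)
  if (length(flips)) {
    # pick the root closest to the previous tau1
    ref <- (warm %||% seg_par)[1L]
    i <- flips[which.min(abs(g[flips] - ref))]
    t1 <- stats::uniroot(function(x) fn(c(x, t2)), c(g[i], g[i + 1L]),
                         tol = 1e-10)$root
    return(done(c(t1, t2)))
  }
  # out of reach for tau1 alone: adjust both backbone torsions, softly
  # regularized toward the segment branch; the realized distance (recorded
  # into the ground truth) may then deviate marginally from the draw
  fnreg <- function(p) c(fn(p), (p - seg_par[1:2]) * 0.03)
  start <- c((warm %||% seg_par[1:2])[1L], seg_par[2L])
  fit <- lm_solve(start, fnreg, tol = 1e-6, max_iter = 40L)
  co <- done(fit$par)
  if (abs(vnorm(co["PA", ] - co["PG", ]) - target) > 0.05) {
    stop(sprintf("infeasible distance draw %.3f A for the segment geometry",
                 target), call. = FALSE)
  }
  co
}

# Mg position against the three tridentate oxygens: closed-form
# trilateration, degrading to the in-plane compromise point when the
# triangle's circumradius exceeds the coordination length
place_mg_tridentate <- function(coords, mg_dist) {
  place_at_distances(coords[c("O2A", "O1B", "O2G"), ], rep(mg_dist, 3L),
                     best_effort = TRUE)
}

# ideal position of an ion bound at a site
ion_site_position <- function(coords, site, coord_length, avoid) {
  if (site == "BG") {
    place_at_distances(coords[c("O2B", "O1G"), ], rep(coord_length, 2L),
                       avoid = avoid, best_effort = TRUE)
  } else if (site == "AG") {
    # An AG assignment requires the ion to stay farther from every beta
    # oxygen (incl. the shared bridging O3A/O3B) than from its alpha
    # anchor, otherwise R_BG undercuts R_AG. Candidates are scored by that
    # clearance margin.
    beta_pts <- coords[intersect(BETA_OXYGENS, rownames(coords)), ,
                       drop = FALSE]
    mind_all <- function(cand, pts) {
      apply(cand, 1L, function(p)
        min(sqrt(rowSums(sweep(pts, 2L, p)^2))))
    }
    gap <- vnorm(coords["O2A", ] - coords["O3G", ])
    if (gap <= 2 * coord_length - 0.02) {
      cand <- circle_points(coords["O2A", ], coord_length,
                            coords["O3G", ], coord_length, 72L)
      margin <- pmin(mind_all(cand, beta_pts) - coord_length,
                     mind_all(cand, avoid) - 2.0)
      cand[which.max(margin), ]
    } else {
      # chain too extended for this ion to bridge alpha and gamma: it stays
      # coordinated to the gamma oxygen, reaching toward alpha (and the
      # realized state is recorded from the actual distances)
      cand <- sweep(probe_directions(72L) * coord_length, 2L,
                    -coords["O3G", ])
      clash <- mind_all(cand, avoid)
      bd_ <- mind_all(cand, beta_pts)
      da <- apply(cand, 1L, function(p) vnorm(p - coords["O2A", ]))
      ok <- clash > 2.0 & bd_ > coord_length
      if (!any(ok)) ok <- clash >= max(clash)
      cand[which(ok)[which.min(da[ok])], ]
    }
  } else { # G: gamma only, away from everything else
    place_at_distances(coords["O3G", , drop = FALSE], coord_length,
                       avoid = rbind(coords[c(ALPHA_OXYGENS, BETA_OXYGENS), ],
                                     avoid))
  }
}

#' Write a synthetic trajectory as a multi-model PDB plus JSON sidecar
#'
#' @param traj a `synthetic_trajectory`.
#' @param path output PDB path; the sidecar goes to `<path>.json`.
#' @param ligand residue name used for the chain atoms (default ATP).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, ligand = "ATP") {
  con <- file(path, open = "w")
  close(con) # truncate
  for (t in seq_along(traj$frames)) {
    co <- traj$frames[[t]]$coords
    atoms <- data.frame(record = "HETATM", atom = rownames(co),
                        resname = ligand, chain = "X", resseq = 1L,
                        x = co[, 1L], y = co[, 2L], z = co[, 3L],
                        element = substr(gsub("[0-9'].*$", "", rownames(co)),
                                         1L, 1L),
                        stringsAsFactors = FALSE)
    atoms$resname[atoms$atom == "Mg"] <- "MG"
    atoms$atom[atoms$atom == "Mg"] <- "MG"
    atoms$element[atoms$atom == "MG"] <- "MG"
    io <- traj$ions[[t]]
    if (nrow(io)) {
      res <- c(K = "K", Na = "NA", NH4 = "NH4")[io$species]
      atm <- c(K = "K", Na = "NA", NH4 = "N")[io$species]
      atoms <- rbind(atoms, data.frame(
        record = "HETATM", atom = atm, resname = res, chain = "Y",
        resseq = seq_len(nrow(io)) + 1L, x = io$x, y = io$y, z = io$z,
        element = c(K = "K", Na = "NA", NH4 = "N")[io$species],
        stringsAsFactors = FALSE))
    }
    write_pdb(atoms, path, model = t, append = TRUE)
  }
  cat("END\n", file = path, append = TRUE)
  sidecar <- traj$truth
  sidecar$bound <- apply(traj$truth$bound, 2L, as.integer)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-model PDB trajectory written by [write_trajectory_pdb()]
#'
#' @param path PDB path.
#' @return list with `frames` (list of [phosphate_chain()]) and `ions`
#'   (list of per-frame data.frames).
#' @export
read_trajectory_pdb <- function(path) {
  df <- read_structure(path, model = NA)
  frames <- list()
  ions <- list()
  for (m in sort(unique(df$model))) {
    sub <- df[df$model == m, ]
    chain_atoms <- sub[sub$chain == "X", ]
    co <- as.matrix(chain_atoms[, c("x", "y", "z")])
    labels <- chain_atoms$atom
    labels[labels == "MG"] <- "Mg"
    rownames(co) <- labels
    frames[[length(frames) + 1L]] <- phosphate_chain(co, source = m,
                                                     check = FALSE)
    io <- sub[sub$chain == "Y", ]
    species <- c(K = "K", "NA" = "Na", NH4 = "NH4")[io$resname]
    ions[[length(ions) + 1L]] <- data.frame(
      id = paste0(species, seq_len(nrow(io))), species = unname(species),
      x = io$x, y = io$y, z = io$z, stringsAsFactors = FALSE)
  }
  list(frames = frames, ions = ions)
}

#' Fixture-structure specification
#'
#' Describes a minimal single-site structure fixture: one NTP-like ligand
#' with a given chain geometry, optionally an Mg2+ ion, an AG-site occupant
#' (cation or water), a P-loop-like Lys stub, and an Arg stub.
#'
#' @param ligand chemical ID (see [ligand_atlas()]); for transition-state
#'   fixtures give the NDP id plus `moiety` (e.g. `"GDP"` + `"ALF"`).
#' @param spec a [chain_spec()] for the chain geometry.
#' @param moiety optional gamma-mimic moiety id (`"ALF"`, `"AF3"`, `"MGF"`,
#'   `"BEF"`).
#' @param mg include the Mg2+ ion (default TRUE).
#' @param cation optional list: `species` (`"K"`, `"NA"`, `"RB"`, `"NH4"`),
#'   `dist_gamma` (to the closest gamma O/F), optional `dist_alpha` (to the
#'   closest alpha O; when feasible both are realized exactly, otherwise
#'   `dist_alpha` is approached as closely as the geometry allows).
#' @param water place a water molecule in the AG position at `dist_gamma`
#'   (mutually exclusive with `cation`).
#' @param lys_nz_dist NZ distance of the Lys stub to the BG-site oxygens
#'   (default 2.8; `NA` drops the Lys).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(ligand, spec, moiety = NULL, mg = TRUE,
                         cation = NULL, water = FALSE, lys_nz_dist = 2.8) {
  stopifnot(inherits(spec, "chain_spec"))
  if (!is.null(cation) && water) {
    stop("give either a cation or a water occupant, not both", call. = FALSE)
  }
  structure(list(ligand = ligand, spec = spec, moiety = moiety, mg = mg,
                 cation = cation, water = water, lys_nz_dist = lys_nz_dist),
            class = "fixture_spec")
}

#' Generate a fixture PDB file from a specification
#'
#' Embeds the chain, renames atoms to the ligand's PDB names, converts the
#' gamma group to the mimic moiety when requested (Al/Be/Mg centre at the PG
#' position, fluorines along the gamma-oxygen directions, the fourth F of
#' AlF4- completing the square plane), places Mg2+, the AG occupant and the
#' Lys stub, and writes a minimal PDB that round-trips through the survey.
#'
#' @param fspec a [fixture_spec()].
#' @param path output PDB path.
#' @return `path`, invisibly; attribute `atoms` carries the atom table.
#' @export
generate_fixture_structure <- function(fspec, path) {
  stopifnot(inherits(fspec, "fixture_spec"))
  atlas <- ligand_atlas()
  amap <- atlas[atlas$ligand == fspec$ligand, ]
  if (nrow(amap) == 0L) {
    stop(sprintf("unknown ligand id: %s", fspec$ligand), call. = FALSE)
  }
  ch <- embed_chain(fspec$spec)
  p <- attr(ch, "params")
  sp <- fspec$spec
  psi_free <- is.null(sp$psi_ab) && is.null(sp$psi_bg) && is.null(sp$psi_ag)
  # The group torsions rho_A / rho_G leave the PA-PG distance and the bridge
  # angle untouched; when the dihedrals are not pinned by the spec they are
  # scanned for an orientation with an open AG face so that the requested
  # occupant placement is realizable.
  rho_grid <- if (psi_free) {
    g <- seq(-180, 165, by = 15)
    c(list(p[3:4]), unlist(lapply(g, function(ra)
      lapply(g, function(rg) c(ra, rg))), recursive = FALSE))
  } else {
    list(p[3:4])
  }
  last_err <- NULL
  for (rho in rho_grid) {
    co <- embed_internal(sp$theta_bridge, p[1L], p[2L], rho[1L], rho[2L], sp)
    at <- tryCatch(fixture_atoms(co, fspec, amap),
                   error = function(e) e)
    if (!inherits(at, "error")) {
      write_pdb(at, path)
      out <- path
      attr(out, "atoms") <- at
      return(invisible(out))
    }
    last_err <- at
  }
  stop(conditionMessage(last_err), call. = FALSE)
}

# one build attempt at fixed chain coordinates; errors on placement conflict
fixture_atoms <- function(co, fspec, amap) {
  atoms <- list()
  addatom <- function(record, atom, resname, chain, resseq, p, element) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      record = record, atom = atom, resname = resname, chain = chain,
      resseq = resseq, x = p[1L], y = p[2L], z = p[3L], element = element,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(amap))) {
    lab <- amap$label[i]
    if (!lab %in% rownames(co)) next
    el <- substr(gsub("[0-9'].*$", "", amap$atom[i]), 1L, 1L)
    addatom("HETATM", amap$atom[i], fspec$ligand, "X", 1L, co[lab, ], el)
  }
  gamma_mimic_atoms <- NULL
  if (!is.null(fspec$moiety)) {
    centre_el <- switch(fspec$moiety, ALF = "AL", AF3 = "AL", MGF = "MG",
                        BEF = "BE")
    pg <- co["PG", ]
    fl <- list()
    for (g in GAMMA_TERMINAL) {
      fl[[g]] <- pg + 1.69 * unitv(co[g, ] - pg)
    }
    if (fspec$moiety == "ALF") {
      # square-planar AlF4-: project the three F into the plane normal to
      # O3B->Al, re-space at 90 degrees, add the fourth
      u <- unitv(pg - co["O3B", ])
      e1 <- unitv(fl[["O1G"]] - pg - sum((fl[["O1G"]] - pg) * u) * u)
      e2 <- vcross(u, e1)
      fl <- lapply(0:3, function(k) {
        pg + 1.69 * (cos(k * pi / 2) * e1 + sin(k * pi / 2) * e2)
      })
      names(fl) <- paste0("F", 1:4)
    } else {
      names(fl) <- paste0("F", seq_along(fl))
    }
    addatom("HETATM", centre_el, fspec$moiety, "X", 2L, pg, centre_el)
    for (nm in names(fl)) addatom("HETATM", nm, fspec$moiety, "X", 2L,
                                  fl[[nm]], "F")
    gamma_mimic_atoms <- do.call(rbind, fl)
  }
  gamma_ref <- if (is.null(gamma_mimic_atoms)) {
    co[GAMMA_TERMINAL, , drop = FALSE]
  } else gamma_mimic_atoms
  # atoms actually written: for mimic fixtures the gamma oxygens are
  # replaced by the fluorines (the centre coincides with PG)
  placed <- if (is.null(gamma_mimic_atoms)) co else
    rbind(co[setdiff(rownames(co), GAMMA_TERMINAL), , drop = FALSE],
          gamma_mimic_atoms)
  mindist <- function(p, pts) {
    if (is.null(pts) || nrow(pts) == 0L) return(Inf)
    min(sqrt(rowSums(sweep(pts, 2L, p)^2)))
  }
  mg_pos <- NULL
  if (fspec$mg) {
    mg_anchors <- rbind(co["O2B", ], gamma_ref[1L, ])
    mg_pos <- place_at_distances(mg_anchors, c(2.07, 2.07),
                                 avoid = co[c("O1A", "O2A", "PA"), ])
    addatom("HETATM", "MG", "MG", "M", 1L, mg_pos, "MG")
    placed <- rbind(placed, mg_pos)
  }
  occ <- fspec$cation
  if (fspec$water) occ <- list(species = "HOH", dist_alpha = 3.0,
                               dist_gamma = 2.9)
  if (!is.null(occ)) {
    # the AG occupant binds an alpha and a gamma atom; the anchors must end
    # up as the occupant's closest alpha and gamma atoms so the recorded
    # distances reproduce the requested ones
    alpha_all <- co[ALPHA_TERMINAL, , drop = FALSE]
    occ_pos <- NULL
    if (!is.null(occ$dist_alpha) && occ$dist_alpha <= 3.5) {
      for (aa in c("O2A", "O1A")) {
        for (fi in seq_len(nrow(gamma_ref))) {
          gap <- vnorm(co[aa, ] - gamma_ref[fi, ])
          if (gap >= occ$dist_alpha + occ$dist_gamma - 0.02 ||
              gap <= abs(occ$dist_alpha - occ$dist_gamma) + 0.02) next
          cand <- circle_points(co[aa, ], occ$dist_alpha, gamma_ref[fi, ],
                                occ$dist_gamma, 144L)
          aother <- alpha_all[rownames(alpha_all) != aa, , drop = FALSE]
          gother <- gamma_ref[-fi, , drop = FALSE]
          valid <- apply(cand, 1L, function(q) {
            mindist(q, aother) > occ$dist_alpha &&
              mindist(q, gother) > occ$dist_gamma &&
              mindist(q, placed) > 2.0
          })
          if (!any(valid)) next
          cand <- cand[valid, , drop = FALSE]
          clearance <- apply(cand, 1L, mindist, pts = placed)
          occ_pos <- cand[which.max(clearance), ]
          break
        }
        if (!is.null(occ_pos)) break
      }
      if (is.null(occ_pos)) {
        stop("placement conflict for AG occupant", call. = FALSE)
      }
    } else {
      # alpha side out of coordination reach: put the occupant on the
      # sphere around the gamma atom nearest the alpha group, as close to
      # the alpha-distance target as the geometry allows
      target_a <- occ$dist_alpha %||% 6
      dga <- apply(gamma_ref, 1L, function(g) mindist(g, alpha_all))
      ganchor <- gamma_ref[which.min(dga), ]
      gother <- gamma_ref[-which.min(dga), , drop = FALSE]
      cand <- sweep(probe_directions(360L) * occ$dist_gamma, 2L, -ganchor)
      clash <- apply(cand, 1L, mindist, pts = placed)
      gok <- apply(cand, 1L, function(q) mindist(q, gother) > occ$dist_gamma)
      da <- apply(cand, 1L, mindist, pts = alpha_all)
      okc <- clash > 2.0 & gok
      if (!any(okc)) stop("placement conflict for AG occupant", call. = FALSE)
      sel <- which(okc)[which.min(abs(da[okc] - target_a))]
      occ_pos <- cand[sel, ]
    }
    if (fspec$water) {
      addatom("HETATM", "O", "HOH", "W", 1L, occ_pos, "O")
    } else {
      addatom("HETATM", occ$species, occ$species, "C", 1L, occ_pos,
              occ$species)
    }
    placed <- rbind(placed, occ_pos)
  }
  if (!is.na(fspec$lys_nz_dist)) {
    nz_anchors <- rbind(co["O1B", ], gamma_ref[min(2L, nrow(gamma_ref)), ])
    nz <- place_at_distances(nz_anchors, rep(fspec$lys_nz_dist, 2L),
                             avoid = placed)
    dir <- unitv(nz - colMeans(co))
    chainpts <- list(NZ = nz)
    for (nm in c("CE", "CD", "CG", "CB", "CA")) {
      chainpts[[nm]] <- nz + (length(chainpts)) * 1.5 * dir
    }
    perp <- unitv(orthogonal_to(dir))
    chainpts$N <- chainpts$CA + 1.46 * unitv(perp + 0.3 * dir)
    chainpts$C <- chainpts$CA + 1.52 * unitv(vcross(dir, perp) + 0.3 * dir)
    chainpts$O <- chainpts$C + 1.23 * dir
    for (nm in c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")) {
      addatom("ATOM", nm, "LYS", "P", 25L, chainpts[[nm]],
              substr(nm, 1L, 1L))
    }
  }
  at <- do.call(rbind, atoms)
  # clash check between separately placed entities
  ext <- at[at$resname %in% c("MG", "HOH", "K", "NA", "RB", "NH4") |
              at$atom == "NZ", ]
  if (nrow(ext) >= 2L) {
    pts <- as.matrix(ext[, c("x", "y", "z")])
    dm <- as.matrix(stats::dist(pts))
    diag(dm) <- Inf
    if (min(dm) < 1.5) {
      stop(sprintf("placement conflict: entities %.2f A apart", min(dm)),
           call. = FALSE)
    }
  }
  at
}
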