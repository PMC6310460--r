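# Canonical representation of the NTP triphosphate chain and its shape
# descriptors.
#
# Atom labels follow the CHARMM / IUPAC naming for nucleoside triphosphates:
# the three phosphorus atoms PA, PB, PG; bridging oxygens O5' (ester link to
# the ribose), O3A (PA-PB bridge) and O3B (PB-PG bridge); terminal oxygens
# O1A/O2A, O1B/O2B and O1G/O2G/O3G. "Mg" is the catalytic Mg2+ when present.

CHAIN_LABELS <- c("PA", "PB", "PG",
                  "O1A", "O2A", "O3A",
                  "O1B", "O2B", "O3B",
                  "O1G", "O2G", "O3G")

# oxygens per phosphate group; bridging oxygens belong to both flanking groups
ALPHA_OXYGENS <- c("O5'", "O1A", "O2A", "O3A")
BETA_OXYGENS  <- c("O3A", "O1B", "O2B", "O3B")
GAMMA_OXYGENS <- c("O3B", "O1G", "O2G", "O3G")

# non-bridging (terminal) oxygens, the ones that coordinate Mg2+
ALPHA_TERMINAL <- c("O1A", "O2A")
BETA_TERMINAL  <- c("O1B", "O2B")
GAMMA_TERMINAL <- c("O1G", "O2G", "O3G")

#' Construct a phosphate-chain object
#'
#' A `phosphate_chain` holds labeled 3D coordinates of the triphosphate atoms
#' of one trajectory frame or one crystal-structure ligand, optionally with
#' the Mg2+ ion, plus per-atom flags marking atoms that stand in for a
#' gamma-phosphate mimic (Al/Be/Mg centre or F of AlF4-, AlF3, MgF3-, BeF3-,
#' or the N/C/S substitutions of non-hydrolyzable analogs).
#'
#' @param coords numeric matrix, n x 3, with rownames giving atom labels
#'   (canonical labels `PA`, `PB`, `PG`, `O1A` ... `O3G`, `O5'`, optionally
#'   `Mg` and `N1`).
#' @param is_mimic logical vector named by atom label; atoms standing in for
#'   mimic atoms. Default: none.
#' @param source free-form tag (frame index or structure/chain/ligand id).
#' @param check if `TRUE`, bonded P-O distances are validated against the
#'   physically plausible 1.2-2.2 Angstrom window for non-mimic atoms;
#'   violations are recorded in `$flags`, never silently dropped.
#' @return object of class `phosphate_chain` with elements `coords`,
#'   `is_mimic`, `source`, `complete` and `flags`.
#' @export
phosphate_chain <- function(coords, is_mimic = NULL, source = NA_character_,
                            check = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || is.null(rownames(coords))) {
    stop("coords must be an n x 3 matrix with atom-label rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(coords))) {
    stop("duplicate atom labels in chain coordinates", call. = FALSE)
  }
  labels <- rownames(coords)
  if (is.null(is_mimic)) {
    is_mimic <- stats::setNames(rep(FALSE, length(labels)), labels)
  } else {
    full <- stats::setNames(rep(FALSE, length(labels)), labels)
    full[names(is_mimic)] <- is_mimic
    is_mimic <- full
  }
  missing <- setdiff(CHAIN_LABELS, labels)
  complete <- length(missing) == 0L
  flags <- character(0)
  if (check && complete) {
    bonds <- list(c("PA", "O1A"), c("PA", "O2A"), c("PA", "O3A"),
                  c("O3A", "PB"), c("PB", "O1B"), c("PB", "O2B"),
                  c("PB", "O3B"), c("O3B", "PG"), c("PG", "O1G"),
                  c("PG", "O2G"), c("PG", "O3G"))
    for (b in bonds) {
      if (any(is_mimic[b])) next
      d <- vnorm(coords[b[1L], ] - coords[b[2L], ])
      if (d < 1.2 || d > 2.2) {
        flags <- c(flags, sprintf("implausible %s-%s bond length %.3f A",
                                  b[1L], b[2L], d))
      }
    }
  }
  structure(list(coords = coords, is_mimic = is_mimic, source = source,
                 complete = complete, missing = missing, flags = flags),
            class = "phosphate_chain")
}

#' @export
print.phosphate_chain <- function(x, ...) {
  cat(sprintf("<phosphate_chain> %d atoms, %s%s\n", nrow(x$coords),
              if (x$complete) "complete" else
                paste0("incomplete (missing ", paste(x$missing, collapse = ", "), ")"),
              if (any(x$is_mimic)) ", mimic-derived" else ""))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

chain_atom <- function(chain, label) {
  if (!label %in% rownames(chain$coords)) {
    stop(sprintf("missing atom: %s", label), call. = FALSE)
  }
  chain$coords[label, ]
}

#' Shape descriptors of a triphosphate chain
#'
#' Computes the five scalar descriptors of chain shape: the PA-PG distance,
#' the PB-O3B-PG bridge angle, and the three inter-phosphate dihedrals
#' psi_ab = O2A-PA-PB-O2B, psi_bg = O1B-PB-PG-O1G and
#' psi_ag = O1A-PA-PG-O3G. Dihedrals are signed (IUPAC convention);
#' 0 degrees is eclipsed, +/-60 staggered. Use `abs()` downstream where a
#' magnitude comparison is wanted.
#'
#' @param chain a [phosphate_chain()]; must be complete (a gamma-phosphate
#'   mimic mapped onto the PG/O*G slots counts as complete).
#' @return object of class `geometry_descriptors`: a list with `d_PA_PG`
#'   (Angstrom), `theta_bridge` (degrees, [0,180]), `psi_ab`, `psi_bg`,
#'   `psi_ag` (degrees, (-180,180]) and `mimic` (TRUE when any atom used is
#'   a mimic stand-in).
#' @export
compute_descriptors <- function(chain) {
  stopifnot(inherits(chain, "phosphate_chain"))
  if (!chain$complete) {
    stop(sprintf("incomplete chain: missing %s",
                 paste(chain$missing, collapse = ", ")), call. = FALSE)
  }
  g <- function(l) chain_atom(chain, l)
  d <- vnorm(g("PA") - g("PG"))
  if (d <= 0) stop("degenerate chain: PA and PG coincide", call. = FALSE)
  theta <- measure_angle(g("PB"), g("O3B"), g("PG"), c("PB", "O3B", "PG"))
  psi_ab <- measure_dihedral(g("O2A"), g("PA"), g("PB"), g("O2B"),
                             c("O2A", "PA", "PB", "O2B"))
  psi_bg <- measure_dihedral(g("O1B"), g("PB"), g("PG"), g("O1G"),
                             c("O1B", "PB", "PG", "O1G"))
  psi_ag <- measure_dihedral(g("O1A"), g("PA"), g("PG"), g("O3G"),
                             c("O1A", "PA", "PG", "O3G"))
  used <- c("PA", "PB", "PG", "O3B", "O1A", "O2A", "O1B", "O2B", "O1G", "O3G")
  structure(list(d_PA_PG = d, theta_bridge = theta,
                 psi_ab = psi_ab, psi_bg = psi_bg, psi_ag = psi_ag,
                 mimic = any(chain$is_mimic[used])),
            class = "geometry_descriptors")
}

#' @export
print.geometry_descriptors <- function(x, ...) {
  cat(sprintf(
    "d(PA-PG) = %.3f A  theta(PB-O3B-PG) = %.2f deg  psi_ab/bg/ag = %.1f / %.1f / %.1f deg%s\n",
    x$d_PA_PG, x$theta_bridge, x$psi_ab, x$psi_bg, x$psi_ag,
    if (isTRUE(x$mimic)) "  [mimic-derived]" else ""))
  invisible(x)
}

#' @export
as.data.frame.geometry_descriptors <- function(x, ...) {
  data.frame(d_PA_PG = x$d_PA_PG, theta_bridge = x$theta_bridge,
             psi_ab = x$psi_ab, psi_bg = x$psi_bg, psi_ag = x$psi_ag,
             mimic = x$mimic)
}

#' Internal-coordinate specification of a triphosphate chain
#'
#' Describes a chain by its target shape descriptors plus the bond-length /
#' bond-angle defaults used to realize them in 3D. Dihedral targets may be
#' `NULL` (left free); the distance and bridge-angle targets are mandatory.
#'
#' @param d_PA_PG target PA-PG distance, Angstrom.
#' @param theta_bridge target PB-O3B-PG angle, degrees.
#' @param psi_ab,psi_bg,psi_ag optional dihedral targets, degrees.
#' @param r_bridge bridging P-O bond length (default 1.60 A).
#' @param r_term terminal P-O bond length (default 1.50 A).
#' @param ang_OPO tetrahedral O-P-O angle (default 109.47 deg).
#' @param ang_POP P-O-P angle at the PA-O3A-PB bridge (default 130 deg).
#' @return object of class `chain_spec`.
#' @export
chain_spec <- function(d_PA_PG, theta_bridge,
                       psi_ab = NULL, psi_bg = NULL, psi_ag = NULL,
                       r_bridge = 1.60, r_term = 1.50,
                       ang_OPO = 109.47122, ang_POP = 130) {
  stopifnot(d_PA_PG > 0, theta_bridge > 0, theta_bridge < 180,
            r_bridge > 0, r_term > 0)
  structure(list(d_PA_PG = d_PA_PG, theta_bridge = theta_bridge,
                 psi_ab = psi_ab, psi_bg = psi_bg, psi_ag = psi_ag,
                 r_bridge = r_bridge, r_term = r_term,
                 ang_OPO = ang_OPO, ang_POP = ang_POP),
            class = "chain_spec")
}

# Forward map: internal torsional parameters -> full chain coordinates.
# theta is realized exactly by construction; tau1/tau2 are the backbone
# torsions PA-O3A-PB-O3B and O3A-PB-O3B-PG, rho_A/rho_G the rotations of the
# alpha/gamma groups about their bridging bonds.
embed_internal <- function(theta, tau1, tau2, rho_A, rho_G, spec) {
  rb <- spec$r_bridge; rt <- spec$r_term
  aO <- spec$ang_OPO; aP <- spec$ang_POP
  th <- theta * DEG
  PB <- c(0, 0, 0)
  O3B <- c(rb, 0, 0)
  PG <- O3B + rb * c(-cos(th), sin(th), 0)
  O3A <- place_atom(PG, O3B, PB, rb, aO, tau2)
  PA <- place_atom(O3B, PB, O3A, rb, aP, tau1)
  O5p <- place_atom(PB, O3A, PA, rb, aO, rho_A)
  ta <- tetrahedral_pair(unitv(O3A - PA), unitv(O5p - PA), aO)
  O1A <- PA + rt * ta[[1L]]
  O2A <- PA + rt * ta[[2L]]
  tb <- tetrahedral_pair(unitv(O3A - PB), unitv(O3B - PB), aO)
  O1B <- PB + rt * tb[[1L]]
  O2B <- PB + rt * tb[[2L]]
  O1G <- place_atom(PB, O3B, PG, rt, aO, rho_G)
  tg <- tetrahedral_pair(unitv(O3B - PG), unitv(O1G - PG), aO)
  O2G <- PG + rt * tg[[1L]]
  O3G <- PG + rt * tg[[2L]]
  coords <- rbind(PA = PA, PB = PB, PG = PG,
                  O1A = O1A, O2A = O2A, O3A = O3A,
                  O1B = O1B, O2B = O2B, O3B = O3B,
                  O1G = O1G, O2G = O2G, O3G = O3G,
                  "O5'" = O5p)
  coords
}

# residuals of the targeted descriptors for a parameter vector
embed_residuals <- function(p, spec, targets) {
  co <- embed_internal(spec$theta_bridge, p[1L], p[2L], p[3L], p[4L], spec)
  ch <- phosphate_chain(co, check = FALSE)
  de <- compute_descriptors(ch)
  r <- numeric(0)
  if ("d" %in% targets) r <- c(r, (de$d_PA_PG - spec$d_PA_PG) * 100)
  if ("psi_ab" %in% targets) r <- c(r, angle_diff(de$psi_ab, spec$psi_ab))
  if ("psi_bg" %in% targets) r <- c(r, angle_diff(de$psi_bg, spec$psi_bg))
  if ("psi_ag" %in% targets) r <- c(r, angle_diff(de$psi_ag, spec$psi_ag))
  r
}

# Levenberg-Marquardt on the torsional parameters with finite-difference
# Jacobian. Small, dense (4 params, <= 4 residuals) and fast enough to call
# per trajectory frame.
lm_solve <- function(p0, fn, tol = 1e-9, max_iter = 60L) {
  p <- p0
  lambda <- 1e-3
  r <- fn(p)
  cost <- sum(r^2)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    jac <- matrix(0, length(r), length(p))
    h <- 1e-5
    for (j in seq_along(p)) {
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      jac[, j] <- (fn(pp) - fn(pm)) / (2 * h)
    }
    repeat {
      a <- crossprod(jac) + lambda * diag(ncol(jac))
      step <- tryCatch(solve(a, crossprod(jac, r)), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; if (lambda > 1e8) break; next }
      pn <- p - as.numeric(step)
      rn <- fn(pn)
      cn <- sum(rn^2)
      if (cn < cost) {
        p <- pn; r <- rn; cost <- cn
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
    if (lambda > 1e8) break
  }
  list(par = p, resid = r, converged = max(abs(r)) < tol)
}

#' Embed a chain specification into 3D coordinates
#'
#' Builds a triphosphate chain whose measured descriptors reproduce the
#' spec's targets: the bridge angle is realized exactly by construction, the
#' PA-PG distance and any requested dihedrals are solved for via
#' Levenberg-Marquardt on the four free torsional parameters of the chain,
#' from a small grid of deterministic starting points.
#'
#' @param spec a [chain_spec()].
#' @param init optional numeric(4) warm start `(tau1, tau2, rho_A, rho_G)`
#'   in degrees, e.g. the solution of the previous trajectory frame.
#' @param tol maximal residual (Angstrom*100 / degrees) accepted, default 1e-7.
#' @return a [phosphate_chain()] with attribute `params` carrying the solved
#'   torsional parameters.
#' @export
embed_chain <- function(spec, init = NULL, tol = 1e-7) {
  stopifnot(inherits(spec, "chain_spec"))
  targets <- c("d",
               if (!is.null(spec$psi_ab)) "psi_ab",
               if (!is.null(spec$psi_bg)) "psi_bg",
               if (!is.null(spec$psi_ag)) "psi_ag")
  # trial parameter sets may pass through degenerate (collinear) geometry;
  # give those an effectively infinite residual so the step is rejected
  fn <- function(p) {
    tryCatch(embed_residuals(p, spec, targets),
             error = function(e) rep(1e8, length(targets)))
  }
  starts <- list()
  if (!is.null(init)) starts <- list(init)
  for (t1 in c(180, 60, -60, 120)) {
    for (t2 in c(180, 60, -60)) {
      starts[[length(starts) + 1L]] <- c(t1, t2, 60, 60)
      starts[[length(starts) + 1L]] <- c(t1, t2, -60, 150)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- lm_solve(s, fn, tol = tol)
    if (is.null(best) || sum(fit$resid^2) < sum(best$resid^2)) best <- fit
    if (fit$converged) { best <- fit; break }
  }
  if (!best$converged) {
    stop(sprintf(
      "infeasible geometry: no embedding reaches the requested descriptors (residual %.3g)",
      max(abs(best$resid))), call. = FALSE)
  }
  p <- best$par
  coords <- embed_internal(spec$theta_bridge, p[1L], p[2L], p[3L], p[4L], spec)
  ch <- phosphate_chain(coords, source = "embedded", check = FALSE)
  attr(ch, "params") <- p
  ch
}
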