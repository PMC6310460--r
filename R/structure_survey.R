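# Comparative survey of P-loop NTPase structures: screen PDB/mmCIF files for
# Mg-bound NTP-like ligands near a Lys residue, map analog atoms onto the
# canonical triphosphate frame, measure chain geometry, and characterize the
# occupant of the AG site (the locus between alpha- and gamma-phosphates
# taken by the activating K+/Na+ ion, Arg/Lys finger, or a water molecule).

# gamma-phosphate mimic moieties: metal-fluoride chemical IDs
MIMIC_MOIETIES <- c("ALF", "AF3", "MGF", "BEF")

#' Ligand atlas: chemical IDs and their mapping onto the triphosphate frame
#'
#' For each supported RCSB chemical ID, maps ligand atom names to canonical
#' chain labels and records the analog class. Substituted bridge/terminal
#' atoms of non-hydrolyzable analogs are mapped onto the oxygen slot they
#' replace and flagged as mimic atoms (imido N3B of AMP-PNP/GMP-PNP,
#' methylene C3B of AMP-PCP/GMP-PCP, the gamma-thio S1G of ATP-gamma-S /
#' GTP-gamma-S). Metal-fluoride moieties (AlF4-, AlF3, MgF3-, BeF3-) paired
#' with an NDP are transition-state mimics: the central Al/Be/Mg atom proxies
#' PG, the fluorines proxy the gamma oxygens.
#'
#' ATP-gamma-S appears both under its dictionary ID `AGS` and under the alias
#' `ASP` used in some derived lists.
#'
#' @return data.frame with columns `ligand`, `class` (`substrate`, `product`,
#'   `non_hydrolyzable`), `atom`, `label`, `mimic`.
#' @export
ligand_atlas <- function() {
  std <- c(PA = "PA", PB = "PB", PG = "PG",
           O1A = "O1A", O2A = "O2A", O3A = "O3A",
           O1B = "O1B", O2B = "O2B", O3B = "O3B",
           O1G = "O1G", O2G = "O2G", O3G = "O3G",
           "O5'" = "O5'")
  row <- function(lig, class, map, mimic_atoms = character(0)) {
    data.frame(ligand = lig, class = class, atom = names(map),
               label = unname(map), mimic = names(map) %in% mimic_atoms,
               stringsAsFactors = FALSE)
  }
  ntp_sub <- function(sub_atom, slot) {
    m <- std
    names(m)[match(slot, m)] <- sub_atom
    m
  }
  ndp <- std[!std %in% c("PG", "O1G", "O2G", "O3G")]
  rbind(
    row("ATP", "substrate", std),
    row("GTP", "substrate", std),
    row("ADP", "product", ndp),
    row("GDP", "product", ndp),
    row("ANP", "non_hydrolyzable", ntp_sub("N3B", "O3B"), "N3B"),
    row("GNP", "non_hydrolyzable", ntp_sub("N3B", "O3B"), "N3B"),
    row("ACP", "non_hydrolyzable", ntp_sub("C3B", "O3B"), "C3B"),
    row("GCP", "non_hydrolyzable", ntp_sub("C3B", "O3B"), "C3B"),
    row("AGS", "non_hydrolyzable", ntp_sub("S1G", "O1G"), "S1G"),
    row("ASP", "non_hydrolyzable", ntp_sub("S1G", "O1G"), "S1G"),
    row("GSP", "non_hydrolyzable", ntp_sub("S1G", "O1G"), "S1G")
  )
}

# atom mapping for a metal-fluoride gamma mimic: centre -> PG, F -> gamma-O
mimic_map <- function(moiety) {
  centre <- switch(moiety, ALF = "AL", AF3 = "AL", MGF = "MG", BEF = "BE")
  nf <- if (moiety == "ALF") 4L else 3L
  stats::setNames(c("PG", GAMMA_TERMINAL, if (nf == 4L) "F4G")[seq_len(nf + 1L)],
                  c(centre, paste0("F", seq_len(nf))))
}

# monovalent-cation residue names in structure files -> species labels
CATION_RESNAMES <- c(K = "K", Na = "NA", Rb = "RB", NH4 = "NH4", Cs = "CS")

#' Screen a structure file for P-loop-bound Mg-NTP-like ligand sites
#'
#' A candidate site is a ligand instance whose chemical ID is in the atlas,
#' with an Mg2+ ion within `mg_cutoff` of any phosphate oxygen and at least
#' one Lys NZ within `lys_cutoff` of any phosphate oxygen (the signature of
#' P-loop binding). NDP ligands qualify only through a nearby metal-fluoride
#' moiety, which also promotes their class to `transition_state`. Every
#' excluded ligand instance gets exactly one logged reason.
#'
#' @param path PDB or mmCIF file.
#' @param atlas ligand atlas (default [ligand_atlas()]).
#' @param mg_cutoff Mg-presence cutoff, Angstrom (default 4; covers
#'   outer-sphere coordination).
#' @param lys_cutoff Lys NZ contact cutoff, Angstrom (default 4, salt-bridge
#'   range).
#' @param mimic_cutoff max distance between the NDP O3B (or PB) and the mimic
#'   centre for pairing a metal fluoride with its NDP (default 4).
#' @param model model number passed to [read_structure()].
#' @return list with `candidates` (list of candidate descriptions) and
#'   `exclusions` (data.frame `ligand`, `chain`, `resseq`, `reason`).
#' @export
screen_structure <- function(path, atlas = ligand_atlas(), mg_cutoff = 4,
                             lys_cutoff = 4, mimic_cutoff = 4, model = 1L) {
  df <- read_structure(path, model = model)
  lig_ids <- unique(atlas$ligand)
  inst <- unique(df[df$resname %in% lig_ids, c("resname", "chain", "resseq")])
  candidates <- list()
  excl <- list()
  note <- function(lig, chain, resseq, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(ligand = lig, chain = chain,
                                             resseq = resseq, reason = reason,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(inst))) {
    lig <- inst$resname[i]; ch <- inst$chain[i]; rs <- inst$resseq[i]
    sel <- df$resname == lig & df$chain == ch & df$resseq == rs
    amap <- atlas[atlas$ligand == lig, ]
    sub <- df[sel, ]
    m <- match(sub$atom, amap$atom)
    mapped <- sub[!is.na(m), ]
    labels <- amap$label[m[!is.na(m)]]
    mims <- amap$mimic[m[!is.na(m)]]
    if (anyDuplicated(labels)) {
      note(lig, ch, rs, "duplicate mapped atoms")
      next
    }
    coords <- as.matrix(mapped[, c("x", "y", "z")])
    rownames(coords) <- labels
    class <- amap$class[1L]
    mimic_res <- NULL
    extra_gamma <- NULL
    if (class == "product") {
      # look for a gamma mimic moiety whose centre sits on the O3B side
      anchor <- if ("O3B" %in% labels) coords["O3B", ] else
        if ("PB" %in% labels) coords["PB", ] else NULL
      found <- FALSE
      if (!is.null(anchor)) {
        mo <- df[df$resname %in% MIMIC_MOIETIES, ]
        if (nrow(mo)) {
          minst <- unique(mo[, c("resname", "chain", "resseq")])
          for (k in seq_len(nrow(minst))) {
            msel <- mo$resname == minst$resname[k] & mo$chain == minst$chain[k] &
              mo$resseq == minst$resseq[k]
            mm <- mimic_map(minst$resname[k])
            matoms <- mo[msel, ]
            ctr <- matoms[matoms$atom %in% names(mm)[mm == "PG"], ]
            if (nrow(ctr) != 1L) next
            if (vnorm(as.numeric(ctr[, c("x", "y", "z")]) - anchor) >
                mimic_cutoff) next
            mmatch <- match(matoms$atom, names(mm))
            mc <- as.matrix(matoms[!is.na(mmatch), c("x", "y", "z")])
            rownames(mc) <- mm[mmatch[!is.na(mmatch)]]
            # the 4th F of AlF4- has no gamma-oxygen slot but still counts
            # for "distance to the closest F"
            extra_gamma <- mc[rownames(mc) == "F4G", , drop = FALSE]
            mc <- mc[rownames(mc) != "F4G", , drop = FALSE]
            coords <- rbind(coords, mc)
            labels <- rownames(coords)
            mims <- c(mims, rep(TRUE, nrow(mc)))
            mimic_res <- minst[k, ]
            found <- TRUE
            break
          }
        }
      }
      if (!found) {
        note(lig, ch, rs, "NDP without gamma-phosphate mimic")
        next
      }
      class <- "transition_state"
    }
    oxy <- coords[intersect(rownames(coords),
                            unique(c(ALPHA_OXYGENS, BETA_OXYGENS,
                                     GAMMA_OXYGENS))), , drop = FALSE]
    if (nrow(oxy) == 0L) {
      note(lig, ch, rs, "no mapped phosphate oxygens")
      next
    }
    mindist_to <- function(pts) {
      if (nrow(pts) == 0L) return(Inf)
      min(apply(as.matrix(pts[, c("x", "y", "z")]), 1L, function(p)
        min(sqrt(rowSums(sweep(oxy, 2L, p)^2)))))
    }
    mg <- df[df$resname == "MG" & df$record == "HETATM", ]
    if (mindist_to(mg) > mg_cutoff) {
      note(lig, ch, rs, sprintf("no Mg within %.1f A of phosphate oxygens",
                                mg_cutoff))
      next
    }
    lys_nz <- df[df$resname == "LYS" & df$atom == "NZ", ]
    if (mindist_to(lys_nz) > lys_cutoff) {
      note(lig, ch, rs, sprintf("no Lys NZ within %.1f A of phosphate oxygens",
                                lys_cutoff))
      next
    }
    is_mimic <- stats::setNames(mims, rownames(coords))
    candidates[[length(candidates) + 1L]] <- list(
      path = path, structure = df, ligand = lig, chain = ch, resseq = rs,
      class = class, coords = coords, is_mimic = is_mimic,
      mimic_res = mimic_res, extra_gamma = extra_gamma,
      source = sprintf("%s %s/%s/%d", basename(path), lig, ch, rs))
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(ligand = character(0), chain = character(0),
               resseq = integer(0), reason = character(0))
  list(candidates = candidates, exclusions = exclusions)
}

#' Measure a candidate ligand site
#'
#' Builds the phosphate chain (with mimic proxies: the Al/Be/Mg centre as PG,
#' the fluorines as gamma oxygens), computes the shape descriptors, records
#' the Table-3-style distances, and determines the AG-site occupant: the
#' nearest qualifying entity within `ag_cutoff` of a gamma-oxygen (or F),
#' searching monovalent cations first, then water oxygens, then Arg/Lys
#' side-chain nitrogens.
#'
#' @param candidate one element of `screen_structure()$candidates`.
#' @param ag_cutoff cation-coordination range for the AG occupant search,
#'   Angstrom (default 3.5).
#' @param lys_cutoff Lys contact cutoff reported in the record (default 4).
#' @return object of class `survey_record`: structure/ligand identifiers,
#'   `class`, `descriptors` (or `NULL` with `incomplete = TRUE`), `occupant`
#'   (`species`, `dist_alpha`, `dist_gamma`) and `lys_contact`.
#' @export
measure_structure <- function(candidate, ag_cutoff = 3.5, lys_cutoff = 4) {
  co <- candidate$coords
  chain <- phosphate_chain(co, is_mimic = candidate$is_mimic,
                           source = candidate$source, check = FALSE)
  desc <- NULL
  incomplete <- !chain$complete
  if (!incomplete) desc <- compute_descriptors(chain)
  df <- candidate$structure
  # Table-3-style occupant distances are measured to the terminal oxygens
  # of the respective phosphate (bridging oxygens are shared between two
  # phosphates and are excluded here; the per-ion r_A/r_B/r_G distances of
  # the trajectory records do include them)
  gamma_atoms <- co[intersect(rownames(co), GAMMA_TERMINAL), , drop = FALSE]
  if (!is.null(candidate$extra_gamma) && nrow(candidate$extra_gamma)) {
    gamma_atoms <- rbind(gamma_atoms, candidate$extra_gamma)
  }
  alpha_atoms <- co[intersect(rownames(co), ALPHA_TERMINAL), , drop = FALSE]
  mind <- function(p, atoms) {
    if (nrow(atoms) == 0L) return(Inf)
    min(sqrt(rowSums(sweep(atoms, 2L, p)^2)))
  }
  occupant <- list(species = "none", dist_alpha = NA_real_,
                   dist_gamma = NA_real_)
  pools <- list(
    cation = df[df$resname %in% CATION_RESNAMES & df$record == "HETATM", ],
    water = df[df$resname %in% c("HOH", "WAT") & df$element != "H", ],
    arglys = df[(df$resname == "ARG" & df$atom %in% c("NH1", "NH2", "NE")) |
                  (df$resname == "LYS" & df$atom == "NZ"), ])
  # exclude atoms of the ligand/mimic themselves
  for (nm in names(pools)) {
    p <- pools[[nm]]
    if (nrow(p) == 0L) next
    dg <- apply(as.matrix(p[, c("x", "y", "z")]), 1L, mind,
                atoms = gamma_atoms)
    p <- p[dg <= ag_cutoff, , drop = FALSE]
    dg <- dg[dg <= ag_cutoff]
    if (nrow(p) == 0L) next
    best <- which.min(dg)
    pos <- as.numeric(p[best, c("x", "y", "z")])
    species <- switch(nm,
      cation = names(CATION_RESNAMES)[match(p$resname[best], CATION_RESNAMES)],
      water = "water",
      arglys = if (p$resname[best] == "ARG") "Arg-guanidinium" else "Lys-NZ")
    occupant <- list(species = species,
                     dist_alpha = unname(mind(pos, alpha_atoms)),
                     dist_gamma = unname(dg[best]))
    break
  }
  lys_nz <- df[df$resname == "LYS" & df$atom == "NZ", ]
  oxy <- co[intersect(rownames(co), unique(c(ALPHA_OXYGENS, BETA_OXYGENS,
                                             GAMMA_OXYGENS))), ,
            drop = FALSE]
  lys_contact <- nrow(lys_nz) > 0L && nrow(oxy) > 0L &&
    min(apply(as.matrix(lys_nz[, c("x", "y", "z")]), 1L, mind,
              atoms = oxy)) <= lys_cutoff
  structure(list(structure_id = basename(candidate$path),
                 ligand = candidate$ligand, chain = candidate$chain,
                 resseq = candidate$resseq, class = candidate$class,
                 descriptors = desc, incomplete = incomplete,
                 occupant = occupant, lys_contact = lys_contact),
            class = "survey_record")
}

#' @export
print.survey_record <- function(x, ...) {
  cat(sprintf("<survey_record> %s %s/%s/%d [%s]\n", x$structure_id, x$ligand,
              x$chain, x$resseq, x$class))
  if (!is.null(x$descriptors)) print(x$descriptors)
  cat(sprintf("AG occupant: %s (d_alpha %.2f, d_gamma %.2f)\n",
              x$occupant$species, x$occupant$dist_alpha,
              x$occupant$dist_gamma))
  invisible(x)
}

#' Survey records as a Table-3-style data frame
#'
#' @param records list of `survey_record`s.
#' @return data.frame, one row per record.
#' @export
survey_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    d <- r$descriptors
    data.frame(structure = r$structure_id, ligand = r$ligand,
               chain = r$chain, resseq = r$resseq, class = r$class,
               ag_occupant = r$occupant$species,
               dist_alpha = r$occupant$dist_alpha,
               dist_gamma = r$occupant$dist_gamma,
               d_PA_PG = if (is.null(d)) NA_real_ else d$d_PA_PG,
               theta_bridge = if (is.null(d)) NA_real_ else d$theta_bridge,
               psi_ab = if (is.null(d)) NA_real_ else d$psi_ab,
               psi_bg = if (is.null(d)) NA_real_ else d$psi_bg,
               psi_ag = if (is.null(d)) NA_real_ else d$psi_ag,
               mimic = if (is.null(d)) NA else d$mimic,
               lys_contact = r$lys_contact,
               stringsAsFactors = FALSE)
  }))
}

#' Superpose P-loop backbones (Kabsch)
#'
#' Least-squares rigid superposition of the backbone N, CA, C, O atoms of the
#' given residue ranges (the P-loop motif with its flanking beta-strand and
#' alpha-helix) of a mobile structure onto a reference.
#'
#' @param mobile,reference atom data.frames from [read_structure()].
#' @param mobile_range,reference_range integer vectors of author residue
#'   numbers defining the matched ranges (same length).
#' @param mobile_chain,reference_chain chain identifiers (default: first
#'   chain present).
#' @return list with `R`, `t`, `rmsd` and `n_atoms`; apply the transform to
#'   an n x 3 matrix `x` as `x %*% t(R) + t`.
#' @export
superpose_ploops <- function(mobile, reference, mobile_range, reference_range,
                             mobile_chain = NULL, reference_chain = NULL) {
  stopifnot(length(mobile_range) == length(reference_range))
  bb <- c("N", "CA", "C", "O")
  pick <- function(df, rng, ch) {
    if (is.null(ch)) ch <- df$chain[df$record == "ATOM"][1L]
    sel <- df[df$record == "ATOM" & df$chain == ch & df$resseq %in% rng &
                df$atom %in% bb, ]
    sel[order(match(sel$resseq, rng), match(sel$atom, bb)), ]
  }
  a <- pick(mobile, mobile_range, mobile_chain)
  b <- pick(reference, reference_range, reference_chain)
  key_a <- paste(match(a$resseq, mobile_range), a$atom)
  key_b <- paste(match(b$resseq, reference_range), b$atom)
  common <- intersect(key_a, key_b)
  if (length(common) < 3L) {
    stop("fewer than 3 paired backbone atoms in the specified ranges",
         call. = FALSE)
  }
  ma <- as.matrix(a[match(common, key_a), c("x", "y", "z")])
  mb <- as.matrix(b[match(common, key_b), c("x", "y", "z")])
  fit <- kabsch(ma, mb)
  fit$n_atoms <- length(common)
  fit
}

#' Overlay point sets for conformational heat maps
#'
#' Splits survey records into analog classes and extracts their
#' (PA-PG distance, bridge angle) pairs, ready for the `overlays` argument of
#' [build_heatmap()].
#'
#' @param records list of `survey_record`s.
#' @return named list of data.frames with columns `d`, `theta` (classes
#'   `transition_state` and `non_hydrolyzable`; substrates under
#'   `substrate` when present).
#' @export
collect_overlay_sets <- function(records) {
  recs <- Filter(function(r) !is.null(r$descriptors), records)
  classes <- unique(vapply(recs, function(r) r$class, character(1)))
  out <- list()
  for (cl in classes) {
    sub <- Filter(function(r) r$class == cl, recs)
    out[[cl]] <- data.frame(
      d = vapply(sub, function(r) r$descriptors$d_PA_PG, numeric(1)),
      theta = vapply(sub, function(r) r$descriptors$theta_bridge, numeric(1)))
  }
  out
}
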