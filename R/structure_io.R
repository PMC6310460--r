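# Minimal readers for PDB and mmCIF coordinate files and a writer for the
# small fixture/trajectory PDBs the package generates. Only the atom-level
# information the survey needs is parsed: record type, atom name, altloc,
# residue name/number, chain, coordinates, occupancy, element. No R-level
# structure parser ships with this environment, hence the hand-rolled
# fixed-column implementation.

#' Read atoms from a PDB or mmCIF file
#'
#' Dispatches on file extension (`.cif`/`.mmcif` vs anything else). By
#' default only the first model of a multi-model file is returned (X-ray
#' focus); set `model = NA` for all models. Alternate locations are reduced
#' to the highest-occupancy altloc per atom (ties broken towards altloc "A").
#'
#' @param path file path.
#' @param model model number to keep (default 1) or `NA` for all.
#' @return data.frame with columns `record`, `serial`, `atom`, `altloc`,
#'   `resname`, `chain`, `resseq`, `x`, `y`, `z`, `occ`, `element`, `model`.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("cif", "mmcif")) read_mmcif_atoms(path)
        else read_pdb_atoms(path)
  if (nrow(df) == 0L) {
    stop(sprintf("format error: no atom records parsed from %s", path),
         call. = FALSE)
  }
  if (!is.na(model)) {
    keep_model <- if (model %in% df$model) model else min(df$model)
    df <- df[df$model == keep_model, , drop = FALSE]
  }
  resolve_altlocs(df)
}

read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model <- 1L
  cur <- 1L
  recs <- vector("list", length(lines))
  n <- 0L
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (startsWith(tag, "MODEL")) {
      cur <- suppressWarnings(as.integer(substr(ln, 11L, 14L)))
      if (is.na(cur)) cur <- model + 1L
      model <- cur
      next
    }
    if (tag == "ATOM  " || tag == "HETATM") {
      n <- n + 1L
      recs[[n]] <- data.frame(
        record = trimws(tag),
        serial = suppressWarnings(as.integer(substr(ln, 7L, 11L))),
        atom = trimws(substr(ln, 13L, 16L)),
        altloc = substr(ln, 17L, 17L),
        resname = trimws(substr(ln, 18L, 20L)),
        chain = substr(ln, 22L, 22L),
        resseq = suppressWarnings(as.integer(substr(ln, 23L, 26L))),
        x = as.numeric(substr(ln, 31L, 38L)),
        y = as.numeric(substr(ln, 39L, 46L)),
        z = as.numeric(substr(ln, 47L, 54L)),
        occ = suppressWarnings(as.numeric(substr(ln, 55L, 60L))),
        element = trimws(substr(ln, 77L, 78L)),
        model = model,
        stringsAsFactors = FALSE)
    }
  }
  if (n == 0L) return(data.frame())
  df <- do.call(rbind, recs[seq_len(n)])
  df$occ[is.na(df$occ)] <- 1
  df$altloc[df$altloc == " "] <- ""
  # fall back to the first letter of the atom name when the element column
  # is absent (common in minimal files)
  noel <- df$element == ""
  df$element[noel] <- toupper(gsub("[^A-Za-z].*$", "",
                                   gsub("^[0-9]+", "", df$atom[noel])))
  df
}

read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the _atom_site loop
  i <- 1L
  n <- length(lines)
  fields <- character(0)
  rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      f <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        f <- c(f, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(f) && all(startsWith(f, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", f)
        k <- j
        while (k <= n) {
          l <- trimws(lines[k])
          if (l == "" || startsWith(l, "#") || startsWith(l, "loop_") ||
              startsWith(l, "_") || startsWith(l, "data_")) break
          rows[[length(rows) + 1L]] <- l
          k <- k + 1L
        }
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) return(data.frame())
  split_cif_row <- function(l) {
    # whitespace-separated tokens; single/double-quoted tokens kept whole
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", l)[[1L]]
    tok <- regmatches(l, list(m))[[1L]]
    gsub("^['\"]|['\"]$", "", tok)
  }
  mat <- t(vapply(rows, split_cif_row, character(length(fields))))
  colnames(mat) <- fields
  getf <- function(nm, alt = NULL, default = NA) {
    if (nm %in% fields) return(mat[, nm])
    if (!is.null(alt) && alt %in% fields) return(mat[, alt])
    rep(default, nrow(mat))
  }
  df <- data.frame(
    record = getf("group_PDB", default = "ATOM"),
    serial = suppressWarnings(as.integer(getf("id"))),
    atom = getf("label_atom_id", "auth_atom_id"),
    altloc = getf("label_alt_id", default = ""),
    resname = getf("auth_comp_id", "label_comp_id"),
    chain = getf("auth_asym_id", "label_asym_id"),
    resseq = suppressWarnings(as.integer(getf("auth_seq_id", "label_seq_id"))),
    x = as.numeric(getf("Cartn_x")),
    y = as.numeric(getf("Cartn_y")),
    z = as.numeric(getf("Cartn_z")),
    occ = suppressWarnings(as.numeric(getf("occupancy", default = "1"))),
    element = getf("type_symbol", default = ""),
    model = suppressWarnings(as.integer(getf("pdbx_PDB_model_num",
                                             default = "1"))),
    stringsAsFactors = FALSE)
  df$altloc[df$altloc %in% c(".", "?")] <- ""
  df$occ[is.na(df$occ)] <- 1
  df$model[is.na(df$model)] <- 1L
  df
}

# keep one altloc per atom: the highest-occupancy one, ties towards "A"
resolve_altlocs <- function(df) {
  has_alt <- df$altloc != ""
  if (!any(has_alt)) return(df)
  key <- paste(df$model, df$chain, df$resseq, df$resname, df$atom, sep = "|")
  keep <- rep(TRUE, nrow(df))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) <= 1L) next
    occ <- df$occ[idx]
    cand <- idx[occ == max(occ)]
    best <- cand[order(df$altloc[cand])][1L]
    keep[idx] <- FALSE
    keep[best] <- TRUE
  }
  df[keep, , drop = FALSE]
}

pdb_atom_line <- function(record, serial, atom, resname, chain, resseq,
                          xyz, occ = 1, b = 0, element = "") {
  # atom-name column convention: 1-2 char element names start in column 14
  name <- if (nchar(atom) >= 4L) substr(atom, 1L, 4L) else sprintf(" %-3s", atom)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, name, "", substr(resname, 1L, 3L),
          chain, resseq %% 10000L, "", xyz[1L], xyz[2L], xyz[3L], occ, b,
          toupper(element))
}

#' Write a set of atoms as a minimal PDB file
#'
#' @param atoms data.frame with columns `record`, `atom`, `resname`, `chain`,
#'   `resseq`, `x`, `y`, `z` and optionally `element`, `occ`.
#' @param path output path.
#' @param model optional model number (wraps records in MODEL/ENDMDL).
#' @param append append to an existing file (used by the trajectory writer).
#' @export
write_pdb <- function(atoms, path, model = NULL, append = FALSE) {
  lines <- character(0)
  if (!is.null(model)) lines <- sprintf("MODEL %8d", model)
  el <- if ("element" %in% names(atoms)) atoms$element else
    gsub("[0-9'].*$", "", atoms$atom)
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, pdb_atom_line(atoms$record[i], i, atoms$atom[i],
                                    atoms$resname[i], atoms$chain[i],
                                    atoms$resseq[i],
                                    c(atoms$x[i], atoms$y[i], atoms$z[i]),
                                    occ = occ[i], element = el[i]))
  }
  if (!is.null(model)) lines <- c(lines, "ENDMDL")
  if (is.null(model) && !append) lines <- c(lines, "END")
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
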