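#' Read ligand poses from an SDF or MOL2 file
#'
#' Reads every record of a multi-record structure file into a list of
#' [pose()] objects, preserving file order and within-record atom order.
#' Docking scores travel in a data field named `SCORE_PKD` (SDF) or in a
#' `# SCORE_PKD <value>` comment line preceding the molecule record
#' (MOL2); records without the field get `NA` scores, as is usual for
#' crystallographic reference poses.
#'
#' Dialects: SDF is V2000 (aromatic bonds encoded as bond type 4, formal
#' charges via `M  CHG`); MOL2 is SYBYL (aromatic atoms/bonds via `.ar`
#' types, the per-atom charge column read as formal charge rounded to the
#' nearest integer).
#'
#' @param path File path.
#' @param format `"sdf"` or `"mol2"`; default guessed from the extension.
#' @return List of `pose` objects.
#' @seealso [write_structures()]
#' @export
read_structures <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("sdf", "mol2"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  recs <- if (format == "sdf") split_sdf(lines) else split_mol2(lines)
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    out[[k]] <- tryCatch(
      if (format == "sdf") parse_sdf_record(recs[[k]])
      else parse_mol2_record(recs[[k]]),
      error = function(e) {
        stop(sprintf("record %d of %s: %s", k, path, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  out
}

#' Write poses to an SDF or MOL2 file
#'
#' Inverse of [read_structures()]; finite scores are written to the
#' `SCORE_PKD` field/comment. Round trips preserve the chemical graph
#' exactly and coordinates to the 1e-4 Angstrom precision of the formats.
#'
#' @param poses A `pose` or list of poses.
#' @param path Output file path.
#' @param format `"sdf"` or `"mol2"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structures <- function(poses, path, format = guess_format(path)) {
  format <- match.arg(format, c("sdf", "mol2"))
  if (inherits(poses, "pose")) poses <- list(poses)
  txt <- unlist(lapply(poses, if (format == "sdf") format_sdf_record
                       else format_mol2_record))
  writeLines(txt, path)
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "sd", "mol")) "sdf"
  else if (ext == "mol2") "mol2"
  else stop("cannot guess format from extension: ", path, call. = FALSE)
}

# ---- SDF (V2000) ----------------------------------------------------------

split_sdf <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  Filter(function(r) any(nzchar(trimws(r))), recs)
}

sdf_charge_from_code <- function(code) {
  # V2000 atom-block charge codes; 4 (doublet radical) maps to 0.
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
    `6` = -2L, `7` = -3L)[as.character(code)]
}

parse_sdf_record <- function(rec) {
  if (length(rec) < 4) stop("truncated record header")
  name <- trimws(rec[1])
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line")
  if (length(rec) < 4 + na + nb) stop("truncated atom/bond block")
  atom_lines <- rec[4 + seq_len(na)]
  tok <- strsplit(trimws(atom_lines), "\\s+")
  coords <- t(vapply(tok, function(t) as.numeric(t[1:3]), numeric(3)))
  if (any(is.na(coords))) stop("malformed atom coordinates")
  element <- vapply(tok, function(t) t[4], character(1))
  bad <- setdiff(unique(element), names(atomic_masses()))
  if (length(bad) > 0) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  code <- vapply(tok, function(t) {
    if (length(t) >= 6) suppressWarnings(as.integer(t[6])) else 0L
  }, integer(1))
  code[is.na(code)] <- 0L
  charge <- sdf_charge_from_code(code)
  bonds <- NULL
  if (nb > 0) {
    bl <- rec[4 + na + seq_len(nb)]
    bt <- strsplit(trimws(bl), "\\s+")
    bm <- t(vapply(bt, function(t) as.integer(t[1:3]), integer(3)))
    if (any(is.na(bm))) stop("malformed bond block")
    bonds <- tibble::tibble(i = bm[, 1], j = bm[, 2],
                            order = ifelse(bm[, 3] == 4L, 1L, bm[, 3]),
                            aromatic = bm[, 3] == 4L)
  }
  rest <- rec[-seq_len(4 + na + nb)]
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines) > 0) {
    charge[] <- 0L
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      n <- f[1]
      for (p in seq_len(n)) {
        charge[f[2 * p]] <- f[2 * p + 1]
      }
    }
  }
  aromatic_atom <- rep(FALSE, na)
  if (!is.null(bonds) && any(bonds$aromatic)) {
    aromatic_atom[unique(c(bonds$i[bonds$aromatic],
                           bonds$j[bonds$aromatic]))] <- TRUE
  }
  score <- NA_real_
  tag <- grep("^>.*<SCORE_PKD>", rest)
  if (length(tag) == 1 && length(rest) > tag[1]) {
    val <- trimws(rest[tag[1] + 1])
    val <- sub("^pKd=", "", val)
    score <- suppressWarnings(as.numeric(val))
  }
  mol <- molecule(
    atoms = tibble::tibble(element = element, charge = charge,
                           aromatic = aromatic_atom),
    bonds = bonds, name = if (nzchar(name)) name else "unnamed")
  pose(mol, coords, score)
}

format_sdf_record <- function(p) {
  mol <- p$mol
  na <- n_atoms(mol); nb <- nrow(mol$bonds)
  out <- c(mol$name, "  poseguide", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (a in seq_len(na)) {
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      p$coords[a, 1], p$coords[a, 2], p$coords[a, 3],
      mol$atoms$element[a]))
  }
  for (b in seq_len(nb)) {
    typ <- if (mol$bonds$aromatic[b]) 4L else mol$bonds$order[b]
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds$i[b], mol$bonds$j[b], typ))
  }
  charged <- which(mol$atoms$charge != 0L)
  if (length(charged) > 0) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp,
                                          mol$atoms$charge[grp]),
                                  collapse = "")))
    }
  }
  out <- c(out, "M  END")
  if (is.finite(p$score)) {
    out <- c(out, "> <SCORE_PKD>", format(p$score, digits = 10), "")
  }
  c(out, "$$$$")
}

# ---- MOL2 (SYBYL) ---------------------------------------------------------

split_mol2 <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no @<TRIPOS>MOLECULE record found",
                                call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(k) {
    # comment lines immediately preceding the record (e.g. SCORE_PKD)
    # belong to it
    lead <- starts[k]
    while (lead > 1 && grepl("^(#|\\s*$)", lines[lead - 1L]) &&
           (k == 1 || lead - 1L > bounds[k - 1L])) {
      lead <- lead - 1L
    }
    lines[lead:(bounds[k + 1L] - 1L)]
  })
}

sybyl_atom_type <- function(element, aromatic) {
  ifelse(aromatic, paste0(element, ".ar"),
         ifelse(element %in% c("C", "N", "O", "S", "P"),
                paste0(element, ".3"), element))
}

parse_mol2_record <- function(rec) {
  score <- NA_real_
  sc <- grep("^#\\s*SCORE_PKD\\s", rec)
  if (length(sc) > 0) {
    score <- suppressWarnings(
      as.numeric(trimws(sub("^#\\s*SCORE_PKD\\s+", "", rec[sc[1]]))))
  }
  mstart <- grep("^@<TRIPOS>MOLECULE", rec)[1]
  if (is.na(mstart)) stop("missing MOLECULE section")
  name <- trimws(rec[mstart + 1])
  counts <- as.integer(strsplit(trimws(rec[mstart + 2]), "\\s+")[[1]])
  na <- counts[1]; nb <- if (length(counts) >= 2) counts[2] else 0L
  if (is.na(na)) stop("malformed counts line")
  astart <- grep("^@<TRIPOS>ATOM", rec)[1]
  if (is.na(astart) || length(rec) < astart + na) stop("truncated ATOM block")
  tok <- strsplit(trimws(rec[astart + seq_len(na)]), "\\s+")
  coords <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  if (any(is.na(coords))) stop("malformed atom coordinates")
  types <- vapply(tok, function(t) t[6], character(1))
  element <- sub("\\..*$", "", types)
  bad <- setdiff(unique(element), names(atomic_masses()))
  if (length(bad) > 0) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  aromatic <- grepl("\\.ar$", types)
  charge <- vapply(tok, function(t) {
    if (length(t) >= 9) {
      v <- suppressWarnings(as.numeric(t[9]))
      if (is.na(v)) 0L else as.integer(round(v))
    } else 0L
  }, integer(1))
  bonds <- NULL
  if (nb > 0) {
    bstart <- grep("^@<TRIPOS>BOND", rec)[1]
    if (is.na(bstart) || length(rec) < bstart + nb) {
      stop("truncated BOND block")
    }
    bt <- strsplit(trimws(rec[bstart + seq_len(nb)]), "\\s+")
    i <- vapply(bt, function(t) as.integer(t[2]), integer(1))
    j <- vapply(bt, function(t) as.integer(t[3]), integer(1))
    typ <- vapply(bt, function(t) t[4], character(1))
    if (any(is.na(i)) || any(is.na(j))) stop("malformed bond record")
    bonds <- tibble::tibble(
      i = i, j = j,
      order = ifelse(typ %in% c("ar", "am"), 1L,
                     suppressWarnings(as.integer(typ))),
      aromatic = typ == "ar")
    if (any(is.na(bonds$order))) stop("malformed bond type")
  }
  mol <- molecule(
    atoms = tibble::tibble(element = element, charge = charge,
                           aromatic = aromatic),
    bonds = bonds, name = if (nzchar(name)) name else "unnamed")
  pose(mol, coords, score)
}

format_mol2_record <- function(p) {
  mol <- p$mol
  na <- n_atoms(mol); nb <- nrow(mol$bonds)
  out <- character()
  if (is.finite(p$score)) {
    out <- c(out, sprintf("# SCORE_PKD %s", format(p$score, digits = 10)))
  }
  out <- c(out, "@<TRIPOS>MOLECULE", mol$name,
           sprintf("%5d %5d     1     0     0", na, nb),
           "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM")
  types <- sybyl_atom_type(mol$atoms$element, mol$atoms$aromatic)
  for (a in seq_len(na)) {
    out <- c(out, sprintf(
      "%7d %-4s %9.4f %9.4f %9.4f %-6s %4d LIG %8.4f",
      a, paste0(mol$atoms$element[a], a),
      p$coords[a, 1], p$coords[a, 2], p$coords[a, 3],
      types[a], 1L, as.numeric(mol$atoms$charge[a])))
  }
  out <- c(out, "@<TRIPOS>BOND")
  for (b in seq_len(nb)) {
    typ <- if (mol$bonds$aromatic[b]) "ar" else as.character(mol$bonds$order[b])
    out <- c(out, sprintf("%6d %5d %5d %-2s",
                          b, mol$bonds$i[b], mol$bonds$j[b], typ))
  }
  out
}
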