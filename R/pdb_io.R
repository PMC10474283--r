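# PDB and multi-frame XYZ input/output.
#
# The PDB reader handles the subset relevant to ensemble analysis:
# ATOM/HETATM/MODEL/ENDMDL/TER/END records in fixed columns, with one frame
# per MODEL block (one frame if no MODEL records are present). altloc and
# insertion codes are out of scope.

.parse_atom_lines <- function(lines, line_numbers) {
  nm <- substr(lines, 13, 16)
  xs <- substr(lines, 31, 38)
  ys <- substr(lines, 39, 46)
  zs <- substr(lines, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("unparseable coordinate field at line ", line_numbers[bad[1]],
         ": ", trimws(lines[bad[1]]), call. = FALSE)
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  bad_id <- which(is.na(resid))
  if (length(bad_id) > 0)
    stop("unparseable residue id at line ", line_numbers[bad_id[1]],
         call. = FALSE)
  elem <- trimws(substr(lines, 77, 78))
  atom_name <- trimws(nm)
  elem[!nzchar(elem)] <- infer_element(atom_name[!nzchar(elem)])
  list(
    atoms = data.frame(
      serial = serial,
      atom_name = atom_name,
      element = toupper(elem),
      residue_name = trimws(substr(lines, 18, 20)),
      residue_id = resid,
      chain_id = substr(lines, 22, 22),
      stringsAsFactors = FALSE
    ),
    xyz = cbind(x, y, z, deparse.level = 0)
  )
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element columns (77-78) are absent, as in many minimized
#' model files. A short two-letter table (Cl, Br, Na, Mg, Zn, Fe, Mn, Cu, Se)
#' is consulted first; otherwise the first alphabetic character of the atom
#' name is taken. Names like `1HG1` therefore resolve to H, `CA` to C (the
#' calcium/C-alpha ambiguity is resolved in favour of carbon, the correct
#' reading inside amino-acid residues).
#'
#' @param atom_name character vector of PDB atom names (whitespace-trimmed)
#' @return character vector of element symbols
#' @export
infer_element <- function(atom_name) {
  up <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(up, 1, 2)
  ifelse(two %in% setdiff(.TWO_LETTER_ELEMENTS, "NA") & nchar(up) == 2,
         two, substr(up, 1, 1))
}

#' Parse a PDB-format string into an Ensemble
#'
#' One frame per MODEL block; a file without MODEL records yields a
#' single-frame ensemble. The element is taken from columns 77-78 when
#' present, otherwise inferred from the atom name via [infer_element()].
#' Residue identifiers are kept verbatim; nothing is renumbered.
#'
#' @param text a single string (or character vector of lines) in PDB format
#' @return an [Ensemble()]
#' @export
parse_structure <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  if (any(is_model)) {
    model_id <- cumsum(is_model)
    keep <- which(is_atom & model_id > 0)
    if (length(keep) == 0L) stop("MODEL blocks contain no atoms")
    groups <- split(keep, model_id[keep])
    counts <- lengths(groups)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("model ", names(groups)[bad], " has ", counts[bad],
           " atoms; expected ", counts[1], call. = FALSE)
    }
    first <- .parse_atom_lines(lines[groups[[1]]], groups[[1]])
    N <- nrow(first$atoms)
    coords <- array(NA_real_, c(N, 3L, length(groups)))
    coords[, , 1L] <- first$xyz
    for (k in seq_along(groups)[-1]) {
      parsed <- .parse_atom_lines(lines[groups[[k]]], groups[[k]])
      coords[, , k] <- parsed$xyz
    }
    Ensemble(Structure(first$atoms, first$xyz), coords)
  } else {
    idx <- which(is_atom)
    parsed <- .parse_atom_lines(lines[idx], idx)
    as_ensemble(Structure(parsed$atoms, parsed$xyz))
  }
}

.format_atom_name <- function(name, element) {
  # Standard PDB alignment: element right-justified in columns 13-14, so
  # single-letter-element names of <4 chars start in column 14.
  ifelse(nchar(name) >= 4L | nchar(element) == 2L,
         formatC(name, width = -4),
         paste0(" ", formatC(name, width = -3)))
}

.format_atom_lines <- function(atoms, xyz) {
  if (any(abs(xyz) >= 10000))
    stop("coordinate magnitude >= 10000 Angstrom cannot be formatted")
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L,
          .format_atom_name(atoms$atom_name, atoms$element),
          atoms$residue_name, atoms$chain_id, atoms$residue_id,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element)
}

#' Write a Structure or Ensemble as a PDB-format string
#'
#' Multi-frame ensembles produce one MODEL/ENDMDL pair per frame;
#' single-frame input produces bare ATOM records. Coordinates are written
#' with 3 decimals (the PDB precision).
#'
#' @param x a [Structure()] or [Ensemble()]
#' @return a single PDB-format string
#' @export
write_structure <- function(x) {
  ens <- as_ensemble(x)
  atoms <- ens$topology$atoms
  F <- n_frames(ens)
  frame_xyz <- function(k) matrix(ens$coords[, , k], ncol = 3L)
  if (F == 1L) {
    body <- c(.format_atom_lines(atoms, frame_xyz(1L)), "END")
  } else {
    body <- unlist(lapply(seq_len(F), function(k) {
      c(sprintf("MODEL     %4d", k),
        .format_atom_lines(atoms, frame_xyz(k)),
        "ENDMDL")
    }))
    body <- c(body, "END")
  }
  paste0(paste(body, collapse = "\n"), "\n")
}

#' Read an ensemble from a PDB or multi-frame XYZ file
#'
#' Format is chosen by extension: `.pdb` files go through
#' [parse_structure()], anything else through [parse_xyz_frames()].
#'
#' @param path file path
#' @return an [Ensemble()]
#' @export
read_ensemble <- function(path) {
  text <- readLines(path, warn = FALSE)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) parse_structure(text)
  else parse_xyz_frames(text)
}

#' Write an ensemble to a PDB or multi-frame XYZ file
#' @param x a [Structure()] or [Ensemble()]
#' @param path output path; `.pdb` selects PDB format, otherwise the XYZ
#'   dialect of [write_xyz_frames()] is used
#' @return `path`, invisibly
#' @export
write_ensemble <- function(x, path) {
  text <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) write_structure(x)
          else write_xyz_frames(x)
  writeLines(sub("\n$", "", text), path)
  invisible(path)
}

#' Parse the multi-frame XYZ dialect
#'
#' Per frame: a line `N`, a comment line `t=<ps>`, then N lines
#' `name resname resid x y z` (whitespace separated). Chain is taken as "A"
#' and elements are inferred from atom names. This dialect exists for large
#' synthetic ensembles where fixed-column PDB is wasteful.
#'
#' @param text a single string or character vector of lines
#' @return an [Ensemble()]
#' @export
parse_xyz_frames <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 0]
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  atoms <- NULL
  while (pos <= length(lines)) {
    N <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(N) || N < 1L) stop("expected atom count at line ", pos)
    if (pos + 1L + N > length(lines) + 0L && pos + N + 1L > length(lines))
      stop("truncated frame starting at line ", pos)
    comment <- lines[pos + 1L]
    t <- suppressWarnings(as.numeric(sub("^.*t=\\s*([-0-9.eE+]+).*$", "\\1",
                                         comment)))
    body <- lines[(pos + 2L):(pos + 1L + N)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) != 6L))
      stop("malformed atom line in frame ", length(frames) + 1L)
    m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
    xyz <- matrix(as.numeric(m[, 4:6]), ncol = 3L)
    if (anyNA(xyz)) stop("unparseable coordinates in frame ", length(frames) + 1L)
    if (is.null(atoms)) {
      atoms <- data.frame(
        serial = seq_len(N),
        atom_name = m[, 1],
        element = infer_element(m[, 1]),
        residue_name = m[, 2],
        residue_id = as.integer(m[, 3]),
        chain_id = "A",
        stringsAsFactors = FALSE
      )
    } else if (N != nrow(atoms)) {
      stop("frame ", length(frames) + 1L, " has ", N, " atoms; expected ",
           nrow(atoms))
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t)
    pos <- pos + 2L + N
  }
  coords <- array(unlist(frames), c(nrow(atoms), 3L, length(frames)))
  if (anyNA(times)) times <- NULL
  Ensemble(Structure(atoms, frames[[1]]), coords, times = times)
}

#' Write an ensemble in the multi-frame XYZ dialect
#' @param x a [Structure()] or [Ensemble()]
#' @param digits coordinate decimals (default 4)
#' @return a single string
#' @export
write_xyz_frames <- function(x, digits = 4) {
  ens <- as_ensemble(x)
  at <- ens$topology$atoms
  F <- n_frames(ens)
  times <- if (is.null(ens$times)) seq_len(F) - 1 else ens$times
  chunks <- vapply(seq_len(F), function(k) {
    xyz <- ens$coords[, , k]
    paste(c(sprintf("%d", nrow(at)),
            sprintf("t=%g", times[k]),
            sprintf("%s %s %d %.*f %.*f %.*f",
                    at$atom_name, at$residue_name, at$residue_id,
                    digits, xyz[, 1], digits, xyz[, 2], digits, xyz[, 3])),
          collapse = "\n")
  }, character(1))
  paste0(paste(chunks, collapse = "\n"), "\n")
}
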