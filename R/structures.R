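#' @useDynLib confens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Atomic masses (Da) used for mass weighting. Unknown elements fall back to
# 12.011 with a warning at structure-construction time.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971
)

# Two-letter element symbols consulted before single-letter fallback when the
# PDB element column is absent.
.TWO_LETTER_ELEMENTS <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CU", "SE")

.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC")

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ATOMIC_MASSES[key]
  if (anyNA(m)) {
    unknown <- unique(element[is.na(m)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; assigning carbon mass", call. = FALSE)
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

#' Construct a molecular structure
#'
#' A `Structure` is a fixed atom topology plus one set of Cartesian
#' coordinates in Angstrom. Residue identifiers are taken verbatim from the
#' input (1-based, mature-sequence style numbering is preserved, never
#' renumbered); atom indices used by [select()] and all geometry operations
#' are 1-based positions into the atom table.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`. Masses are derived from the
#'   element unless a `mass` column is supplied.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @return An object of class `Structure`.
#' @export
Structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(atoms) != nrow(xyz)) stop("atoms and xyz disagree on atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  required <- c("serial", "atom_name", "element", "residue_name",
                "residue_id", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("non-positive mass")
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues\n",
              nrow(x$atoms), n_residues(x)))
  invisible(x)
}

#' Number of atoms in a Structure or Ensemble
#' @param x a `Structure` or `Ensemble`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Ensemble")) nrow(x$topology$atoms) else nrow(x$atoms)
}

n_residues <- function(x) {
  at <- if (inherits(x, "Ensemble")) x$topology$atoms else x$atoms
  length(unique(paste(at$chain_id, at$residue_id)))
}

#' Construct a conformational ensemble
#'
#' An `Ensemble` is a topology plus `F` frames of coordinates; the universal
#' input of every analysis stage. Frames are stored as an N x 3 x F array.
#'
#' @param topology a [Structure()] giving the atom table (its own coordinates
#'   are ignored in favour of frame 1).
#' @param coords N x 3 x F numeric array of coordinates (Angstrom).
#' @param times optional numeric vector of frame times (ps), strictly
#'   increasing.
#' @return An object of class `Ensemble`.
#' @export
Ensemble <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "Structure"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  storage.mode(coords) <- "double"
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) stop("coords must be N x 3 x F")
  if (d[1] != n_atoms(topology))
    stop("frame atom count (", d[1], ") does not match topology (",
         n_atoms(topology), ")")
  if (d[3] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != d[3]) stop("times length does not match frame count")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  topology$xyz <- coords[, , 1L, drop = TRUE]
  if (is.null(dim(topology$xyz)))
    topology$xyz <- matrix(topology$xyz, ncol = 3L)
  structure(list(topology = topology, coords = coords, times = times),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d atoms x %d frames%s\n", n_atoms(x), n_frames(x),
              if (is.null(x$times)) "" else
                sprintf(", t = %g..%g ps", x$times[1],
                        x$times[length(x$times)])))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `Ensemble`
#' @return integer frame count
#' @export
n_frames <- function(ensemble) {
  if (inherits(ensemble, "Structure")) return(1L)
  dim(ensemble$coords)[3]
}

#' Extract one frame of an ensemble as a Structure
#' @param ensemble an `Ensemble`
#' @param i frame index (1-based)
#' @return a `Structure`
#' @export
get_frame <- function(ensemble, i) {
  if (inherits(ensemble, "Structure")) {
    if (i != 1L) stop("a Structure has a single frame")
    return(ensemble)
  }
  F <- n_frames(ensemble)
  if (i < 1L || i > F) stop("frame index out of range")
  s <- ensemble$topology
  s$xyz <- matrix(ensemble$coords[, , i], ncol = 3L)
  s
}

#' Promote a Structure to a single-frame Ensemble
#' @param structure a `Structure`
#' @return an `Ensemble` with F = 1
#' @export
as_ensemble <- function(structure) {
  if (inherits(structure, "Ensemble")) return(structure)
  Ensemble(structure, array(structure$xyz, c(nrow(structure$xyz), 3L, 1L)))
}

#' Restrict an ensemble to a subset of frames
#' @param ensemble an `Ensemble`
#' @param idx integer frame indices to keep, in order
#' @return an `Ensemble`
#' @export
subset_frames <- function(ensemble, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("cannot build an empty ensemble")
  if (any(idx < 1L | idx > n_frames(ensemble))) stop("frame index out of range")
  # times survive only for an order-preserving subset (e.g. a time window);
  # reordered picks such as cluster centers are no longer a time series
  keep_times <- !is.null(ensemble$times) &&
    (length(idx) < 2L || all(diff(idx) > 0))
  Ensemble(ensemble$topology,
           ensemble$coords[, , idx, drop = FALSE],
           if (keep_times) ensemble$times[idx])
}

#' Restrict an ensemble to a time window
#'
#' Keeps frames with `t_start <= t < t_end` (half-open, order preserved), the
#' operation used to discard an equilibration segment before clustering or
#' landscape construction. When the ensemble carries no times, `frame_start` /
#' `frame_end` give the same half-open window on 1-based frame indices.
#'
#' @param ensemble an `Ensemble`
#' @param t_start,t_end window bounds in ps
#' @param frame_start,frame_end frame-index window used when times are absent
#' @return an `Ensemble`; an empty selection is an error because every
#'   downstream stage requires at least one frame.
#' @export
time_window <- function(ensemble, t_start = NULL, t_end = NULL,
                        frame_start = NULL, frame_end = NULL) {
  if (!is.null(t_start) || !is.null(t_end)) {
    if (is.null(ensemble$times))
      stop("ensemble has no times; use frame_start/frame_end")
    if (is.null(t_start)) t_start <- -Inf
    if (is.null(t_end)) t_end <- Inf
    if (t_start > t_end) stop("t_start must not exceed t_end")
    keep <- which(ensemble$times >= t_start & ensemble$times < t_end)
  } else {
    F <- n_frames(ensemble)
    if (is.null(frame_start)) frame_start <- 1L
    if (is.null(frame_end)) frame_end <- F + 1L
    keep <- which(seq_len(F) >= frame_start & seq_len(F) < frame_end)
  }
  if (length(keep) == 0L) stop("time window selects no frames")
  subset_frames(ensemble, keep)
}
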