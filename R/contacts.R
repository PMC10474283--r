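# Per-residue contact prevalence, residue-pair contact matrices, a geometric
# hydrogen-bond proxy, polar/hydrophobic residue classification, and
# occupancy grids.
#
# The contact criterion is inclusive: two heavy atoms are "in contact" when
# their distance is <= cutoff, so boundary ties are deterministic.

.HYDROPHOBIC_AA <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                     "GLY")
.POLAR_AA <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS")
.CHARGED_AA <- c("ASP", "GLU", "LYS", "ARG")

.heavy_subset <- function(ensemble, idx) {
  el <- ensemble$topology$atoms$element[idx]
  idx[!(el %in% c("H", "D"))]
}

.residue_groups <- function(ensemble, idx) {
  at <- ensemble$topology$atoms
  key <- paste(at$chain_id[idx], at$residue_id[idx])
  split(idx, factor(key, levels = unique(key)))
}

#' Per-residue contact prevalence against a partner group
#'
#' For each residue of `group_a`, the percentage of frames in which any of
#' its heavy atoms lies within `cutoff` (inclusive) of any heavy atom of
#' `group_b`. This is the standard per-residue intermolecular-contact
#' statistic for protein-peptide, protein-ligand and protein-membrane
#' interfaces.
#'
#' @param ensemble an [Ensemble()]
#' @param group_a selection whose residues are tabulated
#' @param group_b partner selection (disjoint from `group_a`)
#' @param cutoff heavy-atom distance criterion in Angstrom (default 3.5)
#' @param heavy_only restrict both groups to heavy atoms (default TRUE)
#' @return a `ContactPrevalenceTable` data.frame: `chain`, `residue_id`,
#'   `residue_name`, `contact_frames`, `percentage` (0-100, one decimal),
#'   with attributes `cutoff` and `n_frames`
#' @export
contact_prevalence <- function(ensemble, group_a, group_b, cutoff = 3.5,
                               heavy_only = TRUE) {
  ia <- resolve_selection(ensemble, group_a)
  ib <- resolve_selection(ensemble, group_b)
  if (length(intersect(ia, ib)) > 0) stop("contact groups overlap")
  if (heavy_only) {
    ia <- .heavy_subset(ensemble, ia)
    ib <- .heavy_subset(ensemble, ib)
    if (length(ia) == 0L || length(ib) == 0L)
      stop("a contact group has no heavy atoms")
  }
  groups <- .residue_groups(ensemble, ia)
  F <- n_frames(ensemble)
  hits <- matrix(FALSE, length(groups), F)
  for (k in seq_len(F)) {
    xyz <- ensemble$coords[, , k]
    B <- xyz[ib, , drop = FALSE]
    for (g in seq_along(groups)) {
      d <- .cross_dist(xyz[groups[[g]], , drop = FALSE], B)
      hits[g, k] <- any(d <= cutoff)
    }
  }
  at <- ensemble$topology$atoms
  first <- vapply(groups, `[`, integer(1), 1L)
  contact_frames <- rowSums(hits)
  out <- data.frame(
    chain = at$chain_id[first],
    residue_id = at$residue_id[first],
    residue_name = at$residue_name[first],
    contact_frames = contact_frames,
    percentage = round(100 * contact_frames / F, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- F
  class(out) <- c("ContactPrevalenceTable", "data.frame")
  out
}

#' Residue-pair contact percentage matrix
#'
#' Entry (i, j) is the percentage of frames in which any heavy-atom pair of
#' residue i (from `group_a`) and residue j (from `group_b`) is within
#' `cutoff`. The row-wise maximum over j reproduces the per-residue
#' prevalence of [contact_prevalence()] only when a single partner residue
#' dominates; in general prevalence >= row maximum.
#'
#' @inheritParams contact_prevalence
#' @return numeric matrix with residue labels (`<resname><resid>`) as
#'   dimnames and attributes `cutoff`, `n_frames`
#' @export
contact_matrix <- function(ensemble, group_a, group_b, cutoff = 3.5,
                           heavy_only = TRUE) {
  ia <- resolve_selection(ensemble, group_a)
  ib <- resolve_selection(ensemble, group_b)
  if (length(intersect(ia, ib)) > 0) stop("contact groups overlap")
  if (heavy_only) {
    ia <- .heavy_subset(ensemble, ia)
    ib <- .heavy_subset(ensemble, ib)
  }
  ga <- .residue_groups(ensemble, ia)
  gb <- .residue_groups(ensemble, ib)
  F <- n_frames(ensemble)
  hits <- array(FALSE, c(length(ga), length(gb), F))
  for (k in seq_len(F)) {
    xyz <- ensemble$coords[, , k]
    for (i in seq_along(ga)) {
      A <- xyz[ga[[i]], , drop = FALSE]
      for (j in seq_along(gb)) {
        d <- .cross_dist(A, xyz[gb[[j]], , drop = FALSE])
        hits[i, j, k] <- any(d <= cutoff)
      }
    }
  }
  at <- ensemble$topology$atoms
  lab <- function(groups) vapply(groups, function(idx)
    paste0(at$residue_name[idx[1]], at$residue_id[idx[1]]), character(1))
  m <- round(100 * apply(hits, c(1, 2), sum) / F, 1)
  dimnames(m) <- list(lab(ga), lab(gb))
  attr(m, "cutoff") <- cutoff
  attr(m, "n_frames") <- F
  m
}

#' Geometric hydrogen-bond proxy
#'
#' Counts a donor/acceptor pair as bonded in a frame when the heavy-atom
#' (N/O) distance is within `cutoff`; when `angle_min` is given and the
#' donor has covalent hydrogens (within 1.25 A in frame 1), the
#' donor-H-acceptor angle must also reach `angle_min` for at least one such
#' hydrogen. This is a purely geometric stand-in for interaction-type
#' analysis, not an energetic model.
#'
#' @param ensemble an [Ensemble()]
#' @param donors,acceptors selections restricted to N and O atoms
#' @param cutoff heavy-atom distance criterion (default 3.5 A)
#' @param angle_min optional minimum donor-H-acceptor angle in degrees
#' @return data.frame of pairs with `prevalence` percentages (one decimal)
#' @export
hbond_proxy <- function(ensemble, donors, acceptors, cutoff = 3.5,
                        angle_min = NULL) {
  id <- resolve_selection(ensemble, donors)
  ia <- resolve_selection(ensemble, acceptors)
  at <- ensemble$topology$atoms
  if (any(!(at$element[c(id, ia)] %in% c("N", "O"))))
    stop("donor/acceptor selections must contain only N and O atoms")
  F <- n_frames(ensemble)
  hyd <- which(at$element == "H")
  xyz1 <- matrix(ensemble$coords[, , 1], ncol = 3L)
  donor_h <- lapply(id, function(d) {
    if (length(hyd) == 0L) return(integer(0))
    dd <- .cross_dist(xyz1[d, , drop = FALSE], xyz1[hyd, , drop = FALSE])
    hyd[dd[1, ] <= 1.25]
  })
  pairs <- expand.grid(donor = seq_along(id), acceptor = seq_along(ia))
  pairs <- pairs[id[pairs$donor] != ia[pairs$acceptor], , drop = FALSE]
  counts <- integer(nrow(pairs))
  for (k in seq_len(F)) {
    xyz <- ensemble$coords[, , k]
    d <- .cross_dist(xyz[id, , drop = FALSE], xyz[ia, , drop = FALSE])
    for (p in seq_len(nrow(pairs))) {
      i <- pairs$donor[p]; j <- pairs$acceptor[p]
      ok <- d[i, j] <= cutoff
      if (ok && !is.null(angle_min) && length(donor_h[[i]]) > 0) {
        ang <- vapply(donor_h[[i]], function(h) {
          u <- xyz[id[i], ] - xyz[h, ]
          v <- xyz[ia[j], ] - xyz[h, ]
          ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
          acos(max(-1, min(1, ct))) * 180 / pi
        }, numeric(1))
        ok <- any(ang >= angle_min)
      }
      if (ok) counts[p] <- counts[p] + 1L
    }
  }
  lab <- function(i) paste0(at$residue_name[i], at$residue_id[i], ":",
                            at$atom_name[i])
  out <- data.frame(
    donor = lab(id[pairs$donor]),
    acceptor = lab(ia[pairs$acceptor]),
    contact_frames = counts,
    prevalence = round(100 * counts / F, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$prevalence, out$donor, out$acceptor), , drop = FALSE]
}

#' Classify a contact table by residue chemistry
#'
#' Adds a `class` column (`hydrophobic`, `polar`, `charged`, or `other`)
#' from a fixed amino-acid lookup (hydrophobic: ALA VAL LEU ILE PRO PHE MET
#' TRP GLY; polar: SER THR ASN GLN TYR CYS HIS; charged: ASP GLU LYS ARG)
#' and sorts within class by percentage descending. Unknown residue names
#' are labeled `other` with a warning.
#'
#' @param table a `ContactPrevalenceTable` from [contact_prevalence()]
#' @return the table with a `class` column, ordered by class then
#'   percentage
#' @export
classify_residue_contacts <- function(table) {
  cls <- ifelse(table$residue_name %in% .HYDROPHOBIC_AA, "hydrophobic",
         ifelse(table$residue_name %in% .POLAR_AA, "polar",
         ifelse(table$residue_name %in% .CHARGED_AA, "charged", "other")))
  if (any(cls == "other"))
    warning("unknown residue name(s): ",
            paste(unique(table$residue_name[cls == "other"]), collapse = ", "),
            call. = FALSE)
  table$class <- factor(cls, levels = c("hydrophobic", "polar", "charged",
                                        "other"))
  out <- table[order(table$class, -table$percentage, table$residue_id), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary occupancy grid over an ensemble
#'
#' Bins selected atom centers into a cubic grid (default 1 A spacing)
#' spanning the selection's bounding box over all frames, padded by one
#' voxel. A voxel is occupied in a frame when at least one selected atom
#' center lies in it; occupancy is the fraction of frames occupied, so
#' occupancy times F is always an integer. Voxels at or above `isovalue`
#' (default 0.44) mark conserved sites such as ordered waters.
#'
#' @param ensemble an [Ensemble()]
#' @param selection atoms to bin (e.g. `"water and name O,OW"`)
#' @param spacing voxel edge length in Angstrom (default 1.0)
#' @param isovalue reporting threshold on occupancy (default 0.44)
#' @param reference_fit optional selection; frames are superposed to frame 1
#'   on it before binning
#' @return an `OccupancyGrid`: list with `origin`, `spacing`, `dims`,
#'   `occupancy` (3D array), `isovalue`, and `sites` (data.frame of voxels
#'   with occupancy >= isovalue, occupancy descending)
#' @export
occupancy_grid <- function(ensemble, selection, spacing = 1.0,
                           isovalue = 0.44, reference_fit = NULL) {
  idx <- resolve_selection(ensemble, selection)
  if (spacing <= 0) stop("spacing must be positive")
  if (!is.null(reference_fit))
    ensemble <- superpose_ensemble(ensemble, get_frame(ensemble, 1L),
                                   reference_fit)
  F <- n_frames(ensemble)
  pts <- ensemble$coords[idx, , , drop = FALSE]
  lo <- apply(pts, 2, min) - spacing
  hi <- apply(pts, 2, max) + spacing
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)), 1L)
  occ_count <- array(0L, dims)
  for (k in seq_len(F)) {
    pk <- pts[, , k]
    if (is.null(dim(pk))) pk <- matrix(pk, 1L, 3L)
    v <- floor(sweep(pk, 2, lo) / spacing) + 1L
    v[] <- pmin(pmax(v, 1L), matrix(dims, nrow(v), 3L, byrow = TRUE))
    lin <- unique((v[, 3] - 1L) * dims[1] * dims[2] +
                    (v[, 2] - 1L) * dims[1] + v[, 1])
    occ_count[lin] <- occ_count[lin] + 1L
  }
  occupancy <- occ_count / F
  above <- which(occupancy >= isovalue, arr.ind = TRUE)
  sites <- data.frame(
    ix = above[, 1], iy = above[, 2], iz = above[, 3],
    x = lo[1] + (above[, 1] - 0.5) * spacing,
    y = lo[2] + (above[, 2] - 0.5) * spacing,
    z = lo[3] + (above[, 3] - 0.5) * spacing,
    occupancy = occupancy[above]
  )
  sites <- sites[order(-sites$occupancy, sites$ix, sites$iy, sites$iz), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 occupancy = occupancy, isovalue = isovalue,
                 n_frames = F, sites = sites),
            class = "OccupancyGrid")
}

#' @export
print.OccupancyGrid <- function(x, ...) {
  cat(sprintf(
    "OccupancyGrid: %d x %d x %d voxels (%.2f A), %d site(s) >= %.2f\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, nrow(x$sites), x$isovalue))
  invisible(x)
}

#' Write an occupancy grid in OpenDX scalar-field format
#'
#' The format (origin, deltas, counts, then values in z-fastest order) is
#' readable by standard molecular viewers.
#'
#' @param grid an `OccupancyGrid`
#' @param path output path (conventionally `.dx`)
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# binary per-frame occupancy, %d frames, isovalue %.2f",
            grid$n_frames, grid$isovalue),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1] + grid$spacing / 2,
            grid$origin[2] + grid$spacing / 2,
            grid$origin[3] + grid$spacing / 2),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # DX order: x slowest, z fastest
  vals <- as.vector(aperm(grid$occupancy, c(3, 2, 1)))
  n <- length(vals)
  rows <- split(vals, (seq_len(n) - 1L) %/% 3L)
  writeLines(vapply(rows, function(r) paste(sprintf("%.6f", r),
                                            collapse = " "), character(1)),
             con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#' @param path path to a `.dx` file
#' @return list with `origin` (voxel centers), `spacing`, `dims`, `values`
#'   (3D array)
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  gp <- lines[grep("gridpositions", lines)[1]]
  dims <- as.integer(strsplit(sub(".*counts ", "", gp), "\\s+")[[1]])
  origin <- as.numeric(strsplit(sub("^origin\\s+", "",
                                    lines[grep("^origin", lines)[1]]),
                                "\\s+")[[1]])
  deltas <- lines[grep("^delta", lines)]
  spacing <- as.numeric(strsplit(sub("^delta\\s+", "", deltas[1]),
                                 "\\s+")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("^attribute", lines)[1]
  if (is.na(end)) end <- length(lines) + 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:(end - 1L)]),
                                     "\\s+")))
  stopifnot(length(vals) == prod(dims))
  arr <- aperm(array(vals, rev(dims)), c(3, 2, 1))
  list(origin = origin, spacing = spacing, dims = dims, values = arr)
}

#' Write a contact prevalence table as TSV
#' @param table a `ContactPrevalenceTable`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contacts_tsv <- function(table, path) {
  .write_tsv(as.data.frame(table), path,
             sprintf("# per-residue contact prevalence (cutoff %.2f A, %d frames)",
                     attr(table, "cutoff"), attr(table, "n_frames")))
  invisible(path)
}
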