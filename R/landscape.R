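# Collective variables and the 2D Gibbs free-energy landscape.
#
# The landscape is a plain Boltzmann inversion of the binned CV density:
# G_ij = -ln(n_ij / n_max) in kT, so the highest-density bin reads exactly
# zero and empty bins are masked (never imputed). Temperature enters only
# when converting to kJ/mol for display.

.BOLTZMANN_KJ <- 0.0083144626  # kJ/(mol K)

#' Define a collective variable
#'
#' A CV definition names a per-frame scalar: a two-group center-of-mass
#' distance or a three-group angle. Two built-in definitions implement the
#' standard hinge-protein reaction coordinates:
#'
#' * `"phe63_asnrepeat_distance"`: distance from the CA of residue 63 to the
#'   CA center of mass of residues 113-116 (the Asn repeat), in Angstrom.
#' * `"interdomain_theta"`: angle at the CA center of mass of residues
#'   120-129 (vertex) subtended by the CA centers of residues 60-62 + 67-69
#'   and residues 90-96 + 100-107, in degrees.
#'
#' @param name a built-in name above, or a label for a custom definition
#' @param type `"distance"` or `"angle"` (ignored for built-ins)
#' @param groups list of selection expressions: 2 for a distance, 3 for an
#'   angle (in order A, B, C)
#' @param vertex for angles, which group is the vertex (default `"B"`, the
#'   second-listed group)
#' @param weighting COM weighting, `"mass"` or `"geometric"`
#' @return a `cv_definition` object for [evaluate_cv()]
#' @export
cv_definition <- function(name, type = NULL, groups = NULL, vertex = "B",
                          weighting = "mass") {
  builtin <- list(
    phe63_asnrepeat_distance = list(
      type = "distance",
      groups = list("resid 63 and ca", "resid 113-116 and ca"),
      units = "Angstrom"),
    interdomain_theta = list(
      type = "angle",
      groups = list("resid 60-62,67-69 and ca", "resid 120-129 and ca",
                    "resid 90-96,100-107 and ca"),
      units = "degrees")
  )
  if (name %in% names(builtin) && is.null(groups)) {
    b <- builtin[[name]]
    type <- b$type
    groups <- b$groups
    units <- b$units
  } else {
    if (is.null(type) || is.null(groups))
      stop("custom CV definitions need type and groups")
    type <- match.arg(type, c("distance", "angle"))
    units <- if (type == "distance") "Angstrom" else "degrees"
  }
  n_need <- if (type == "distance") 2L else 3L
  if (length(groups) != n_need)
    stop(type, " CV needs ", n_need, " groups")
  structure(list(name = name, type = type, groups = groups, vertex = vertex,
                 weighting = weighting, units = units),
            class = "cv_definition")
}

.check_cv_groups <- function(ensemble, def) {
  for (g in def$groups) {
    idx <- resolve_selection(ensemble, g, allow_empty = TRUE)
    if (length(idx) == 0L)
      stop("CV '", def$name, "': selection '",
           if (is.character(g)) g else "<indices>",
           "' matches no atoms in the topology")
  }
}

#' Evaluate a collective variable over an ensemble
#'
#' @param ensemble an [Ensemble()]
#' @param definition a [cv_definition()] or a built-in CV name
#' @return a `CVSeries`: list with `name`, `values` (one per frame),
#'   `units`, and the `definition`
#' @export
evaluate_cv <- function(ensemble, definition) {
  if (is.character(definition)) definition <- cv_definition(definition)
  stopifnot(inherits(definition, "cv_definition"))
  .check_cv_groups(ensemble, definition)
  sels <- lapply(definition$groups, resolve_selection, topology = ensemble)
  vals <- vapply(seq_len(n_frames(ensemble)), function(k) {
    fr <- get_frame(ensemble, k)
    if (definition$type == "distance")
      group_distance(fr, sels[[1]], sels[[2]], definition$weighting)
    else
      group_angle(fr, sels[[1]], sels[[2]], sels[[3]],
                  vertex = definition$vertex,
                  weighting = definition$weighting)
  }, numeric(1))
  structure(list(name = definition$name, values = vals,
                 units = definition$units, definition = definition),
            class = "CVSeries")
}

#' @export
print.CVSeries <- function(x, ...) {
  cat(sprintf("CVSeries '%s': %d frames, range %.3f..%.3f %s\n",
              x$name, length(x$values), min(x$values), max(x$values),
              x$units))
  invisible(x)
}

.cv_values <- function(x) if (inherits(x, "CVSeries")) x$values else as.numeric(x)

#' Build a 2D Gibbs free-energy landscape from two CV series
#'
#' Bins the joint samples on a `bins` x `bins` grid spanning the data range
#' of each series and applies Boltzmann inversion: `G = -ln(n / n_max)` in
#' kT units, so the most populated bin is exactly 0 and the free-energy
#' difference between any two bins is the log of their count ratio. Empty
#' bins are masked.
#'
#' @param cv_x,cv_y `CVSeries` (or plain numeric vectors) of equal length
#' @param bins number of bins per axis (default 120)
#' @param temperature temperature in K (default 310); only used when
#'   converting to kJ/mol
#' @return a `FreeEnergyLandscape`: list with `bin_edges_x`, `bin_edges_y`,
#'   `counts`, `free_energy` (kT; `NA` where masked), `mask`, `temperature`,
#'   and axis names/units
#' @export
build_fel <- function(cv_x, cv_y, bins = 120, temperature = 310) {
  x <- .cv_values(cv_x); y <- .cv_values(cv_y)
  if (length(x) != length(y)) stop("CV series differ in length")
  if (length(x) < 1L) stop("no samples")
  if (bins < 2L) stop("need at least 2 bins per axis")
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0 || diff(ry) == 0)
    stop("zero-variance CV series: degenerate grid")
  ex <- seq(rx[1], rx[2], length.out = bins + 1L)
  ey <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(findInterval(x, ex, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, ey, rightmost.closed = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  tb <- table(factor(ix, levels = seq_len(bins)),
              factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tb)
  mask <- counts == 0L
  G <- matrix(NA_real_, bins, bins)
  G[!mask] <- -log(counts[!mask] / max(counts))
  structure(list(
    bin_edges_x = ex, bin_edges_y = ey, counts = counts, free_energy = G,
    mask = mask, temperature = temperature,
    name_x = if (inherits(cv_x, "CVSeries")) cv_x$name else "cv_x",
    name_y = if (inherits(cv_y, "CVSeries")) cv_y$name else "cv_y",
    units_x = if (inherits(cv_x, "CVSeries")) cv_x$units else "",
    units_y = if (inherits(cv_y, "CVSeries")) cv_y$units else ""
  ), class = "FreeEnergyLandscape")
}

#' @export
print.FreeEnergyLandscape <- function(x, ...) {
  cat(sprintf(
    "FreeEnergyLandscape: %d x %d bins, %d occupied, max G %.2f kT (T = %g K)\n",
    nrow(x$counts), ncol(x$counts), sum(!x$mask),
    max(x$free_energy, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Bin centers of a landscape axis
#' @param fel a `FreeEnergyLandscape`
#' @param axis `"x"` or `"y"`
#' @return numeric vector of bin centers
#' @export
fel_bin_centers <- function(fel, axis = c("x", "y")) {
  e <- if (match.arg(axis) == "x") fel$bin_edges_x else fel$bin_edges_y
  (head(e, -1) + tail(e, -1)) / 2
}

#' Convert a landscape to kJ/mol
#' @param fel a `FreeEnergyLandscape`
#' @return matrix of free energies in kJ/mol (`NA` where masked)
#' @export
fel_kjmol <- function(fel) {
  fel$free_energy * .BOLTZMANN_KJ * fel$temperature
}

#' Locate free-energy basins
#'
#' Local minima of the unmasked grid under 4-neighborhood comparison
#' (masked neighbors count as +Inf), sorted ascending by free energy with
#' ties broken by row-major bin index.
#'
#' @param fel a `FreeEnergyLandscape`
#' @param top_k number of minima to report (default all)
#' @return data.frame with bin indices, bin-center coordinates, `G_kT`,
#'   and counts
#' @export
locate_minima <- function(fel, top_k = Inf) {
  G <- fel$free_energy
  B1 <- nrow(G); B2 <- ncol(G)
  Gp <- matrix(Inf, B1 + 2L, B2 + 2L)
  inner <- G; inner[is.na(inner)] <- Inf
  Gp[2:(B1 + 1L), 2:(B2 + 1L)] <- inner
  core <- Gp[2:(B1 + 1L), 2:(B2 + 1L)]
  is_min <- !fel$mask &
    core <= Gp[1:B1, 2:(B2 + 1L)] &
    core <= Gp[3:(B1 + 2L), 2:(B2 + 1L)] &
    core <= Gp[2:(B1 + 1L), 1:B2] &
    core <= Gp[2:(B1 + 1L), 3:(B2 + 2L)]
  idx <- which(is_min, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(bin_x = integer(0), bin_y = integer(0),
                      x = numeric(0), y = numeric(0),
                      G_kT = numeric(0), count = integer(0)))
  g <- G[idx]
  rowmajor <- (idx[, 1] - 1L) * B2 + idx[, 2]
  ord <- order(g, rowmajor)
  idx <- idx[ord, , drop = FALSE]
  out <- data.frame(
    bin_x = idx[, 1], bin_y = idx[, 2],
    x = fel_bin_centers(fel, "x")[idx[, 1]],
    y = fel_bin_centers(fel, "y")[idx[, 2]],
    G_kT = G[idx], count = fel$counts[idx]
  )
  head(out, if (is.finite(top_k)) top_k else nrow(out))
}

#' Write a landscape as a TSV matrix
#'
#' First row and column carry bin centers; masked bins are written as `NA`.
#' Header comment lines record axes, units, temperature and bin count.
#'
#' @param fel a `FreeEnergyLandscape`
#' @param path output path
#' @param units `"kT"` (default) or `"kJ/mol"`
#' @return `path`, invisibly
#' @export
write_fel_tsv <- function(fel, path, units = c("kT", "kJ/mol")) {
  units <- match.arg(units)
  G <- if (units == "kT") fel$free_energy else fel_kjmol(fel)
  cx <- fel_bin_centers(fel, "x"); cy <- fel_bin_centers(fel, "y")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# free-energy landscape: %s (%s) x %s (%s)",
            fel$name_x, fel$units_x, fel$name_y, fel$units_y),
    sprintf("# temperature_K=%g bins=%d units=%s", fel$temperature,
            nrow(fel$counts), units),
    "# rows = x bins, columns = y bins; first row/column are bin centers"
  ), con)
  header <- paste(c("x_center\\y_center", format(cy, digits = 8)),
                  collapse = "\t")
  writeLines(header, con)
  for (i in seq_along(cx)) {
    row <- ifelse(is.na(G[i, ]), "NA", format(G[i, ], digits = 8))
    writeLines(paste(c(format(cx[i], digits = 8), row), collapse = "\t"), con)
  }
  invisible(path)
}
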