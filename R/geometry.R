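# Core geometric measurements on frames and ensembles. All distances are in
# Angstrom, angles in degrees. A "frame" argument accepts a Structure (or a
# single-frame Ensemble); selections may be Selection objects, expression
# strings, or raw 1-based index vectors.

.frame_structure <- function(frame) {
  if (inherits(frame, "Ensemble")) {
    if (n_frames(frame) != 1L)
      stop("expected a single frame; got an ensemble with ", n_frames(frame))
    return(get_frame(frame, 1L))
  }
  stopifnot(inherits(frame, "Structure"))
  frame
}

.weights_for <- function(structure, idx, weighting) {
  weighting <- match.arg(weighting, c("mass", "geometric"))
  if (weighting == "mass") structure$atoms$mass[idx]
  else rep(1, length(idx))
}

#' Center of mass of a selection
#'
#' @param frame a [Structure()] (or single-frame ensemble)
#' @param selection selection (expression, `Selection`, or indices)
#' @param weighting `"mass"` (default) or `"geometric"` (equal weights).
#'   For all-CA selections the two coincide.
#' @return length-3 numeric vector (Angstrom)
#' @export
center_of_mass <- function(frame, selection, weighting = "mass") {
  s <- .frame_structure(frame)
  idx <- resolve_selection(s, selection)
  w <- .weights_for(s, idx, weighting)
  colSums(s$xyz[idx, , drop = FALSE] * w) / sum(w)
}

#' Distance between the centers of mass of two groups
#' @inheritParams center_of_mass
#' @param selA,selB the two groups
#' @return scalar distance (Angstrom)
#' @export
group_distance <- function(frame, selA, selB, weighting = "mass") {
  a <- center_of_mass(frame, selA, weighting)
  b <- center_of_mass(frame, selB, weighting)
  sqrt(sum((a - b)^2))
}

#' Angle subtended at a vertex group by two arm groups
#'
#' Computes the angle (degrees, in \[0, 180\]) at the center of mass of the
#' vertex group between the centers of mass of the other two groups. This is
#' the three-group interdomain angle used as a hinge-bending collective
#' variable.
#'
#' @inheritParams center_of_mass
#' @param selA,selB,selC the three groups, in order
#' @param vertex which group holds the vertex: `"A"`, `"B"` (default), or `"C"`
#' @return angle in degrees
#' @export
group_angle <- function(frame, selA, selB, selC, vertex = "B",
                        weighting = "mass") {
  vertex <- match.arg(vertex, c("A", "B", "C"))
  coms <- list(A = center_of_mass(frame, selA, weighting),
               B = center_of_mass(frame, selB, weighting),
               C = center_of_mass(frame, selC, weighting))
  v <- coms[[vertex]]
  arms <- coms[setdiff(names(coms), vertex)]
  u1 <- arms[[1]] - v
  u2 <- arms[[2]] - v
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("degenerate geometry: vertex coincides with an arm center of mass")
  ct <- sum(u1 * u2) / (n1 * n2)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Minimum atom-atom distance between two disjoint groups
#'
#' @inheritParams center_of_mass
#' @param selA,selB the two groups; they must not share atoms (a shared atom
#'   would force a trivial zero)
#' @return scalar minimum distance (Angstrom)
#' @export
min_distance <- function(frame, selA, selB) {
  s <- .frame_structure(frame)
  ia <- resolve_selection(s, selA)
  ib <- resolve_selection(s, selB)
  if (length(intersect(ia, ib)) > 0) stop("selections overlap")
  min(.cross_dist(s$xyz[ia, , drop = FALSE], s$xyz[ib, , drop = FALSE]))
}

# all-pairs Euclidean cross distances, na x nb
.cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Per-frame minimum-distance series over an ensemble
#' @param ensemble an [Ensemble()]
#' @param selA,selB disjoint groups
#' @return numeric vector of length `n_frames(ensemble)`
#' @export
min_distance_series <- function(ensemble, selA, selB) {
  ia <- resolve_selection(ensemble, selA)
  ib <- resolve_selection(ensemble, selB)
  if (length(intersect(ia, ib)) > 0) stop("selections overlap")
  vapply(seq_len(n_frames(ensemble)), function(k) {
    xyz <- ensemble$coords[, , k]
    min(.cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
}

#' Radius of gyration of a selection
#'
#' `sqrt(sum(m_i * |x_i - COM|^2) / sum(m_i))`, mass-weighted by default.
#'
#' @inheritParams center_of_mass
#' @return scalar Rg (Angstrom)
#' @export
radius_of_gyration <- function(frame, selection, weighting = "mass") {
  s <- .frame_structure(frame)
  idx <- resolve_selection(s, selection)
  w <- .weights_for(s, idx, weighting)
  xyz <- s$xyz[idx, , drop = FALSE]
  com <- colSums(xyz * w) / sum(w)
  dx <- sweep(xyz, 2, com)
  sqrt(sum(w * rowSums(dx^2)) / sum(w))
}

#' Per-frame radius-of-gyration series
#' @inheritParams min_distance_series
#' @param selection the group to measure
#' @param weighting `"mass"` or `"geometric"`
#' @return numeric vector of length `n_frames(ensemble)`
#' @export
rg_series <- function(ensemble, selection, weighting = "mass") {
  vapply(seq_len(n_frames(ensemble)), function(k)
    radius_of_gyration(get_frame(ensemble, k), selection, weighting),
    numeric(1))
}

#' Kabsch superposition transform
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD of
#' `fit_selection` atoms of the mobile frame onto the reference frame.
#' Reflections are corrected, so the rotation determinant is always +1.
#'
#' @param mobile_frame,reference_frame [Structure()]s with matching atom
#'   counts over the fit selection
#' @param fit_selection atoms used for the fit (at least 3, non-collinear)
#' @param weighting `"mass"` or `"geometric"`
#' @return a `Transform`: list with `rotation` (3 x 3) and `translation`
#'   (length 3); apply with [apply_transform()] as `x %*% R + t`
#' @export
kabsch_fit <- function(mobile_frame, reference_frame, fit_selection,
                       weighting = "geometric") {
  mob <- .frame_structure(mobile_frame)
  ref <- .frame_structure(reference_frame)
  idx <- resolve_selection(mob, fit_selection)
  if (length(idx) < 3L) stop("fit selection needs at least 3 atoms")
  w <- .weights_for(mob, idx, weighting)
  .kabsch_xyz(mob$xyz[idx, , drop = FALSE], ref$xyz[idx, , drop = FALSE], w)
}

.kabsch_xyz <- function(X, Y, w) {
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check: rank of the weighted coordinate spread
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1e-30))
    stop("degenerate (collinear) fit selection")
  H <- crossprod(Xc * w, Yc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # x %*% R maps mobile onto reference
  structure(list(rotation = R, translation = cy - as.vector(cx %*% R)),
            class = "Transform")
}

#' Apply a superposition transform to coordinates
#' @param xyz N x 3 matrix, a [Structure()], or an [Ensemble()]
#' @param transform a `Transform` from [kabsch_fit()]
#' @return object of the same type with transformed coordinates
#' @export
apply_transform <- function(xyz, transform) {
  if (inherits(xyz, "Ensemble")) {
    for (k in seq_len(n_frames(xyz)))
      xyz$coords[, , k] <- apply_transform(xyz$coords[, , k], transform)
    xyz$topology$xyz <- xyz$coords[, , 1]
    return(xyz)
  }
  if (inherits(xyz, "Structure")) {
    xyz$xyz <- apply_transform(xyz$xyz, transform)
    return(xyz)
  }
  sweep(xyz %*% transform$rotation, 2, transform$translation, "+")
}

#' Best-fit RMSD between two frames
#'
#' Superposes the mobile frame onto the reference over `fit_selection`, then
#' evaluates the root-mean-square deviation over `calc_selection` (default:
#' the fit selection). Distinct fit and calc selections support measurements
#' such as ligand RMSD after receptor-backbone alignment.
#'
#' @inheritParams kabsch_fit
#' @param calc_selection atoms over which the deviation is evaluated
#' @param fit superpose before measuring (default TRUE); FALSE gives the raw
#'   coordinate RMSD
#' @return scalar RMSD (Angstrom)
#' @export
rmsd <- function(mobile_frame, reference_frame, fit_selection = "all",
                 calc_selection = fit_selection, weighting = "geometric",
                 fit = TRUE) {
  mob <- .frame_structure(mobile_frame)
  ref <- .frame_structure(reference_frame)
  ic <- resolve_selection(mob, calc_selection)
  if (fit) {
    tr <- kabsch_fit(mob, ref, fit_selection, weighting)
    mx <- apply_transform(mob$xyz, tr)
  } else {
    mx <- mob$xyz
  }
  sqrt(mean(rowSums((mx[ic, , drop = FALSE] - ref$xyz[ic, , drop = FALSE])^2)))
}

#' Per-frame RMSD series against a reference frame
#' @param ensemble an [Ensemble()]
#' @param reference a [Structure()] (e.g. frame 1 or an average structure)
#' @inheritParams rmsd
#' @return numeric vector of per-frame RMSD (Angstrom)
#' @export
rmsd_series <- function(ensemble, reference, fit_selection = "all",
                        calc_selection = fit_selection,
                        weighting = "geometric") {
  vapply(seq_len(n_frames(ensemble)), function(k)
    rmsd(get_frame(ensemble, k), reference, fit_selection, calc_selection,
         weighting),
    numeric(1))
}

#' Iteratively fitted average structure of an ensemble
#'
#' All frames are superposed to frame 1 over `fit_selection`, the mean
#' coordinates are taken, then one re-fit pass to that mean refines the
#' average. The result serves as the reference for convergence RMSD series
#' and as the PCA mean.
#'
#' @param ensemble an [Ensemble()]
#' @param fit_selection atoms used for superposition
#' @param weighting `"mass"` or `"geometric"`
#' @return a [Structure()] holding the average coordinates
#' @export
average_structure <- function(ensemble, fit_selection = "all",
                              weighting = "geometric") {
  s <- ensemble$topology
  mean_of_fit <- function(reference) {
    acc <- matrix(0, n_atoms(ensemble), 3L)
    for (k in seq_len(n_frames(ensemble))) {
      fk <- get_frame(ensemble, k)
      tr <- kabsch_fit(fk, reference, fit_selection, weighting)
      acc <- acc + apply_transform(fk$xyz, tr)
    }
    acc / n_frames(ensemble)
  }
  m1 <- s; m1$xyz <- mean_of_fit(get_frame(ensemble, 1L))
  m2 <- s; m2$xyz <- mean_of_fit(m1)
  m2
}

#' Superpose every frame of an ensemble onto a reference
#' @inheritParams rmsd_series
#' @return an [Ensemble()] with superposed coordinates
#' @export
superpose_ensemble <- function(ensemble, reference = NULL,
                               fit_selection = "all",
                               weighting = "geometric") {
  if (is.null(reference))
    reference <- average_structure(ensemble, fit_selection, weighting)
  for (k in seq_len(n_frames(ensemble))) {
    tr <- kabsch_fit(get_frame(ensemble, k), reference, fit_selection,
                     weighting)
    ensemble$coords[, , k] <- apply_transform(ensemble$coords[, , k], tr)
  }
  ensemble$topology$xyz <- ensemble$coords[, , 1]
  ensemble
}
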