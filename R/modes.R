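# Elastic-network normal modes with rotation-translation-block (RTB)
# reduction, essential-dynamics PCA, and mode overlap.
#
# Coordinate vectors are 3N-dimensional with per-atom interleaving
# (x1, y1, z1, x2, ...). Mode numbering follows the convention that counts
# the six rigid-body modes first, so the softest internal motion is mode 7.

flatten_xyz <- function(xyz) as.vector(t(xyz))
unflatten_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Build an anisotropic elastic-network Hessian
#'
#' Standard ENM second-derivative matrix: every atom pair within `cutoff`
#' contributes a spring; the pair super-element is
#' `-k(r) * (d %o% d) / r^2` with `d` the equilibrium separation, and
#' diagonal blocks are minus the sum of the off-diagonal blocks, so uniform
#' translations are annihilated exactly.
#'
#' @param structure a [Structure()]
#' @param cutoff interaction cutoff in Angstrom (default 8)
#' @param spring `"uniform"` (k constant, default), `"inverse6"`
#'   (k proportional to r^-6), or a function of distance returning k
#' @param k force-constant scale (arbitrary units, default 1)
#' @return dense 3N x 3N symmetric Hessian (not mass-weighted)
#' @export
build_enm_hessian <- function(structure, cutoff = 8, spring = "uniform",
                              k = 1) {
  xyz <- structure$xyz
  N <- nrow(xyz)
  if (N < 2L) stop("need at least 2 atoms")
  if (cutoff <= 0) stop("cutoff must be positive")
  kfun <- if (is.function(spring)) spring
          else switch(match.arg(spring, c("uniform", "inverse6")),
                      uniform = function(r) rep(k, length(r)),
                      inverse6 = function(r) k * (r / cutoff)^-6)
  D <- as.matrix(stats::dist(xyz))
  within <- D > 0 & D <= cutoff
  if (any(rowSums(within) == 0))
    stop("isolated atom(s) with no neighbor within the cutoff: system disconnected (atom ",
         which(rowSums(within) == 0)[1], ")")
  H <- matrix(0, 3L * N, 3L * N)
  pairs <- which(upper.tri(within) & within, arr.ind = TRUE)
  kk <- kfun(D[pairs])
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    d <- xyz[j, ] - xyz[i, ]
    K <- kk[p] * tcrossprod(d) / sum(d^2)
    ri <- (3L * (i - 1L) + 1L):(3L * i)
    rj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ri, rj] <- H[ri, rj] - K
    H[rj, ri] <- H[rj, ri] - K
    H[ri, ri] <- H[ri, ri] + K
    H[rj, rj] <- H[rj, rj] + K
  }
  H
}

# Default block definition: one block per residue (chain + residue id),
# in atom order.
residue_blocks <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain_id, at$residue_id)
  unname(split(seq_len(nrow(at)), factor(key, levels = unique(key))))
}

# Orthonormal rigid-body basis (mass-weighted metric) for the atoms `idx`;
# columns live in the 3N space restricted to those atoms (3*length(idx) rows).
.block_rigid_basis <- function(xyz, masses) {
  n <- nrow(xyz)
  sq <- sqrt(masses)
  com <- colSums(xyz * masses) / sum(masses)
  rel <- sweep(xyz, 2, com)
  cols <- matrix(0, 3L * n, 6L)
  for (a in 1:3) {
    tr <- matrix(0, n, 3L); tr[, a] <- 1
    cols[, a] <- flatten_xyz(tr * sq)
  }
  ax <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(rel, 1, function(r) c(ax[a, 2] * r[3] - ax[a, 3] * r[2],
                                         ax[a, 3] * r[1] - ax[a, 1] * r[3],
                                         ax[a, 1] * r[2] - ax[a, 2] * r[1])))
    if (n == 1L) rot <- matrix(rot, 1L, 3L)
    cols[, 3L + a] <- flatten_xyz(rot * sq)
  }
  qr_d <- qr(cols)
  keep <- abs(diag(qr.R(qr_d))) > 1e-8 * sqrt(n)
  Q <- qr.Q(qr_d)[, seq_len(qr_d$rank), drop = FALSE]
  Q
}

.mass_weight_hessian <- function(hessian, masses) {
  inv_sq <- rep(1 / sqrt(masses), each = 3L)
  hessian * tcrossprod(inv_sq)
}

.modeset <- function(eigenvalues, cart_vectors, masses, block_sizes = NULL) {
  norms <- sqrt(colSums(cart_vectors^2))
  cart_vectors <- sweep(cart_vectors, 2, norms, "/")
  mx <- max(abs(eigenvalues))
  n_zero <- sum(abs(eigenvalues) < 1e-8 * mx)
  structure(list(eigenvalues = eigenvalues, vectors = cart_vectors,
                 n_zero = n_zero, masses = masses,
                 block_sizes = block_sizes),
            class = "NormalModeSet")
}

#' @export
print.NormalModeSet <- function(x, ...) {
  cat(sprintf("NormalModeSet: %d modes, %d rigid-body; first internal eigenvalue %.4g\n",
              length(x$eigenvalues), x$n_zero,
              x$eigenvalues[x$n_zero + 1L]))
  invisible(x)
}

#' Full elastic-network normal modes
#'
#' Diagonalizes the mass-weighted Hessian directly (no block reduction).
#' Eigenvalues are ascending; the first six vanish for a connected,
#' non-linear system. Vectors are returned as normalized Cartesian
#' displacements, mutually orthogonal in the mass-weighted metric.
#'
#' @param hessian from [build_enm_hessian()]
#' @param structure the [Structure()] the Hessian was built from (masses)
#' @return a `NormalModeSet`
#' @export
enm_modes <- function(hessian, structure) {
  masses <- structure$atoms$mass
  Hm <- .mass_weight_hessian(hessian, masses)
  eig <- eigen((Hm + t(Hm)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  cart <- vecs / rep(sqrt(masses), each = 3L)
  .modeset(vals, cart, masses)
}

#' RTB-reduced elastic-network normal modes
#'
#' Projects the mass-weighted Hessian onto the rigid-body subspace of the
#' blocks (3 translations + 3 rotations per block; rotational axes are
#' dropped for blocks with fewer than 3 non-collinear atoms), diagonalizes
#' the reduced matrix, and back-projects the eigenvectors to all-atom
#' Cartesian space. With single-atom blocks the reduction is exact.
#'
#' @param hessian from [build_enm_hessian()]
#' @param structure the [Structure()] the Hessian was built from
#' @param blocks list of atom-index vectors, one block per entry; default is
#'   one amino-acid residue per block
#' @return a `NormalModeSet`
#' @export
rtb_modes <- function(hessian, structure, blocks = NULL) {
  masses <- structure$atoms$mass
  N <- length(masses)
  if (is.null(blocks)) blocks <- residue_blocks(structure)
  if (any(lengths(blocks) == 0L)) stop("empty block")
  if (length(unique(unlist(blocks))) != N || length(unlist(blocks)) != N)
    stop("blocks must partition the atoms")
  Hm <- .mass_weight_hessian(hessian, masses)
  basis <- lapply(blocks, function(idx)
    .block_rigid_basis(structure$xyz[idx, , drop = FALSE], masses[idx]))
  ncols <- vapply(basis, ncol, integer(1))
  P <- matrix(0, 3L * N, sum(ncols))
  col0 <- 0L
  for (b in seq_along(blocks)) {
    rows <- as.vector(t(outer(blocks[[b]], 1:3,
                              function(i, a) 3L * (i - 1L) + a)))
    P[rows, (col0 + 1L):(col0 + ncols[b])] <- basis[[b]]
    col0 <- col0 + ncols[b]
  }
  Hred <- crossprod(P, Hm %*% P)
  eig <- eigen((Hred + t(Hred)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))
  vals <- eig$values[ord]
  V <- P %*% eig$vectors[, ord, drop = FALSE]
  cart <- V / rep(sqrt(masses), each = 3L)
  .modeset(vals, cart, masses, block_sizes = lengths(blocks))
}

#' Essential-dynamics principal component analysis
#'
#' Superposes every frame onto the iteratively fitted average structure over
#' `fit_selection`, then eigendecomposes the covariance of the
#' `analysis_selection` coordinates (population covariance, divisor F).
#' Eigenvalues are variances in Angstrom^2, descending; PC1 is the dominant
#' collective displacement ("MD mode 1").
#'
#' @param ensemble an [Ensemble()] with F >= 2
#' @param fit_selection atoms used for superposition (default `"all"`)
#' @param analysis_selection atoms entering the covariance (default: the
#'   fit selection)
#' @param mass_weighted weight coordinates by sqrt(mass) before the
#'   decomposition (default FALSE)
#' @param superpose superpose frames onto the average structure first
#'   (default TRUE); FALSE analyzes raw coordinates, appropriate when the
#'   input is already aligned
#' @return a `PCAResult`: list with `mean` ([Structure()]), `eigenvalues`,
#'   `vectors` (3n x K, orthonormal columns), `projections` (F x K), and the
#'   selections used
#' @export
pca <- function(ensemble, fit_selection = "all",
                analysis_selection = fit_selection, mass_weighted = FALSE,
                superpose = TRUE) {
  if (n_frames(ensemble) < 2L) stop("PCA needs at least 2 frames")
  idx <- resolve_selection(ensemble, analysis_selection)
  avg <- average_structure(ensemble, fit_selection)
  fitted <- if (superpose) superpose_ensemble(ensemble, avg, fit_selection)
            else ensemble
  F <- n_frames(fitted)
  X <- t(vapply(seq_len(F), function(k)
    flatten_xyz(fitted$coords[idx, , k]), numeric(3L * length(idx))))
  wt <- if (mass_weighted) rep(sqrt(ensemble$topology$atoms$mass[idx]),
                               each = 3L) else rep(1, 3L * length(idx))
  Xc <- sweep(sweep(X, 2, colMeans(X)), 2, wt, "*")
  sv <- svd(Xc)
  eigenvalues <- sv$d^2 / F
  structure(list(
    mean = avg, eigenvalues = eigenvalues, vectors = sv$v,
    projections = Xc %*% sv$v,
    fit_selection = fit_selection, analysis_selection = analysis_selection,
    atom_indices = idx, mass_weighted = mass_weighted
  ), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("PCAResult: %d modes; PC1 variance %.4g A^2 (%.1f%% of total)\n",
              length(x$eigenvalues), x$eigenvalues[1],
              100 * x$eigenvalues[1] / max(tot, .Machine$double.eps)))
  invisible(x)
}

#' Overlap between two displacement vectors
#'
#' The normalized inner product `a . b / (|a| |b|)` in \[-1, 1\], the
#' standard measure of similarity between an essential-dynamics eigenvector
#' and a normal mode. `centered = TRUE` gives the Pearson-correlation
#' variant (components centered before the product).
#'
#' @param vector_a,vector_b numeric vectors of equal length, both nonzero
#' @param centered center components first (default FALSE)
#' @return scalar overlap
#' @export
mode_overlap <- function(vector_a, vector_b, centered = FALSE) {
  if (length(vector_a) != length(vector_b)) stop("vector lengths differ")
  if (centered) {
    vector_a <- vector_a - mean(vector_a)
    vector_b <- vector_b - mean(vector_b)
  }
  na <- sqrt(sum(vector_a^2)); nb <- sqrt(sum(vector_b^2))
  if (na == 0 || nb == 0) stop("zero vector")
  sum(vector_a * vector_b) / (na * nb)
}

#' Restrict a 3N mode vector to a subset of atoms
#' @param vector a 3N displacement vector (per-atom interleaved)
#' @param atom_indices 1-based atom indices to keep, in order
#' @return a 3n vector over the kept atoms
#' @export
mode_subvector <- function(vector, atom_indices) {
  rows <- as.vector(t(outer(as.integer(atom_indices), 1:3,
                            function(i, a) 3L * (i - 1L) + a)))
  vector[rows]
}

#' Animate a structure along a mode
#'
#' Generates `n_frames` frames at
#' `x + amplitude * sin(2 * pi * k / n_frames) * v`, k = 0..n-1, for
#' visualizing a normal mode or principal component as a trajectory.
#'
#' @param structure a [Structure()]
#' @param mode_vector 3N displacement vector (will be unit-normalized)
#' @param amplitude peak displacement scale in Angstrom (> 0)
#' @param n_frames number of frames (default 20)
#' @return an [Ensemble()]
#' @export
animate_mode <- function(structure, mode_vector, amplitude = 2,
                         n_frames = 20) {
  if (amplitude <= 0) stop("amplitude must be positive")
  N <- nrow(structure$xyz)
  if (length(mode_vector) != 3L * N) stop("mode vector length != 3N")
  v <- unflatten_xyz(mode_vector / sqrt(sum(mode_vector^2)))
  coords <- array(NA_real_, c(N, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    s <- amplitude * sin(2 * pi * (k - 1L) / n_frames)
    coords[, , k] <- structure$xyz + s * v
  }
  Ensemble(structure, coords)
}

#' Write mode vectors as a plain-text table
#' @param modes a `NormalModeSet` or `PCAResult`
#' @param path output TSV path
#' @param which integer vector of mode numbers to write (columns)
#' @return `path`, invisibly
#' @export
write_modes_tsv <- function(modes, path, which = NULL) {
  V <- modes$vectors
  if (is.null(which)) which <- seq_len(min(ncol(V), 12L))
  out <- data.frame(atom = rep(seq_len(nrow(V) %/% 3L), each = 1L))
  for (m in which) {
    xyz <- unflatten_xyz(V[, m])
    out[[sprintf("mode%d_dx", m)]] <- xyz[, 1]
    out[[sprintf("mode%d_dy", m)]] <- xyz[, 2]
    out[[sprintf("mode%d_dz", m)]] <- xyz[, 3]
  }
  .write_tsv(out, path, "# normalized Cartesian mode displacement vectors")
  invisible(path)
}
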