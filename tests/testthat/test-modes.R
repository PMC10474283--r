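# Elastic-network normal modes, RTB reduction, PCA and overlap.

enm_energy <- function(xyz0, xyz, cutoff, k = 1) {
  D0 <- as.matrix(dist(xyz0))
  D <- as.matrix(dist(xyz))
  within <- D0 > 0 & D0 <= cutoff & upper.tri(D0)
  0.5 * k * sum((D[within] - D0[within])^2)
}

test_that("diatomic Hessian matches the closed form", {
  s <- Structure(atom_table(2), rbind(c(0, 0, 0), c(2, 0, 0)))
  k <- 3.7
  H <- build_enm_hessian(s, cutoff = 5, k = k)
  K <- matrix(0, 3, 3); K[1, 1] <- k
  expect_equal(H, rbind(cbind(K, -K), cbind(-K, K)))
  modes <- enm_modes(H, s)
  m <- s$atoms$mass[1]
  expect_equal(modes$n_zero, 5L)  # linear diatomic: 5 rigid-body modes
  expect_equal(modes$eigenvalues[6], 2 * k / m, tolerance = 1e-9)
})

test_that("Hessian annihilates translations and matches finite differences", {
  s <- random_ca_structure(30, seed = 61, spread = 5)
  H <- build_enm_hessian(s, cutoff = 8)
  # translational invariance: every 3-row band sums to zero over atoms
  for (a in 1:3) {
    tr <- matrix(0, 30, 3); tr[, a] <- 1
    expect_lt(max(abs(H %*% flat(tr))), 1e-10)
  }
  # numeric second derivative of the ENM energy
  h <- 1e-4
  idx <- c(1, 2, 3, 40, 41, 77)  # spot-check rows
  for (i in idx) {
    for (j in idx) {
      pert <- function(di, dj) {
        x <- flat(s$xyz)
        x[i] <- x[i] + di; x[j] <- x[j] + dj
        enm_energy(s$xyz, matrix(x, ncol = 3, byrow = TRUE), 8)
      }
      num <- (pert(h, h) - pert(h, -h) - pert(-h, h) + pert(-h, -h)) /
        (4 * h * h)
      expect_equal(H[i, j], num, tolerance = 1e-4)
    }
  }
  iso <- Structure(atom_table(3), rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)))
  expect_error(build_enm_hessian(iso, cutoff = 8), "disconnected")
})

test_that("RTB with single-atom blocks reproduces the full spectrum", {
  s <- random_ca_structure(25, seed = 62, spread = 4)
  H <- build_enm_hessian(s, cutoff = 8)
  full <- enm_modes(H, s)
  red <- rtb_modes(H, s, blocks = as.list(seq_len(25)))
  internal <- 7:30
  expect_equal(red$eigenvalues[internal], full$eigenvalues[internal],
               tolerance = 1e-6)
  expect_equal(full$n_zero, 6L)
  expect_equal(red$n_zero, 6L)
})

test_that("residue-block RTB keeps 6 zero modes and bounds the spectrum", {
  prot <- make_test_protein(12, seed = 63)
  H <- build_enm_hessian(prot, cutoff = 8)
  full <- enm_modes(H, prot)
  red <- rtb_modes(H, prot)  # one residue per block
  expect_equal(red$n_zero, 6L)
  # variational property: reduced eigenvalues bound the full ones above
  n_int <- 20
  expect_true(all(red$eigenvalues[6 + seq_len(n_int)] >=
                    full$eigenvalues[6 + seq_len(n_int)] - 1e-10))
  # vectors orthonormal in the mass-weighted metric
  m <- rep(prot$atoms$mass, each = 3)
  V <- red$vectors[, 7:12]
  G <- crossprod(V * sqrt(m))
  G <- G / sqrt(tcrossprod(diag(G)))
  expect_equal(G, diag(6), tolerance = 1e-8)
  expect_error(rtb_modes(H, prot, blocks = list(integer(0))), "empty block")
})

test_that("the hinge toy's softest internal mode is the planted hinge motion", {
  gen <- make_hinge_ensemble(hinge_spec(n_frames = 2, state_angles = 100,
                                        state_weights = 1, angle_sigma = 0,
                                        thermal_noise_sigma = 0, seed = 12))
  s <- get_frame(gen$ensemble, 1)
  H <- build_enm_hessian(s, cutoff = 8)
  modes <- rtb_modes(H, s)
  expect_equal(modes$n_zero, 6L)
  field <- hinge_displacement_field(s, gen$ground_truth)
  expect_gt(abs(mode_overlap(modes$vectors[, 7], field)), 0.8)
  expect_lt(abs(mode_overlap(modes$vectors[, 8], field)), 0.4)
})

test_that("PCA recovers planted displacement directions and the trace", {
  prot <- make_test_protein(15, seed = 64)
  N <- n_atoms(prot)
  e_same <- Ensemble(prot, array(rep(prot$xyz, 3), c(N, 3, 3)))
  pc0 <- pca(e_same, "all")
  expect_lt(max(pc0$eigenvalues), 1e-18)

  # frames displaced along a fixed rigid-free direction with unit variance
  set.seed(64)
  v <- flat(matrix(rnorm(N * 3), N, 3))
  sq <- rep(sqrt(prot$atoms$mass), each = 3)
  Q <- confens:::.block_rigid_basis(prot$xyz, prot$atoms$mass)
  vm <- v * sq
  v <- as.vector(vm - Q %*% crossprod(Q, vm)) / sq
  v <- v / sqrt(sum(v^2))
  F <- 80
  disp <- scale(rnorm(F))[, 1]  # exactly unit sample variance
  coords <- array(NA_real_, c(N, 3, F))
  for (k in seq_len(F))
    coords[, , k] <- prot$xyz + disp[k] * matrix(v, ncol = 3, byrow = TRUE)
  e <- Ensemble(prot, coords)
  pc <- pca(e, "all")
  expect_gt(abs(mode_overlap(pc$vectors[, 1], v)), 0.999)
  expect_equal(pc$eigenvalues[1], var(disp) * (F - 1) / F, tolerance = 1e-2)

  # trace oracle: total variance equals the mean squared fluctuation sum
  e2 <- random_ensemble(8, 40, seed = 65, spread = 2)
  pc2 <- pca(e2, "all")
  fitted <- superpose_ensemble(e2, average_structure(e2, "all"), "all")
  X <- t(sapply(seq_len(40), function(k) flat(fitted$coords[, , k])))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(pc2$eigenvalues), sum(Xc^2) / 40, tolerance = 1e-8)
  expect_equal(crossprod(pc2$vectors[, 1:5]), diag(5), tolerance = 1e-8)

  # independent oracle: eigendecomposition via prcomp on the same matrix
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(pc2$eigenvalues[1:5], pr$sdev[1:5]^2 * (39 / 40),
               tolerance = 1e-8)
  expect_gt(abs(mode_overlap(pc2$vectors[, 1], pr$rotation[, 1])), 0.999999)
})

test_that("mode_overlap handles signs, orthogonality and bad input", {
  v <- c(1, 2, 3, -1, 0.5, 2)
  expect_equal(mode_overlap(v, v), 1.0)
  expect_equal(mode_overlap(v, -v), -1.0)
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  expect_identical(mode_overlap(e1, e2), 0)
  expect_error(mode_overlap(v, v[1:3]), "length")
  expect_error(mode_overlap(v, numeric(6)), "zero vector")
  # centered variant equals the Pearson correlation
  set.seed(66)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(mode_overlap(a, b, centered = TRUE), cor(a, b),
               tolerance = 1e-12)
})

test_that("animate_mode produces sinusoidal displacements along the mode", {
  prot <- make_test_protein(10, seed = 67)
  N <- n_atoms(prot)
  set.seed(67)
  v <- rnorm(3 * N); v <- v / sqrt(sum(v^2))
  amp <- 1.5; nf <- 16
  anim <- animate_mode(prot, v, amplitude = amp, n_frames = nf)
  for (k in c(1, 3, 8, 12)) {
    expected <- abs(amp * sin(2 * pi * (k - 1) / nf)) / sqrt(N)
    got <- rmsd(get_frame(anim, k), prot, "all", fit = FALSE)
    expect_equal(got, expected, tolerance = 1e-9)
  }
  expect_error(animate_mode(prot, v, amplitude = 0), "positive")

  # animation along a rigid rotation mode leaves Rg unchanged to first order
  H <- build_enm_hessian(prot, cutoff = 8)
  modes <- rtb_modes(H, prot)
  rigid <- modes$vectors[, 4]  # a rotational zero mode
  anim2 <- animate_mode(prot, rigid, amplitude = 1e-4, n_frames = 8)
  rgs <- rg_series(anim2, "all")
  expect_lt(diff(range(rgs)), 1e-6)
})
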