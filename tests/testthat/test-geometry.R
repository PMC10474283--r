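# Geometric measurements: centers of mass, distances, angles, Rg, Kabsch
# superposition and RMSD.

test_that("center_of_mass matches direct summation and symmetry cases", {
  s1 <- Structure(atom_table(1), matrix(c(1, 2, 3), 1))
  expect_equal(center_of_mass(s1, "all"), c(1, 2, 3))

  s2 <- Structure(atom_table(2), rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(center_of_mass(s2, "all"), c(0, 0, 0))

  set.seed(21)
  at <- atom_table(50, element = sample(c("C", "N", "O", "S"), 50, TRUE))
  xyz <- matrix(rnorm(150), 50, 3)
  s <- Structure(at, xyz)
  m <- s$atoms$mass
  expect_equal(center_of_mass(s, "all"),
               colSums(xyz * m) / sum(m), tolerance = 1e-12)
  expect_equal(center_of_mass(s, "all", "geometric"), colMeans(xyz),
               tolerance = 1e-12)
})

test_that("group_distance and min_distance agree with brute force", {
  s <- Structure(atom_table(2), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(group_distance(s, 1, 2), 5.0)
  expect_equal(group_distance(s, c(1, 2), c(1, 2)), 0)
  expect_equal(min_distance(s, 1, 2), 5.0)

  set.seed(22)
  s2 <- random_ca_structure(100, seed = 22)
  ia <- 1:40; ib <- 41:100
  d_oracle <- min(sapply(ia, function(i) sapply(ib, function(j)
    sqrt(sum((s2$xyz[i, ] - s2$xyz[j, ])^2)))))
  expect_equal(min_distance(s2, ia, ib), d_oracle, tolerance = 1e-12)
  coma <- colMeans(s2$xyz[ia, ])
  comb <- colMeans(s2$xyz[ib, ])
  expect_equal(group_distance(s2, ia, ib, "geometric"),
               sqrt(sum((coma - comb)^2)), tolerance = 1e-12)
  expect_error(min_distance(s2, 1:5, 5:10), "overlap")
})

test_that("min_distance series decreases for a linearly approaching ligand", {
  n <- 10
  coords <- array(NA_real_, c(2, 3, n))
  for (k in seq_len(n)) coords[, , k] <- rbind(c(0, 0, 0), c(20 - k, 0, 0))
  e <- Ensemble(Structure(atom_table(2), coords[, , 1]), coords)
  ser <- min_distance_series(e, 1, 2)
  expect_equal(ser, 19:10)
  expect_true(all(diff(ser) < 0))
})

test_that("group_angle reproduces closed forms and the arccos oracle", {
  s <- Structure(atom_table(3), rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(group_angle(s, 1, 2, 3, vertex = "B"), 180.0)

  s2 <- Structure(atom_table(3), rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(group_angle(s2, 1, 2, 3, vertex = "B"), 90.0)

  set.seed(23)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(9, sd = 5), 3, 3)
    s3 <- Structure(atom_table(3), xyz)
    u <- xyz[1, ] - xyz[2, ]; v <- xyz[3, ] - xyz[2, ]
    expected <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(group_angle(s3, 1, 2, 3, vertex = "B"), expected,
                 tolerance = 1e-10)
    # invariance under uniform scaling about the vertex
    s4 <- s3
    s4$xyz <- sweep(sweep(s3$xyz, 2, xyz[2, ]) * 3.7, 2, xyz[2, ], "+")
    expect_equal(group_angle(s4, 1, 2, 3, vertex = "B"), expected,
                 tolerance = 1e-9)
  }
  s5 <- Structure(atom_table(3), rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(group_angle(s5, 1, 2, 3, vertex = "B"), "degenerate")
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  s1 <- Structure(atom_table(1), matrix(c(5, 5, 5), 1))
  expect_equal(radius_of_gyration(s1, "all"), 0)

  d <- 7.3
  s2 <- Structure(atom_table(2), rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(radius_of_gyration(s2, "all"), d / 2)

  set.seed(24)
  at <- atom_table(60, element = sample(c("C", "N", "O"), 60, TRUE))
  xyz <- matrix(rnorm(180, sd = 4), 60, 3)
  s <- Structure(at, xyz)
  m <- s$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  expected <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(s, "all"), expected, tolerance = 1e-10)

  R <- random_rotation(24)
  s_rot <- s
  s_rot$xyz <- sweep(xyz %*% R, 2, c(10, -4, 2), "+")
  expect_equal(radius_of_gyration(s_rot, "all"), expected, tolerance = 1e-9)
  ia <- 1:30; ib <- 31:60
  expect_equal(group_distance(s_rot, ia, ib), group_distance(s, ia, ib),
               tolerance = 1e-9)
})

test_that("kabsch_fit recovers planted rigid transforms exactly", {
  s <- random_ca_structure(40, seed = 25)
  tr <- kabsch_fit(s, s, "all")
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-10)

  Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mob <- s
  mob$xyz <- sweep(s$xyz %*% t(Rz90), 2, c(5, 0, 0), "+")
  tr2 <- kabsch_fit(mob, s, "all")
  expect_lt(rmsd(mob, s, "all"), 1e-10)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-10)

  for (seed in 26:30) {
    R <- random_rotation(seed)
    set.seed(seed)
    shift <- rnorm(3, sd = 20)
    mob2 <- s
    mob2$xyz <- sweep(s$xyz %*% R, 2, shift, "+")
    expect_lt(rmsd(mob2, s, "all"), 1e-9)
    expect_equal(det(kabsch_fit(mob2, s, "all")$rotation), 1,
                 tolerance = 1e-9)
  }

  col <- Structure(atom_table(4), cbind(1:4, 0, 0))
  expect_error(kabsch_fit(col, col, "all"), "collinear")
})

test_that("rmsd separates fit and calc selections and matches bio3d", {
  s <- random_ca_structure(30, seed = 31)
  expect_equal(rmsd(s, s, "all"), 0)

  # calc group rigidly displaced +2 A after perfect fit-group match
  mob <- s
  calc <- 21:30
  mob$xyz[calc, 1] <- mob$xyz[calc, 1] + 2
  expect_equal(rmsd(mob, s, fit_selection = 1:20, calc_selection = calc),
               2.0, tolerance = 1e-9)

  set.seed(32)
  for (rep in 1:5) {
    mob2 <- s
    mob2$xyz <- s$xyz + matrix(rnorm(90, sd = 0.5), 30, 3)
    mine <- rmsd(mob2, s, "all")
    ref <- bio3d::rmsd(flat(s$xyz), flat(mob2$xyz), fit = TRUE)
    expect_equal(mine, ref, tolerance = 2e-3)  # bio3d reports 3 decimals
    expect_equal(rmsd(mob2, s, "all"), rmsd(s, mob2, "all"),
                 tolerance = 1e-9)
  }
})

test_that("average_structure converges to the planted mean", {
  s <- random_ca_structure(20, seed = 33)
  e_same <- Ensemble(s, array(rep(s$xyz, 3), c(20, 3, 3)))
  avg <- average_structure(e_same, "all")
  expect_equal(avg$xyz, s$xyz, tolerance = 1e-9)

  # two frames mirror-displaced along one coordinate; fitting on the
  # undisplaced atoms makes the superposition exactly the identity
  up <- s$xyz; up[5, 1] <- up[5, 1] + 0.4
  dn <- s$xyz; dn[5, 1] <- dn[5, 1] - 0.4
  e2 <- Ensemble(s, array(c(up, dn), c(20, 3, 2)))
  avg2 <- average_structure(e2, setdiff(1:20, 5))
  expect_equal(avg2$xyz, s$xyz, tolerance = 1e-9)

  # planted-noise ensemble: per-coordinate error within 3 sigma / sqrt(F)
  set.seed(34)
  F <- 200; sigma <- 0.1
  coords <- array(rep(s$xyz, F) + rnorm(20 * 3 * F, sd = sigma),
                  c(20, 3, F))
  avg3 <- average_structure(Ensemble(s, coords), "all")
  expect_lt(max(abs(avg3$xyz - s$xyz)), 4 * sigma / sqrt(F) + 0.02)
})
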