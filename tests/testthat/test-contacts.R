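# Contact prevalence, contact matrices, hydrogen-bond proxy, residue
# classification and occupancy grids.

test_that("contact prevalence counts planted schedules exactly", {
  prot <- make_test_protein(12, seed = 71)
  lt <- make_ligand_trajectory(prot, 0.6, n_frames = 5, seed = 71)
  # exactly 3 of 5 frames bound
  expect_equal(sum(lt$ground_truth$bound), 3L)
  tab <- contact_prevalence(lt$ensemble, "protein", "resname LIG")
  target <- tab$residue_id == lt$ground_truth$target_residue
  expect_equal(tab$percentage[target], 60.0)
  expect_true(all(tab$percentage[!target] == 0))

  # fixed ligand at 2.0 A from one residue in every frame
  lt2 <- make_ligand_trajectory(prot, 1.0, contact_distance = 2.0,
                                n_frames = 4, seed = 72)
  tab2 <- contact_prevalence(lt2$ensemble, "protein", "resname LIG")
  expect_equal(tab2$percentage[tab2$residue_id ==
                                 lt2$ground_truth$target_residue], 100.0)
  expect_true(all(tab2$percentage[tab2$residue_id !=
                                    lt2$ground_truth$target_residue] == 0))
  expect_error(contact_prevalence(lt$ensemble, "protein", "ca"), "overlap")
})

test_that("contact prevalence equals the all-pairs oracle on random input", {
  set.seed(73)
  for (rep in 1:6) {
    n <- 14
    at <- atom_table(n, residue_id = rep(1:7, each = 2),
                     element = sample(c("C", "N", "O", "H"), n, TRUE))
    coords <- array(runif(n * 3 * 8, 0, 10), c(n, 3, 8))
    e <- Ensemble(Structure(at, coords[, , 1]), coords)
    ia <- which(at$residue_id <= 4)
    ib <- which(at$residue_id > 4)
    tab <- contact_prevalence(e, ia, ib, cutoff = 3.5)
    expect_equal(tab$percentage, round(unname(contact_oracle(e, ia, ib, 3.5)), 1),
                 tolerance = 1e-9)
  }
})

test_that("contact prevalence is monotone in cutoff and frame-duplication invariant", {
  set.seed(74)
  n <- 12
  at <- atom_table(n, residue_id = rep(1:6, each = 2))
  coords <- array(runif(n * 3 * 6, 0, 8), c(n, 3, 6))
  e <- Ensemble(Structure(at, coords[, , 1]), coords)
  ia <- 1:6; ib <- 7:12
  p1 <- contact_prevalence(e, ia, ib, cutoff = 2.5)$percentage
  p2 <- contact_prevalence(e, ia, ib, cutoff = 3.5)$percentage
  p3 <- contact_prevalence(e, ia, ib, cutoff = 5.0)$percentage
  expect_true(all(p2 >= p1) && all(p3 >= p2))

  dup <- Ensemble(e$topology, e$coords[, , rep(1:6, 2)])
  expect_equal(contact_prevalence(dup, ia, ib, 3.5)$percentage, p2)

  # inclusive boundary: a pair at exactly the cutoff counts
  s2 <- Structure(atom_table(2, residue_id = 1:2),
                  rbind(c(0, 0, 0), c(3.5, 0, 0)))
  tab <- contact_prevalence(as_ensemble(s2), 1, 2, cutoff = 3.5)
  expect_equal(tab$percentage, 100.0)
})

test_that("contact_matrix resolves residue pairs consistently", {
  # one always-touching pair among several residues
  at <- atom_table(6, residue_id = c(1, 2, 3, 11, 12, 13))
  xyz <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0),
               c(2, 0, 0), c(60, 0, 0), c(80, 0, 0))
  e <- as_ensemble(Structure(at, xyz))
  m <- contact_matrix(e, 1:3, 4:6)
  expect_equal(sum(m == 100), 1L)
  expect_equal(m["ALA1", "ALA11"], 100.0)
  expect_equal(sum(m), 100.0)

  # against a single-residue partner the row maximum is the prevalence
  prot <- make_test_protein(10, seed = 75)
  lt <- make_ligand_trajectory(prot, 0.4, n_frames = 10, seed = 75)
  tab <- contact_prevalence(lt$ensemble, "protein", "resname LIG")
  m2 <- contact_matrix(lt$ensemble, "protein", "resname LIG")
  expect_equal(unname(apply(m2, 1, max)), tab$percentage)
  expect_error(contact_matrix(lt$ensemble, "protein", "protein"), "overlap")
})

test_that("hbond proxy applies distance and angle criteria", {
  at <- data.frame(serial = 1:3, atom_name = c("N", "H", "O"),
                   element = c("N", "H", "O"),
                   residue_name = c("ALA", "ALA", "SER"),
                   residue_id = c(1L, 1L, 2L), chain_id = "A",
                   stringsAsFactors = FALSE)
  lin <- Structure(at, rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  e <- as_ensemble(lin)
  tab <- hbond_proxy(e, donors = 1, acceptors = 3)
  expect_equal(tab$prevalence, 100.0)
  # angle criterion: N-H-O is linear here, 180 degrees
  tab2 <- hbond_proxy(e, donors = 1, acceptors = 3, angle_min = 150)
  expect_equal(tab2$prevalence, 100.0)
  # bent arrangement fails a tight angle criterion
  bent <- lin
  bent$xyz[3, ] <- c(1, 2.8, 0)
  e2 <- as_ensemble(bent)
  expect_equal(hbond_proxy(e2, 1, 3, angle_min = 150)$prevalence, 0.0)
  expect_equal(hbond_proxy(e2, 1, 3)$prevalence, 100.0)

  far <- lin; far$xyz[3, 1] <- 4.0
  expect_equal(hbond_proxy(as_ensemble(far), 1, 3)$prevalence, 0.0)

  # 50% schedule
  coords <- array(c(lin$xyz, far$xyz), c(3, 3, 2))
  e3 <- Ensemble(lin, coords)
  expect_equal(hbond_proxy(e3, 1, 3)$prevalence, 50.0)
  expect_error(hbond_proxy(e, donors = 2, acceptors = 3), "N and O")
})

test_that("residue classification partitions the twenty amino acids", {
  tab <- data.frame(chain = "A", residue_id = 1:20,
                    residue_name = c("ALA", "ARG", "ASN", "ASP", "CYS",
                                     "GLN", "GLU", "GLY", "HIS", "ILE",
                                     "LEU", "LYS", "MET", "PHE", "PRO",
                                     "SER", "THR", "TRP", "TYR", "VAL"),
                    contact_frames = 20:1,
                    percentage = seq(100, 5, by = -5),
                    stringsAsFactors = FALSE)
  cls <- classify_residue_contacts(tab)
  expect_equal(as.vector(table(cls$class)[c("hydrophobic", "polar",
                                            "charged")]), c(9L, 7L, 4L))
  expect_equal(cls$class[cls$residue_name == "LEU"], factor("hydrophobic",
    levels = c("hydrophobic", "polar", "charged", "other")))
  expect_equal(as.character(cls$class[cls$residue_name == "LYS"]), "charged")
  # sorted by percentage within class
  for (cl in c("hydrophobic", "polar", "charged"))
    expect_false(is.unsorted(rev(cls$percentage[cls$class == cl])))

  tab$residue_name[1] <- "XYZ"
  expect_warning(cls2 <- classify_residue_contacts(tab), "XYZ")
  expect_equal(as.character(cls2$class[cls2$residue_name == "XYZ"]), "other")
})

test_that("occupancy grids count binary per-frame presence", {
  prot <- make_test_protein(8, seed = 76)
  hs <- make_hydrated_site(prot, 1.0, n_frames = 10, seed = 76)
  g1 <- occupancy_grid(hs$ensemble, "water and heavy")
  expect_equal(nrow(g1$sites), 1L)
  expect_equal(g1$sites$occupancy, 1.0)

  hs2 <- make_hydrated_site(prot, 0.5, n_frames = 40, seed = 77)
  g2 <- occupancy_grid(hs2$ensemble, "water and heavy")
  expect_equal(max(g2$occupancy), 0.5)
  expect_equal(g2$sites$occupancy[1], 0.5)
  expect_true(all(g2$occupancy * 40 == round(g2$occupancy * 40)))

  # brute-force binning oracle on the per-frame occupied voxel count
  set.seed(78)
  n <- 6
  at <- atom_table(n, atom_name = "O", element = "O", residue_name = "HOH")
  coords <- array(runif(n * 3 * 5, 0, 6), c(n, 3, 5))
  e <- Ensemble(Structure(at, coords[, , 1]), coords)
  g3 <- occupancy_grid(e, "all", spacing = 1)
  total <- sum(g3$occupancy) * 5
  oracle <- 0
  lo <- apply(coords, 2, min) - 1
  for (k in 1:5)
    oracle <- oracle + nrow(unique(floor(sweep(coords[, , k], 2, lo))))
  expect_equal(total, oracle)
})

test_that("DX export round-trips the grid for standard viewers", {
  prot <- make_test_protein(8, seed = 79)
  hs <- make_hydrated_site(prot, 0.5, n_frames = 20, seed = 79)
  g <- occupancy_grid(hs$ensemble, "water and heavy")
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  dx <- read_dx(path)
  expect_equal(dx$dims, unname(g$dims))
  expect_equal(max(dx$values), 0.5)
  expect_equal(dx$values, unname(g$occupancy), tolerance = 1e-6)
  lines <- readLines(path)
  expect_true(any(grepl("gridpositions", lines)))
  expect_true(any(grepl("0.500000", lines, fixed = TRUE)))
})
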