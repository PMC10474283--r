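# Structure and ensemble input/output and the selection grammar.

test_that("parse_structure reads single records and MODEL blocks", {
  txt <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  e <- parse_structure(txt)
  expect_equal(n_frames(e), 1L)
  expect_equal(n_atoms(e), 1L)
  expect_equal(as.vector(e$coords[1, , 1]), c(1, 2, 3))

  lines <- c("MODEL     1",
             sprintf("ATOM  %5d  CA  ALA A%4d      %8.3f%8.3f%8.3f", 1:3, 1:3,
                     1:3, 0, 0),
             "ENDMDL", "MODEL     2",
             sprintf("ATOM  %5d  CA  ALA A%4d      %8.3f%8.3f%8.3f", 1:3, 1:3,
                     4:6, 0, 0),
             "ENDMDL", "END")
  # fix column alignment of hand-rolled records via the package writer instead
  s <- Structure(atom_table(3), cbind(1:3, 0, 0))
  e2 <- parse_structure(write_structure(Ensemble(s, array(c(cbind(1:3, 0, 0),
        cbind(4:6, 0, 0)), c(3, 3, 2)))))
  expect_equal(n_frames(e2), 2L)
  expect_equal(n_atoms(e2), 3L)
})

test_that("parse_structure reports inconsistent models and bad coordinates", {
  s <- Structure(atom_table(2), cbind(1:2, 0, 0))
  txt <- write_structure(Ensemble(s, array(0, c(2, 3, 2))))
  lines <- strsplit(txt, "\n")[[1]]
  broken <- paste(lines[-6], collapse = "\n")  # drop an atom from model 2
  expect_error(parse_structure(broken), "model 2")

  bad <- sub("0\\.000", "x.000", lines[2])
  expect_error(parse_structure(paste(c(lines[1], bad, lines[3:4]),
                                     collapse = "\n")), "line 2")
})

test_that("write_structure emits bare ATOM records or MODEL blocks", {
  s <- Structure(atom_table(1), matrix(c(1, 2, 3), 1))
  txt <- write_structure(s)
  expect_equal(sum(grepl("^ATOM", strsplit(txt, "\n")[[1]])), 1L)
  expect_false(grepl("MODEL", txt))

  e <- Ensemble(s, array(rnorm(9), c(1, 3, 3)))
  lines <- strsplit(write_structure(e), "\n")[[1]]
  expect_equal(sum(startsWith(lines, "MODEL")), 3L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 3L)
  expect_error(write_structure(Structure(atom_table(1),
                                         matrix(c(12345, 0, 0), 1))),
               "10000")
})

test_that("PDB round-trip reproduces coordinates to PDB precision", {
  set.seed(11)
  e <- random_ensemble(100, 5, seed = 11)
  e2 <- parse_structure(write_structure(e))
  expect_lt(max(abs(e2$coords - e$coords)), 5.001e-4)
  # idempotence: a second round trip is exact
  e3 <- parse_structure(write_structure(e2))
  expect_identical(e3$coords, e2$coords)
  expect_identical(e2$topology$atoms$residue_id, e$topology$atoms$residue_id)
})

test_that("written PDB is readable by an independent parser", {
  e <- make_hinge_ensemble(hinge_spec(n_frames = 2, seed = 3))$ensemble
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, path)
  ref <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(ref$atom), n_atoms(e))
  expect_equal(ref$atom$resno, e$topology$atoms$residue_id)
  xyz1 <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(xyz1 - e$coords[, , 1])), 5.001e-4)
})

test_that("XYZ dialect round-trips coordinates and times", {
  e <- make_hinge_ensemble(hinge_spec(n_frames = 4, seed = 2))$ensemble
  e2 <- parse_xyz_frames(write_xyz_frames(e))
  expect_lt(max(abs(e2$coords - e$coords)), 5.1e-5)
  expect_equal(e2$times, e$times)
  expect_equal(e2$topology$atoms$residue_id, e$topology$atoms$residue_id)
  expect_error(parse_xyz_frames("3\nt=0\nCA ALA 1 0 0 0"), "truncated")
})

test_that("element inference prefers two-letter symbols then first letter", {
  expect_equal(infer_element(c("CA", "CL", "1HG1", "OXT", "NA", "BR")),
               c("C", "CL", "H", "O", "N", "BR"))
})

test_that("selection grammar resolves ranges, keywords and boolean algebra", {
  s <- random_ca_structure(31, seed = 4)
  s$atoms$residue_id <- 100:130
  sel <- select(s, "resid 113-116 and ca")
  expect_equal(length(sel$indices), 4L)
  expect_equal(s$atoms$residue_id[sel$indices], 113:116)

  w <- water_structure()
  expect_equal(length(select(w, "heavy")$indices), 1L)
  expect_equal(length(select(w, "water")$indices), 3L)
  expect_equal(length(select(w, "protein")$indices), 0L)

  expect_error(select(s, "resid 113-"), "position")
  expect_error(select(s, "ca and"), "end of expression")
  expect_error(select(s, "(ca"), "')'")
})

test_that("selection complement and de Morgan identities hold", {
  prot <- make_test_protein(15, seed = 6)
  exprs <- c("ca", "resid 3-7", "name N,O", "backbone and resid 2-10",
             "heavy or water")
  for (e in exprs) {
    a <- select(prot, e)$indices
    b <- select(prot, paste("not (", e, ")"))$indices
    expect_equal(sort(c(a, b)), seq_len(n_atoms(prot)))
    expect_length(intersect(a, b), 0)
  }
  lhs <- select(prot, "not (ca or name O)")$indices
  rhs <- select(prot, "not ca and not name O")$indices
  expect_equal(lhs, rhs)
  lhs2 <- select(prot, "not (ca and resid 2-5)")$indices
  rhs2 <- select(prot, "not ca or not resid 2-5")$indices
  expect_equal(lhs2, rhs2)
})

test_that("time_window keeps a half-open interval and is idempotent", {
  n <- 500
  e <- random_ensemble(5, n, seed = 7)
  e$times <- (seq_len(n) - 1) * 1000  # 1 ns spacing, ps units
  w <- time_window(e, 50000, 500000)
  expect_equal(n_frames(w), 450L)
  expect_equal(w$times[1], 50000)

  all_w <- time_window(e, 0, max(e$times) + 1)
  expect_equal(all_w$coords, e$coords)

  w2 <- time_window(w, 50000, 500000)
  expect_equal(w2$coords, w$coords)

  # brute-force linear scan oracle on an irregular window
  keep <- which(e$times >= 123456 & e$times < 333333)
  w3 <- time_window(e, 123456, 333333)
  expect_equal(w3$coords, e$coords[, , keep, drop = FALSE])

  expect_error(time_window(e, 1e9, 2e9), "no frames")

  e$times <- NULL
  wf <- time_window(e, frame_start = 51, frame_end = 501)
  expect_equal(n_frames(wf), 450L)
})
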