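# Deterministic synthetic-ensemble generators with exact ground truth.
#
# These stand in for undeposited MD trajectories: they reproduce the
# statistical structure the analyses assume (two-state hinge geometry,
# planted contact schedules, planted site occupancies, a labeled membrane
# slab) while making every downstream statistic predictable exactly or
# within stated stochastic bounds. They are not force-field dynamics.

.CHAIN_SPACING <- 3.8  # CA-CA virtual bond length, Angstrom

# Concatenate atom tables; the derived mass column is dropped so the new
# Structure re-derives it from the elements.
.rbind_atoms <- function(a, b) {
  a$mass <- NULL; b$mass <- NULL
  rbind(a, b)
}

# Run expr with a private RNG stream; the caller's stream is untouched.
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# rotation matrix about z by theta degrees (active, x %*% t(R))
.rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# proper rotation taking unit vector a onto unit vector b (Rodrigues)
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# serpentine walk through an nx x ny x (ceiling) lattice; consecutive points
# are one spacing apart, giving a compact chain-contiguous blob
.snake_lattice <- function(n, nx, ny, spacing = .CHAIN_SPACING) {
  out <- matrix(NA_real_, n, 3)
  for (r in seq_len(n) - 1L) {
    iz <- r %/% (nx * ny)
    rem <- r %% (nx * ny)
    iy <- rem %/% nx
    if (iz %% 2L == 1L) iy <- ny - 1L - iy
    ix <- rem %% nx
    if (iy %% 2L == 1L) ix <- nx - 1L - ix
    out[r + 1L, ] <- c(ix, iy, iz) * spacing
  }
  out
}

# residue names for a pseudo-protein in mature-sequence numbering: positions
# referenced by the built-in CV definitions get their canonical identities,
# the rest cycle through a fixed mixed-chemistry set
.pseudo_residue_names <- function(resids) {
  cycle <- c("ALA", "VAL", "SER", "LEU", "THR", "GLU", "GLY", "LYS")
  nm <- cycle[(resids %% length(cycle)) + 1L]
  special <- c(`22` = "PRO", `31` = "ARG", `32` = "ARG", `59` = "LYS",
               `60` = "CYS", `61` = "CYS", `62` = "VAL", `63` = "PHE",
               `67` = "LYS", `68` = "LYS", `69` = "CYS", `70` = "LEU",
               `71` = "ASP", `72` = "SER", `73` = "LYS", `74` = "GLY",
               `75` = "ASP", `76` = "VAL", `78` = "GLU", `90` = "PHE",
               `96` = "ASP", `100` = "ASN", `107` = "TYR", `110` = "CYS",
               `113` = "ASN", `114` = "ASN", `115` = "ASN", `116` = "ASN",
               `118` = "GLN", `120` = "LYS", `129` = "ASN", `133` = "PRO")
  hit <- as.character(resids) %in% names(special)
  nm[hit] <- special[as.character(resids[hit])]
  nm
}

.ca_atom_table <- function(resids, chain = "A") {
  data.frame(
    serial = seq_along(resids),
    atom_name = "CA",
    element = "C",
    residue_name = .pseudo_residue_names(resids),
    residue_id = as.integer(resids),
    chain_id = chain,
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic two-domain hinge ensemble
#'
#' Defaults encode the emulated study conditions: a closed state near 85
#' degrees and an open state near 118 degrees, populated 70/30, with a
#' 3-degree intra-state angular spread and 0.15 A isotropic coordinate
#' noise, sampled every 10 ps.
#'
#' @param n_frames number of frames (default 2000)
#' @param state_angles interdomain angle of each state, degrees
#' @param state_weights state probabilities (summing to 1)
#' @param angle_sigma within-state angular standard deviation, degrees
#' @param thermal_noise_sigma isotropic per-atom coordinate noise, Angstrom
#' @param frame_dt frame spacing, ps
#' @param seed RNG seed (default 0)
#' @return a `hinge_spec` list
#' @export
hinge_spec <- function(n_frames = 2000, state_angles = c(85, 118),
                       state_weights = c(0.7, 0.3), angle_sigma = 3,
                       thermal_noise_sigma = 0.15, frame_dt = 10, seed = 0) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (length(state_angles) != length(state_weights))
    stop("state_angles and state_weights differ in length")
  if (abs(sum(state_weights) - 1) > 1e-9) stop("state weights must sum to 1")
  if (any(state_weights < 0)) stop("negative state weight")
  if (angle_sigma < 0 || thermal_noise_sigma < 0) stop("sigmas must be >= 0")
  if (any(state_angles <= 0 | state_angles >= 180))
    stop("state angles must lie in (0, 180) degrees")
  list(n_frames = as.integer(n_frames), state_angles = state_angles,
       state_weights = state_weights, angle_sigma = angle_sigma,
       thermal_noise_sigma = thermal_noise_sigma, frame_dt = frame_dt,
       seed = seed)
}

# Rigid placement of the N-terminal domain: its designated angle-group
# center of mass goes on the +x axis with the domain body extending further
# along +x, and the domain face kept `gap` Angstrom clear of the hinge.
.place_domain_a <- function(xyz, group_idx, gap = 5.0) {
  gcom <- colMeans(xyz[group_idx, , drop = FALSE])
  centroid <- colMeans(xyz)
  dir <- centroid - gcom
  if (sqrt(sum(dir^2)) < 1e-6) dir <- c(1, 0, 0)
  R <- .rotation_between(dir, c(1, 0, 0))
  xyz <- sweep(xyz, 2, gcom) %*% t(R)
  gcom2 <- colMeans(xyz[group_idx, , drop = FALSE])  # origin by construction
  shift <- c(gap - min(xyz[, 1]), 0, 0)
  xyz <- sweep(xyz, 2, shift, "+")
  xyz
}

# Rigid placement of the C-terminal domain in its reference orientation:
# vertex-group COM exactly at the origin (the hinge point) and arm-group COM
# on the +x axis; per-frame rotation about z then sets the interdomain angle
# exactly.
.place_domain_b <- function(xyz, vertex_idx, arm_idx) {
  vcom <- colMeans(xyz[vertex_idx, , drop = FALSE])
  xyz <- sweep(xyz, 2, vcom)
  acom <- colMeans(xyz[arm_idx, , drop = FALSE])
  R <- .rotation_between(acom, c(1, 0, 0))
  xyz %*% t(R)
}

#' Generate a two-domain hinge ensemble with exact ground truth
#'
#' Builds a CA-only pseudo-protein in mature-sequence numbering: two rigid,
#' deliberately elongated bead-column domains (N-terminal residues 22-70,
#' C-terminal residues 76-133) joined by a 5-residue hinge strip (residues
#' 71-75) alongside the rotation axis. The C-terminal domain is placed so
#' the center of mass of its designated vertex group (residues 120-129)
#' sits exactly on the hinge. Per frame a state is drawn from
#' `state_weights`, the interdomain angle from
#' `Normal(state_angle, angle_sigma)`, and the C-terminal domain is rotated
#' about the hinge axis by that angle, so the built-in `interdomain_theta`
#' collective variable recovers the drawn angle exactly in the noiseless
#' limit. Isotropic Gaussian coordinate noise is added last.
#'
#' Two geometric choices serve the downstream analyses: the long lever arms
#' separate distinct angular states by well over the 4 A clustering cutoff
#' in best-fit RMSD, and the near-axis hinge strip barely resists in-plane
#' hinge rotation (elastic springs to a bead on the rotation axis are
#' orthogonal to that motion), so the softest internal elastic-network mode
#' of the structure is the planted hinge motion (see
#' [hinge_displacement_field()]). The strip is a stylized hinge, not a
#' geometrically contiguous backbone segment.
#'
#' @param spec a [hinge_spec()] (or arguments forwarded to it via `...`)
#' @param ... used when `spec` is missing
#' @return list with `ensemble` (an [Ensemble()]) and `ground_truth`: per-
#'   frame `state` labels and exact `angle` values, the hinge point/axis,
#'   atom index sets of the two domains and linker, and the CV group
#'   definitions the generator guarantees
#' @export
make_hinge_ensemble <- function(spec = hinge_spec(...), ...) {
  na <- 49L; nl <- 5L; nb <- 58L
  resid_a <- 22:70; resid_l <- 71:75; resid_b <- 76:133
  group_i_resid <- c(60:62, 67:69)
  vertex_resid <- 120:129
  arm_resid <- c(90:96, 100:107)

  # Domains are elongated 2 x 2 bead columns (cross spacing 3.8 A, layer
  # pitch 6.0 A, both inside the 8 A elastic-network cutoff). The
  # deliberately large aspect ratio gives the hinge rotation a long lever
  # arm, so distinct angular states are well separated in best-fit RMSD --
  # the property the downstream clustering analyses rely on.
  cross <- matrix(c(-1.9, -1.9, 1.9, -1.9, -1.9, 1.9, 1.9, 1.9), 4, 2,
                  byrow = TRUE)
  pitch <- 6.0
  column_slots <- function(n) t(vapply(seq_len(n) - 1L, function(s)
    c(s %/% 4L * pitch, cross[s %% 4L + 1L, ]), numeric(3)))

  .with_seed(spec$seed, function() {
    # domain A: elongated 2 x 2 column, C-terminal (hinge-facing) residues
    # at the near end so the designated angle group keeps a useful lever arm
    xa <- matrix(NA_real_, na, 3L)
    xa[match(rev(resid_a), resid_a), ] <- column_slots(na)
    xa <- xa + matrix(runif(na * 3L, -0.3, 0.3), na, 3L)
    xa <- .place_domain_a(xa, match(group_i_resid, resid_a))

    # domain B: elongated 2 x 2 column; residues ordered so the vertex
    # group and both chain ends sit at the hinge-proximal end and the arm
    # group at the distal end
    near <- sort(c(vertex_resid, 130:133, 76:81))
    far <- sort(arm_resid)
    mid <- sort(setdiff(resid_b, c(near, far)))
    fill_order <- match(c(near, mid, far), resid_b)
    xb <- matrix(NA_real_, nb, 3L)
    xb[fill_order, ] <- column_slots(nb)
    xb <- xb + matrix(runif(nb * 3L, -0.3, 0.3), nb, 3L)
    xb <- .place_domain_b(xb, match(vertex_resid, resid_b),
                          match(arm_resid, resid_b))

    # hinge strip: beads along the rotation axis (z), static like domain A.
    # Elastic springs from a bead on the axis to anything are orthogonal to
    # z-rotation displacements, so a strip exactly on the axis leaves the
    # two domains free to counter-rotate at zero energy; a small x-offset
    # gives that relative rotation a weak restoring force, making it the
    # softest internal mode instead of a spurious seventh zero mode.
    xl <- cbind(0.8, 0, seq(-4, 4, length.out = nl))
    xl[, 3] <- xl[, 3] + runif(nl, -0.2, 0.2)

    atoms <- .ca_atom_table(c(resid_a, resid_l, resid_b))
    ia <- seq_len(na)
    il <- na + seq_len(nl)
    ib <- na + nl + seq_len(nb)
    N <- na + nl + nb

    F <- spec$n_frames
    state <- sample(seq_along(spec$state_weights), F, replace = TRUE,
                    prob = spec$state_weights)
    angle <- rnorm(F, spec$state_angles[state], spec$angle_sigma)
    angle <- pmin(pmax(angle, 1), 179)

    coords <- array(NA_real_, c(N, 3L, F))
    base <- rbind(xa, xl, xb)
    for (k in seq_len(F)) {
      fr <- base
      fr[ib, ] <- xb %*% t(.rot_z(angle[k]))
      if (spec$thermal_noise_sigma > 0)
        fr <- fr + matrix(rnorm(N * 3L, 0, spec$thermal_noise_sigma), N, 3L)
      coords[, , k] <- fr
    }

    ensemble <- Ensemble(Structure(atoms, coords[, , 1]), coords,
                         times = (seq_len(F) - 1) * spec$frame_dt)
    ground_truth <- list(
      state = state, angle = angle,
      state_angles = spec$state_angles, state_weights = spec$state_weights,
      hinge_point = c(0, 0, 0), hinge_axis = c(0, 0, 1),
      domain_a_atoms = ia, linker_atoms = il, domain_b_atoms = ib,
      cv_groups = list(
        group_i = "resid 60-62,67-69 and ca",
        vertex = "resid 120-129 and ca",
        arm = "resid 90-96,100-107 and ca",
        distance_a = "resid 63 and ca",
        distance_b = "resid 113-116 and ca"
      ),
      spec = spec
    )
    list(ensemble = ensemble, ground_truth = ground_truth)
  })
}

#' Planted hinge-rotation displacement field
#'
#' The infinitesimal displacement of the hinge motion the generator planted:
#' rotation of the C-terminal domain about the hinge axis, zero elsewhere,
#' with the six rigid-body components projected out in the mass-weighted
#' metric (so it is comparable to internal normal modes), then normalized.
#'
#' @param structure the [Structure()] the field refers to (e.g. a frame or
#'   average of the generated ensemble)
#' @param ground_truth the `ground_truth` list of [make_hinge_ensemble()]
#' @param project_rigid remove net translation/rotation (default TRUE)
#' @return unit 3N displacement vector (per-atom interleaved)
#' @export
hinge_displacement_field <- function(structure, ground_truth,
                                     project_rigid = TRUE) {
  xyz <- structure$xyz
  axis <- ground_truth$hinge_axis
  pt <- ground_truth$hinge_point
  u <- matrix(0, nrow(xyz), 3L)
  rel <- sweep(xyz[ground_truth$domain_b_atoms, , drop = FALSE], 2, pt)
  u[ground_truth$domain_b_atoms, ] <- cbind(
    axis[2] * rel[, 3] - axis[3] * rel[, 2],
    axis[3] * rel[, 1] - axis[1] * rel[, 3],
    axis[1] * rel[, 2] - axis[2] * rel[, 1])
  v <- flatten_xyz(u)
  if (project_rigid) {
    m <- structure$atoms$mass
    sq <- rep(sqrt(m), each = 3L)
    Q <- .block_rigid_basis(xyz, m)   # whole molecule as one block
    vm <- v * sq
    vm <- vm - Q %*% crossprod(Q, vm)
    v <- as.vector(vm) / sq
  }
  v / sqrt(sum(v^2))
}

#' Small decorated pseudo-protein for contact and hydrogen-bond toys
#'
#' A compact lattice chain with four atoms per residue (N, CA, C, O), so
#' heavy-atom, backbone and donor/acceptor selections all resolve.
#'
#' @param n_residues number of residues (default 24)
#' @param start_resid first residue id (default 1)
#' @param seed RNG seed for the small coordinate jitter
#' @return a [Structure()]
#' @export
make_test_protein <- function(n_residues = 24, start_resid = 1, seed = 0) {
  .with_seed(seed, function() {
    ca <- .snake_lattice(n_residues, 3L, 3L)
    ca <- ca + matrix(runif(n_residues * 3L, -0.25, 0.25), n_residues, 3L)
    offs <- list(N = c(-1.2, 0.6, 0.2), CA = c(0, 0, 0),
                 C = c(1.2, 0.6, -0.2), O = c(1.4, 1.7, 0.1))
    resids <- start_resid:(start_resid + n_residues - 1L)
    rows <- do.call(rbind, lapply(seq_len(n_residues), function(r) {
      t(vapply(names(offs), function(a) ca[r, ] + offs[[a]], numeric(3)))
    }))
    atoms <- data.frame(
      serial = seq_len(4L * n_residues),
      atom_name = rep(c("N", "CA", "C", "O"), n_residues),
      element = rep(c("N", "C", "C", "O"), n_residues),
      residue_name = rep(.pseudo_residue_names(resids), each = 4L),
      residue_id = rep(as.integer(resids), each = 4L),
      chain_id = "A",
      stringsAsFactors = FALSE
    )
    Structure(atoms, rows)
  })
}

#' Generate a ligand trajectory with a planted bound fraction
#'
#' A small rigid ligand is placed so that its nearest heavy atom lies
#' exactly `contact_distance` from the designated receptor residue in
#' exactly `round(bound_fraction * n_frames)` frames (drawn at random from
#' the seeded stream) and at `unbound_distance` otherwise, along the
#' outward direction from the receptor centroid. Placement is verified: in
#' bound frames no other receptor residue may fall within 3.5 A of the
#' ligand, and in unbound frames none at all; violation is an error.
#'
#' @param receptor a [Structure()]
#' @param bound_fraction fraction of frames in contact (0-1)
#' @param contact_distance bound nearest-atom distance, <= 3.5 A
#' @param unbound_distance unbound nearest-atom distance, > 3.5 A
#' @param n_frames number of frames (default 100)
#' @param seed RNG seed
#' @param target_residue residue id to bind (default: the residue whose CA,
#'   or first heavy atom, is most distal from the receptor centroid)
#' @return list with `ensemble` and `ground_truth` (`bound` flags,
#'   `target_residue`, ligand atom indices)
#' @export
make_ligand_trajectory <- function(receptor, bound_fraction,
                                   contact_distance = 3.0,
                                   unbound_distance = 8.0,
                                   n_frames = 100, seed = 0,
                                   target_residue = NULL) {
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must lie in [0, 1]")
  if (!(contact_distance <= 3.5 && 3.5 < unbound_distance))
    stop("need contact_distance <= 3.5 < unbound_distance")
  at <- receptor$atoms
  heavy <- which(!(at$element %in% c("H", "D")))
  centroid <- colMeans(receptor$xyz[heavy, , drop = FALSE])
  if (is.null(target_residue)) {
    d <- sqrt(rowSums(sweep(receptor$xyz[heavy, , drop = FALSE], 2,
                            centroid)^2))
    target_residue <- at$residue_id[heavy[which.max(d)]]
  }
  tidx <- heavy[at$residue_id[heavy] == target_residue]
  if (length(tidx) == 0L) stop("target residue has no heavy atoms")
  dt <- sqrt(rowSums(sweep(receptor$xyz[tidx, , drop = FALSE], 2,
                           centroid)^2))
  anchor <- receptor$xyz[tidx[which.max(dt)], ]
  u <- anchor - centroid
  u <- u / sqrt(sum(u^2))
  R <- .rotation_between(c(1, 0, 0), u)
  template <- matrix(c(0, 0, 0, 1.4, 0, 0, 2.4, 1.0, 0.2,
                       1.2, -1.1, 0.3, 3.6, 0.3, -0.4),
                     5, 3, byrow = TRUE) %*% t(R)
  lig_atoms <- data.frame(
    serial = max(at$serial) + 1:5,
    atom_name = c("C1", "N1", "O1", "C2", "C3"),
    element = c("C", "N", "O", "C", "C"),
    residue_name = "LIG",
    residue_id = max(at$residue_id) + 1L,
    chain_id = "L",
    stringsAsFactors = FALSE
  )
  place <- function(d) sweep(template, 2, anchor + d * u, "+")
  # verify the planted geometry at both distances
  other <- setdiff(heavy, tidx)
  for (d in c(contact_distance, unbound_distance)) {
    lig <- place(d)
    dmin_target <- min(.cross_dist(lig, receptor$xyz[tidx, , drop = FALSE]))
    dmin_other <- min(.cross_dist(lig, receptor$xyz[other, , drop = FALSE]))
    if (abs(dmin_target - d) > 1e-6 && d == contact_distance)
      stop("geometric placement failure: another target atom intercepts the ligand")
    if (d == contact_distance && dmin_other <= 3.5)
      stop("geometric placement failure: non-target residue within cutoff when bound")
    if (d == unbound_distance && min(dmin_target, dmin_other) <= 3.5)
      stop("geometric placement failure: receptor within cutoff when unbound")
  }
  n_bound <- round(bound_fraction * n_frames)
  .with_seed(seed, function() {
    bound <- rep(FALSE, n_frames)
    bound[sample.int(n_frames, n_bound)] <- TRUE
    N <- nrow(at) + 5L
    coords <- array(NA_real_, c(N, 3L, n_frames))
    for (k in seq_len(n_frames)) {
      coords[, , k] <- rbind(receptor$xyz,
                             place(if (bound[k]) contact_distance
                                   else unbound_distance))
    }
    topo <- Structure(.rbind_atoms(at, lig_atoms), coords[, , 1])
    list(
      ensemble = Ensemble(topo, coords, times = (seq_len(n_frames) - 1) * 10),
      ground_truth = list(bound = bound, target_residue = target_residue,
                          ligand_atoms = nrow(at) + 1:5,
                          bound_fraction = n_bound / n_frames)
    )
  })
}

#' Generate an ensemble with a planted water-site occupancy
#'
#' One water oxygen occupies a fixed point (hence a fixed 1 A voxel) in
#' exactly `round(site_occupancy * n_frames)` frames; in the remaining
#' frames it is scattered more than 3 voxels away. The scattered cloud
#' includes one anchor position at a fixed lattice offset so the occupancy
#' grid's origin, and therefore the site's voxel, is reproducible.
#'
#' @param protein a [Structure()] kept static in every frame
#' @param site_occupancy fraction of frames the site is occupied (0-1)
#' @param n_frames number of frames (default 50)
#' @param seed RNG seed
#' @return list with `ensemble` and `ground_truth` (`site_point`,
#'   `occupied` flags, water atom index)
#' @export
make_hydrated_site <- function(protein, site_occupancy, n_frames = 50,
                               seed = 0) {
  if (site_occupancy < 0 || site_occupancy > 1)
    stop("site_occupancy must lie in [0, 1]")
  p0 <- apply(protein$xyz, 2, max) + 4
  n_occ <- round(site_occupancy * n_frames)
  wat <- data.frame(serial = max(protein$atoms$serial) + 1L,
                    atom_name = "O", element = "O", residue_name = "HOH",
                    residue_id = max(protein$atoms$residue_id) + 1L,
                    chain_id = "W", stringsAsFactors = FALSE)
  .with_seed(seed, function() {
    occupied <- rep(FALSE, n_frames)
    occupied[sample.int(n_frames, n_occ)] <- TRUE
    N <- nrow(protein$atoms) + 1L
    coords <- array(NA_real_, c(N, 3L, n_frames))
    first_away <- TRUE
    for (k in seq_len(n_frames)) {
      w <- if (occupied[k]) p0
           else if (first_away) { first_away <- FALSE; p0 - 8.5 }
           else p0 - runif(3, 5.5, 8.5)
      coords[, , k] <- rbind(protein$xyz, w)
    }
    topo <- Structure(.rbind_atoms(protein$atoms, wat), coords[, , 1])
    list(
      ensemble = Ensemble(topo, coords, times = (seq_len(n_frames) - 1) * 10),
      ground_truth = list(site_point = p0, occupied = occupied,
                          water_atom = N,
                          site_occupancy = n_occ / n_frames)
    )
  })
}

#' Generate a protein-on-membrane system with planted anchor residues
#'
#' Builds a planar two-leaflet slab of pseudo-lipids (residue name POP,
#' one polar-head bead PH of phosphorus and two apolar tail beads C1/C2),
#' orients the protein so the requested anchor residues face the slab, and
#' places it so every anchor residue keeps a heavy atom within 3.5 A of a
#' head bead in every frame while every other residue stays beyond 5 A of
#' all lipid atoms. Bounded per-frame jitter on the lipid beads preserves
#' both margins. Infeasible anchor sets (residues that cannot all face the
#' slab with the rest clear) raise an error.
#'
#' @param protein a [Structure()]
#' @param anchor_residues integer residue ids to anchor
#' @param n_frames number of frames (default 50)
#' @param seed RNG seed
#' @return list with `ensemble` and `ground_truth` (`anchor_residues`,
#'   `head_atoms`, `tail_atoms`, `protein_atoms`)
#' @export
make_membrane_system <- function(protein, anchor_residues, n_frames = 50,
                                 seed = 0) {
  at <- protein$atoms
  heavy <- which(!(at$element %in% c("H", "D")))
  aidx <- heavy[at$residue_id[heavy] %in% anchor_residues]
  if (length(aidx) == 0L ||
      !all(anchor_residues %in% at$residue_id))
    stop("anchor residues not found in protein")
  xyz <- protein$xyz
  dir <- colMeans(xyz[aidx, , drop = FALSE]) - colMeans(xyz[heavy, , drop = FALSE])
  if (sqrt(sum(dir^2)) < 1e-6)
    stop("placement infeasible: anchors are not on one side of the protein")
  xyz <- xyz %*% t(.rotation_between(dir, c(0, 0, -1)))
  # per anchor residue, its lowest heavy atom sits 3.0 A above z = 0
  shift <- 3.0 - min(xyz[aidx, 3])
  xyz[, 3] <- xyz[, 3] + shift
  anchor_low <- vapply(anchor_residues, function(r) {
    ii <- heavy[at$residue_id[heavy] == r]
    ii[which.min(xyz[ii, 3])]
  }, integer(1))
  other <- heavy[!(at$residue_id[heavy] %in% anchor_residues)]

  # lipid slab: grid heads at z = 0 and -18, tails between, plus one
  # dedicated lipid directly beneath each anchor residue's lowest atom
  gx <- seq(min(xyz[, 1]) - 10, max(xyz[, 1]) + 10, by = 8)
  gy <- seq(min(xyz[, 2]) - 10, max(xyz[, 2]) + 10, by = 8)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  dedicated <- cbind(xyz[anchor_low, 1:2, drop = FALSE])
  dedic_z <- xyz[anchor_low, 3] - 3.0
  # drop grid lipids that would crowd a dedicated one or sit under a
  # non-anchor residue closer than the 5 A clearance
  keep <- apply(grid, 1, function(g) {
    if (nrow(dedicated) &&
        min(sqrt(rowSums(sweep(dedicated, 2, g)^2))) < 4) return(FALSE)
    d2 <- sqrt((xyz[other, 1] - g[1])^2 + (xyz[other, 2] - g[2])^2 +
                 xyz[other, 3]^2)
    all(d2 > 5.6)
  })
  grid <- grid[keep, , drop = FALSE]
  heads_xy <- rbind(dedicated, grid)
  head_z <- c(dedic_z, rep(0, nrow(grid)))
  n_lip_leaf <- nrow(heads_xy)
  one_leaflet <- function(zh, zt1, zt2, xy, resid0) {
    do.call(rbind, lapply(seq_len(nrow(xy)), function(i) {
      cbind(matrix(c(xy[i, ], zh[i], xy[i, ], zt1[i], xy[i, ], zt2[i]),
                   3, 3, byrow = TRUE))
    }))
  }
  upper <- one_leaflet(head_z, head_z - 4, head_z - 8, heads_xy)
  lower <- one_leaflet(rep(-18, nrow(grid)), rep(-14, nrow(grid)),
                       rep(-10, nrow(grid)), grid)
  lip_xyz <- rbind(upper, lower)
  n_lip <- n_lip_leaf + nrow(grid)
  lip_atoms <- data.frame(
    serial = max(at$serial) + seq_len(3L * n_lip),
    atom_name = rep(c("PH", "C1", "C2"), n_lip),
    element = rep(c("P", "C", "C"), n_lip),
    residue_name = "POP",
    residue_id = max(at$residue_id) + rep(seq_len(n_lip), each = 3L),
    chain_id = "M",
    stringsAsFactors = FALSE
  )
  # feasibility: every anchor within 3.5 - jitter, every other residue > 5
  heads_all <- lip_xyz[rep(c(TRUE, FALSE, FALSE), n_lip), , drop = FALSE]
  for (r in anchor_residues) {
    ii <- heavy[at$residue_id[heavy] == r]
    if (min(.cross_dist(xyz[ii, , drop = FALSE], heads_all)) > 3.2)
      stop("placement infeasible: anchor residue ", r,
           " cannot reach the slab")
  }
  if (length(other) &&
      min(.cross_dist(xyz[other, , drop = FALSE], lip_xyz)) < 5.3)
    stop("placement infeasible: non-anchor residue too close to the slab")

  .with_seed(seed, function() {
    N <- nrow(at) + 3L * n_lip
    coords <- array(NA_real_, c(N, 3L, n_frames))
    for (k in seq_len(n_frames)) {
      jit <- matrix(runif(length(lip_xyz), -0.15, 0.15), nrow(lip_xyz), 3L)
      coords[, , k] <- rbind(xyz, lip_xyz + jit)
    }
    topo <- Structure(.rbind_atoms(at, lip_atoms), coords[, , 1])
    np <- nrow(at)
    list(
      ensemble = Ensemble(topo, coords, times = (seq_len(n_frames) - 1) * 10),
      ground_truth = list(
        anchor_residues = anchor_residues,
        protein_atoms = seq_len(np),
        head_atoms = np + which(lip_atoms$atom_name == "PH"),
        tail_atoms = np + which(lip_atoms$atom_name != "PH")
      )
    )
  })
}
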