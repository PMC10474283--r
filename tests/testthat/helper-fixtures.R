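# Small in-code fixtures shared across test files.

# bare atom table for hand-built structures
atom_table <- function(n, atom_name = "CA", element = "C",
                       residue_name = "ALA", residue_id = seq_len(n),
                       chain_id = "A") {
  data.frame(serial = seq_len(n), atom_name = atom_name, element = element,
             residue_name = residue_name, residue_id = as.integer(residue_id),
             chain_id = chain_id, stringsAsFactors = FALSE)
}

# a single water molecule (O, H, H)
water_structure <- function() {
  at <- data.frame(serial = 1:3, atom_name = c("O", "H1", "H2"),
                   element = c("O", "H", "H"), residue_name = "HOH",
                   residue_id = 1L, chain_id = "W",
                   stringsAsFactors = FALSE)
  Structure(at, rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
}

# random CA-only structure with the given residue count
random_ca_structure <- function(n, seed = 1, spread = 10) {
  set.seed(seed)
  Structure(atom_table(n), matrix(runif(n * 3, -spread, spread), n, 3))
}

# ensemble of F random frames over a fixed topology
random_ensemble <- function(n_atoms, n_frames, seed = 1, spread = 10) {
  set.seed(seed)
  coords <- array(runif(n_atoms * 3 * n_frames, -spread, spread),
                  c(n_atoms, 3, n_frames))
  Ensemble(Structure(atom_table(n_atoms), coords[, , 1]), coords)
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# independent brute-force re-implementation of the GROMOS neighbor-count
# loop, used as the clustering oracle
gromos_oracle <- function(m, cutoff) {
  F <- nrow(m)
  remaining <- rep(TRUE, F)
  assignments <- integer(F)
  centers <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    best <- -1L; center <- NA_integer_
    for (i in which(remaining)) {
      cnt <- 0L
      for (j in which(remaining))
        if (j != i && m[i, j] < cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; center <- i }
    }
    members <- center
    for (j in which(remaining))
      if (j != center && m[center, j] < cutoff) members <- c(members, j)
    assignments[members] <- cl
    centers[cl] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(assignments, nbins = cl)
  ord <- order(-sizes, centers)
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  list(assignments = relabel[assignments], centers = centers[ord],
       sizes = sizes[ord])
}

# flatten an N x 3 matrix the way mode vectors are stored
flat <- function(m) as.vector(t(m))

# brute-force per-frame all-pairs contact scan (heavy atoms, inclusive cutoff)
contact_oracle <- function(ensemble, ia, ib, cutoff) {
  at <- ensemble$topology$atoms
  ia <- ia[!(at$element[ia] %in% c("H", "D"))]
  ib <- ib[!(at$element[ib] %in% c("H", "D"))]
  res <- split(ia, factor(paste(at$chain_id[ia], at$residue_id[ia]),
                          levels = unique(paste(at$chain_id[ia],
                                                at$residue_id[ia]))))
  F <- n_frames(ensemble)
  sapply(res, function(idx) {
    hits <- 0
    for (k in seq_len(F)) {
      xyz <- ensemble$coords[, , k]
      found <- FALSE
      for (i in idx) for (j in ib) {
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
          found <- TRUE; break
        }
      }
      if (found) hits <- hits + 1
    }
    100 * hits / F
  })
}
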