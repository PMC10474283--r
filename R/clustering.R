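# GROMOS conformational clustering: iterative neighbor counting on a
# pairwise best-fit RMSD matrix. The frame with the most neighbors under the
# cutoff becomes a cluster center, its neighborhood is removed, and the scan
# repeats until every frame is assigned. Clusters are relabeled by size.

#' Pairwise best-fit RMSD matrix of an ensemble
#'
#' Entry (i, j) is `rmsd(frame_i, frame_j)` with both the fit and the
#' deviation evaluated on `selection`. Computed in compiled code; a 2000
#' frame matrix takes seconds.
#'
#' @param ensemble an [Ensemble()] with at least 2 frames
#' @param selection atoms used for fit and deviation (default `"backbone"`;
#'   on CA-only models use `"ca"` or `"all"`)
#' @param weighting `"geometric"` (default) or `"mass"`
#' @return symmetric F x F matrix (Angstrom) with zero diagonal
#' @export
pairwise_rmsd_matrix <- function(ensemble, selection = "backbone",
                                 weighting = "geometric") {
  if (n_frames(ensemble) < 2L) stop("need at least 2 frames")
  idx <- resolve_selection(ensemble, selection)
  if (length(idx) < 3L) stop("fit selection needs at least 3 atoms")
  w <- .weights_for(ensemble$topology, idx, weighting)
  # reject degenerate (collinear) fit sets up front, as kabsch_fit would
  X <- ensemble$coords[idx, , 1]
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-30))
    stop("degenerate (collinear) fit selection")
  .pairwise_rmsd_cpp(ensemble$coords, as.integer(idx), as.numeric(w))
}

#' GROMOS clustering of a pairwise RMSD matrix
#'
#' Iteratively: count, for every unassigned frame, its unassigned neighbors
#' at RMSD strictly below `cutoff`; the frame with the most neighbors (ties
#' broken by lowest frame index) becomes a center and forms a cluster with
#' its neighbors; all are removed; repeat. Cluster 1 is the largest
#' (ties by center frame index).
#'
#' @param matrix symmetric non-negative F x F RMSD matrix
#' @param cutoff neighbor criterion in Angstrom (default 4.0, strict `<`)
#' @return a `ClusteringResult`: list with `assignments` (per-frame cluster
#'   label, 1-based), `centers` (frame index per cluster), `populations`
#'   (percentages), `sizes`, and `cutoff`
#' @export
gromos_cluster <- function(matrix, cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  m <- as.matrix(matrix)
  F <- nrow(m)
  if (F != ncol(m)) stop("matrix must be square")
  if (any(m < 0)) stop("matrix must be non-negative")
  if (max(abs(m - t(m))) > 1e-6) stop("matrix must be symmetric")
  adj <- m < cutoff
  diag(adj) <- FALSE
  remaining <- rep(TRUE, F)
  assignments <- integer(F)
  centers <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(adj[remaining, , drop = FALSE]) # neighbors among remaining
    counts[!remaining] <- -1L
    center <- which.max(counts)  # ties -> lowest index
    members <- which(remaining & (adj[center, ] | seq_len(F) == center))
    assignments[members] <- cl
    centers[cl] <- center
    remaining[members] <- FALSE
    adj[members, ] <- FALSE
    adj[, members] <- FALSE
  }
  sizes <- tabulate(assignments, nbins = cl)
  ord <- order(-sizes, centers)
  relabel <- integer(cl)
  relabel[ord] <- seq_len(cl)
  structure(list(
    assignments = relabel[assignments],
    centers = centers[ord],
    sizes = sizes[ord],
    populations = 100 * sizes[ord] / F,
    cutoff = cutoff,
    n_frames = F
  ), class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("GROMOS clustering: %d frames, %d clusters (cutoff %.2f A)\n",
              x$n_frames, length(x$centers), x$cutoff))
  k <- min(length(x$centers), 10L)
  for (i in seq_len(k))
    cat(sprintf("  %s: %d frames (%.1f%%), center frame %d\n",
                cluster_label(i), x$sizes[i], x$populations[i], x$centers[i]))
  if (length(x$centers) > k) cat("  ...\n")
  invisible(x)
}

#' Letter label for a cluster rank ("Cl-a", "Cl-b", ...)
#' @param i cluster rank (1-based, by size)
#' @return character label
#' @export
cluster_label <- function(i) {
  suffix <- vapply(i, function(k) {
    out <- ""
    k <- k - 1L
    repeat {
      out <- paste0(letters[k %% 26L + 1L], out)
      k <- k %/% 26L - 1L
      if (k < 0L) break
    }
    out
  }, character(1))
  paste0("Cl-", suffix)
}

#' Extract cluster central structures
#'
#' @param result a `ClusteringResult` computed from `ensemble`
#' @param ensemble the clustered [Ensemble()]
#' @return an [Ensemble()] whose frame k is the center of cluster k
#' @export
central_structures <- function(result, ensemble) {
  if (result$n_frames != n_frames(ensemble))
    stop("clustering result was computed from a different ensemble (",
         result$n_frames, " vs ", n_frames(ensemble), " frames)")
  subset_frames(ensemble, result$centers)
}

#' Write clustering assignments and summary tables
#' @param result a `ClusteringResult`
#' @param path_assignments TSV path for per-frame labels (frame, time, cluster)
#' @param path_summary TSV path for the per-cluster summary
#' @param times optional per-frame times (ps)
#' @return invisibly, a list with both paths
#' @export
write_clustering_tsv <- function(result, path_assignments, path_summary,
                                 times = NULL) {
  a <- data.frame(frame = seq_len(result$n_frames),
                  time_ps = if (is.null(times)) NA else times,
                  cluster = cluster_label(result$assignments))
  .write_tsv(a, path_assignments,
             sprintf("# GROMOS clustering assignments (cutoff %.2f A)",
                     result$cutoff))
  s <- data.frame(cluster = cluster_label(seq_along(result$centers)),
                  size = result$sizes,
                  percentage = sprintf("%.1f", result$populations),
                  center_frame = result$centers)
  .write_tsv(s, path_summary,
             sprintf("# GROMOS clustering summary (%d frames, cutoff %.2f A)",
                     result$n_frames, result$cutoff))
  invisible(list(assignments = path_assignments, summary = path_summary))
}

.write_tsv <- function(df, path, header_comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(header_comments, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, format), sep = "\t")), con)
  invisible(path)
}
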