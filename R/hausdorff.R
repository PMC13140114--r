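#' Directed Hausdorff distance between trajectories
#'
#' Treats each trajectory as a set of conformations under the α-carbon
#' RMSD metric (frames are assumed already superposed onto one shared
#' reference; no per-pair refitting) and computes
#' `h(A -> B) = max_{a in A} min_{b in B} RMSD(a, b)`.
#'
#' @param traj_a,traj_b `F x N x 3` arrays in a common frame, each with at
#'   least one frame and matching N.
#' @param refit Kabsch-refit every frame pair before taking its RMSD
#'   (default FALSE: one prior global superposition is assumed; refitting
#'   costs a rigid fit per frame pair).
#' @return Directed Hausdorff distance in Å.
#' @export
directed_hausdorff <- function(traj_a, traj_b, refit = FALSE) {
  D <- frame_rmsd_matrix(traj_a, traj_b, refit = refit)
  max(apply(D, 1, min))
}

#' Pairwise frame RMSD matrix between two trajectories
#' @noRd
frame_rmsd_matrix <- function(traj_a, traj_b, refit = FALSE) {
  for (tr in list(traj_a, traj_b)) {
    assert_that(length(dim(tr)) == 3L && dim(tr)[3] == 3L,
                "trajectories must be F x N x 3 arrays")
    assert_that(dim(tr)[1] >= 1L, "empty trajectory")
  }
  n_atoms <- dim(traj_a)[2]
  assert_that(dim(traj_b)[2] == n_atoms, "atom count mismatch")
  if (refit) {
    fa <- dim(traj_a)[1]; fb <- dim(traj_b)[1]
    D <- matrix(0, fa, fb)
    for (i in seq_len(fa)) for (j in seq_len(fb)) {
      D[i, j] <- kabsch_superpose(traj_a[i, , ], traj_b[j, , ])$rmsd
    }
    return(D)
  }
  A <- matrix(traj_a, nrow = dim(traj_a)[1])  # F_a x 3N
  B <- matrix(traj_b, nrow = dim(traj_b)[1])
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2 / n_atoms)
}

#' Symmetrized Hausdorff distance matrix over replicas
#'
#' `D(i, j) = max(h(i -> j), h(j -> i))` over all replica trajectories,
#' after superposing every frame onto a single shared reference (by
#' default the first frame of the first replica).
#'
#' @param replicas List of `F x N x 3` arrays (condition-labelled via
#'   `labels`).
#' @param labels Optional character labels for rows/columns.
#' @param reference Optional `N x 3` shared reference; `NULL` skips
#'   superposition (frames assumed pre-aligned).
#' @param refit See [directed_hausdorff()].
#' @return Symmetric matrix with zero diagonal, dimnames = labels.
#' @export
hausdorff_matrix <- function(replicas, labels = NULL, reference = NULL,
                             refit = FALSE) {
  assert_that(is.list(replicas) && length(replicas) >= 2L,
              "need at least 2 replicas")
  if (!is.null(reference)) {
    replicas <- lapply(replicas, superpose_frames, reference = reference)
  }
  n <- length(replicas)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M <- frame_rmsd_matrix(replicas[[i]], replicas[[j]], refit = refit)
      D[i, j] <- D[j, i] <- max(max(apply(M, 1, min)), max(apply(M, 2, min)))
    }
  }
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  D
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward minimum-variance criterion
#' (squared-distance Lance-Williams updates, the `ward.D2` convention).
#'
#' @param D Symmetric non-negative distance matrix (zero diagonal), or a
#'   `dist` object; at least 2 items.
#' @return An `hclust` object (merge heights nondecreasing).
#' @export
ward_cluster <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    assert_that(nrow(D) >= 2L, "need at least 2 items to cluster")
    assert_that(isTRUE(all.equal(D, t(D))), "distance matrix must be symmetric")
    assert_that(all(diag(D) == 0), "distance matrix diagonal must be zero")
    assert_that(all(D >= 0), "distances must be non-negative")
    D <- stats::as.dist(D)
  }
  stats::hclust(D, method = "ward.D2")
}

#' Top-split membership of a dendrogram
#'
#' Cuts the tree into two clusters and reports the assignment, useful for
#' asking whether the highest merge separates two known conditions.
#'
#' @param hc An `hclust` object.
#' @return Integer vector of cluster assignments (1/2).
#' @export
top_split <- function(hc) {
  assert_that(inherits(hc, "hclust"), "hc must be an hclust object")
  stats::cutree(hc, k = 2)
}
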