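#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' via the Kabsch algorithm: center both, take the SVD of the covariance,
#' and form the proper rotation (determinant +1, reflections corrected).
#'
#' @param mobile,reference Numeric `N x 3` matrices with matching rows,
#'   `N >= 3`.
#' @return List with `coords` (mobile after superposition), `rmsd` (Å),
#'   `rotation` (3x3), `translation` (length 3), and `degenerate` (TRUE
#'   when the point set is collinear so the rotation is not unique).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  assert_that(ncol(mobile) == 3L && ncol(reference) == 3L,
              "coordinates must be N x 3")
  assert_that(nrow(mobile) == nrow(reference), "atom count mismatch")
  assert_that(nrow(mobile) >= 3L, "need at least 3 points")
  assert_that(all(is.finite(mobile)) && all(is.finite(reference)),
              "coordinates must be finite")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300)
  rotated <- A %*% t(R)
  coords <- sweep(rotated, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((coords - reference)^2)))
  list(coords = coords, rmsd = rmsd, rotation = R,
       translation = cr - as.vector(R %*% cm), degenerate = degenerate)
}

#' RMSD between two superposed coordinate sets
#' @param a,b `N x 3` matrices (already in a common frame).
#' @return RMSD in Å.
#' @export
coord_rmsd <- function(a, b) {
  assert_that(all(dim(a) == dim(b)), "dimension mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param frames `F x N x 3` array of α-carbon coordinates.
#' @param reference `N x 3` matrix.
#' @return Array of the same shape with each frame Kabsch-superposed.
#' @export
superpose_frames <- function(frames, reference) {
  assert_that(length(dim(frames)) == 3L && dim(frames)[3] == 3L,
              "frames must be an F x N x 3 array")
  out <- frames
  for (f in seq_len(dim(frames)[1])) {
    out[f, , ] <- kabsch_superpose(frames[f, , ], reference)$coords
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are iteratively superposed onto their mean structure (two
#' mean-superpose rounds), then
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)`.
#'
#' @param frames `F x N x 3` array, `F >= 2`.
#' @param iterations Mean-superposition rounds (default 2).
#' @return Numeric length-N vector of RMSF values (Å).
#' @export
rmsf_profile <- function(frames, iterations = 2L) {
  assert_that(length(dim(frames)) == 3L && dim(frames)[3] == 3L,
              "frames must be an F x N x 3 array")
  assert_that(dim(frames)[1] >= 2L, "need at least 2 frames")
  for (it in seq_len(iterations)) {
    mean_struct <- apply(frames, c(2, 3), mean)
    frames <- superpose_frames(frames, mean_struct)
  }
  mean_struct <- apply(frames, c(2, 3), mean)
  dev2 <- sweep(frames, c(2, 3), mean_struct)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and axes, times 3 axes
}

#' Differential RMSF test between conditions
#'
#' Per residue, a pooled-variance two-sample Student t-test on per-replica
#' RMSF values (wild-type vs mutant), with Bonferroni correction over all
#' residues at the stated family-wise level.
#'
#' @param group_wt,group_mut Lists of per-replica RMSF profiles (each a
#'   length-N numeric vector); at least 2 replicas per condition.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame with one row per residue: `mean_wt`, `mean_mut`,
#'   `t`, `p_raw`, `p_adj` (`min(1, p_raw * N)`), `significant`,
#'   `degenerate` (zero pooled variance with unequal means).
#' @export
compare_rmsf <- function(group_wt, group_mut, alpha = 0.05) {
  assert_that(length(group_wt) >= 2L && length(group_mut) >= 2L,
              "need at least 2 replicas per condition")
  W <- do.call(rbind, group_wt)   # replicas x residues
  M <- do.call(rbind, group_mut)
  assert_that(ncol(W) == ncol(M), "residue count mismatch between conditions")
  n1 <- nrow(W); n2 <- nrow(M); nres <- ncol(W)
  m1 <- colMeans(W); m2 <- colMeans(M)
  v1 <- apply(W, 2, stats::var); v2 <- apply(M, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  p_raw[degenerate & m1 == m2] <- 1
  p_raw[degenerate & m1 != m2] <- 0
  tstat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0,
                              sign(m1[degenerate] - m2[degenerate]) * Inf)
  p_adj <- pmin(1, p_raw * nres)
  data.frame(residue = seq_len(nres), mean_wt = m1, mean_mut = m2,
             t = tstat, p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < alpha, degenerate = degenerate,
             row.names = NULL)
}
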