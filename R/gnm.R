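#' Gaussian network model Kirchhoff matrix
#'
#' Builds the α-carbon elastic-network connectivity (Kirchhoff / graph
#' Laplacian) matrix: residues within the distance cutoff are connected by
#' springs of constant `gamma`, so `K[i, j] = -gamma` for contacts and the
#' diagonal holds the negated row sums. Field-standard α-carbon defaults:
#' 7 Å cutoff, unit spring constant.
#'
#' @param coords `N x 3` matrix of α-carbon coordinates (Å), `N >= 2`.
#' @param cutoff Contact cutoff in Å (> 0; default 7).
#' @param gamma Spring constant (default 1).
#' @param weights Optional `N x N` symmetric matrix of per-contact spring
#'   multipliers (used to model localized mutation perturbations).
#' @return List of class `kirchhoff_model` with `matrix`, `n`, `cutoff`,
#'   `gamma`.
#' @export
build_gnm <- function(coords, cutoff = 7, gamma = 1, weights = NULL) {
  coords <- as.matrix(coords)
  assert_that(ncol(coords) == 3L && nrow(coords) >= 2L,
              "coords must be N x 3 with N >= 2")
  assert_that(cutoff > 0, "cutoff must be positive")
  assert_that(gamma > 0, "gamma must be positive")
  d <- as.matrix(stats::dist(coords))
  contact <- d > 0 & d <= cutoff
  K <- matrix(0, nrow(coords), nrow(coords))
  K[contact] <- -gamma
  if (!is.null(weights)) {
    assert_that(all(dim(weights) == dim(K)), "weights must be N x N")
    K <- K * weights
  }
  diag(K) <- -rowSums(K)
  structure(list(matrix = K, n = nrow(coords), cutoff = cutoff, gamma = gamma),
            class = "kirchhoff_model")
}

#' Eigenvalue spectrum of a Kirchhoff matrix
#'
#' Symmetric eigendecomposition with zero modes identified by a relative
#' tolerance; the number of zero modes equals the number of connected
#' components of the contact graph.
#'
#' @param model A `kirchhoff_model` (or a symmetric matrix).
#' @param tol_rel Relative zero-mode tolerance (default 1e-8 times the
#'   largest eigenvalue).
#' @return List of class `eig_spectrum` with `eigenvalues` (ascending),
#'   `nonzero` (zero modes excluded), `n_zero_modes`.
#' @export
gnm_spectrum <- function(model, tol_rel = 1e-8) {
  K <- if (inherits(model, "kirchhoff_model")) model$matrix else as.matrix(model)
  ev <- sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- max(ev, 0)
  tol <- tol_rel * max(lmax, .Machine$double.eps)
  ev[abs(ev) <= tol] <- 0
  assert_that(all(ev >= 0), "Kirchhoff matrix must be positive semidefinite")
  list_out <- list(eigenvalues = ev, nonzero = ev[ev > 0],
                   n_zero_modes = sum(ev == 0))
  structure(list_out, class = "eig_spectrum")
}

#' Sampled elastic-network spectra along a trajectory
#'
#' Rebuilds the Kirchhoff matrix on frames sampled at a stride and pools
#' the non-zero eigenvalues, giving a frame-resolved picture of how the
#' contact topology (and hence the collective flexibility spectrum)
#' fluctuates along the trajectory.
#'
#' @param frames `F x N x 3` array.
#' @param stride Sample every `stride`-th frame (default 100; `stride = F`
#'   yields a single spectrum).
#' @param cutoff,gamma Passed to [build_gnm()].
#' @return List with `spectra` (one `eig_spectrum` per sampled frame) and
#'   `pooled` (all non-zero eigenvalues concatenated).
#' @export
gnm_spectra_over_trajectory <- function(frames, stride = 100L, cutoff = 7,
                                        gamma = 1) {
  assert_that(is_count(stride) && stride >= 1, "stride must be >= 1")
  nf <- dim(frames)[1]
  idx <- seq(1L, nf, by = stride)
  spectra <- lapply(idx, function(f) {
    gnm_spectrum(build_gnm(frames[f, , ], cutoff = cutoff, gamma = gamma))
  })
  list(spectra = spectra,
       frames_sampled = idx,
       pooled = unlist(lapply(spectra, `[[`, "nonzero")))
}

#' Bootstrap eigenvalue densities and their overlap
#'
#' Non-parametric bootstrap of pooled elastic-network eigenvalues: each of
#' `n_boot` iterations resamples the pooled spectrum with replacement at
#' its original size; a Gaussian kernel density is estimated per iteration
#' on a grid shared across conditions and averaged. The overlap
#' coefficient between two condition densities is the integral of their
#' pointwise minimum (1 = indistinguishable conformational-flexibility
#' spectra, 0 = disjoint).
#'
#' @param pooled_by_condition Named list of numeric eigenvalue vectors
#'   (>= 10 values each), one per condition.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed; each condition uses an independent substream
#'   derived from it, so results are reproducible and per-condition
#'   draws do not interact.
#' @param grid_n Shared grid resolution (default 512).
#' @return List with `grid`, `density` (named list of averaged densities,
#'   each integrating to 1 on the grid), `overlap` (matrix of pairwise
#'   overlap coefficients), `n_boot`.
#' @export
bootstrap_eigs <- function(pooled_by_condition, n_boot = 1000L, seed,
                           grid_n = 512L) {
  assert_that(is.list(pooled_by_condition) && !is.null(names(pooled_by_condition)),
              "pooled_by_condition must be a named list")
  assert_that(is_count(n_boot) && n_boot >= 1, "n_boot must be >= 1")
  assert_that(!missing(seed), "an explicit seed is required")
  for (v in pooled_by_condition) {
    assert_that(length(v) >= 10L, "need >= 10 pooled eigenvalues per condition")
  }
  all_vals <- unlist(pooled_by_condition)
  bw0 <- stats::bw.nrd0(all_vals)
  pad <- 3 * bw0
  grid <- seq(min(all_vals) - pad, max(all_vals) + pad, length.out = grid_n)
  conds <- names(pooled_by_condition)
  dens <- vector("list", length(conds)); names(dens) <- conds
  for (k in seq_along(conds)) {
    vals <- pooled_by_condition[[k]]
    set.seed(as.integer((seed + 7919L * k) %% .Machine$integer.max))
    acc <- numeric(grid_n)
    for (b in seq_len(n_boot)) {
      draw <- sample(vals, length(vals), replace = TRUE)
      d <- stats::density(draw, bw = bw0, from = grid[1], to = grid[grid_n],
                          n = grid_n)
      acc <- acc + d$y
    }
    f <- acc / n_boot
    dens[[k]] <- f / trapz(grid, f)  # renormalize on the shared grid
  }
  overlap <- matrix(1, length(conds), length(conds),
                    dimnames = list(conds, conds))
  if (length(conds) > 1) {
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i != j) overlap[i, j] <- trapz(grid, pmin(dens[[i]], dens[[j]]))
    }
  }
  list(grid = grid, density = dens, overlap = overlap, n_boot = n_boot)
}

#' Ligand RMSD stability test between conditions
#'
#' For each replica, protein frames are superposed onto the replica's
#' first frame, the same rigid transform is applied to the ligand atoms,
#' and the ligand RMSD to its first-frame pose is averaged over frames.
#' Per-replica mean ligand RMSDs are then compared between conditions with
#' a pooled-variance two-sample Student t-test: a significant increase in
#' the mutant indicates mutation-induced destabilization of the bound
#' ligand.
#'
#' @param wt,mut Lists with elements `protein` (`F x N x 3`) and `ligand`
#'   (`F x M x 3`) per replica.
#' @return List with `mean_rmsd_wt`, `mean_rmsd_mut` (per replica), `t`,
#'   `p_two_sided`, `degenerate` (TRUE when either condition has zero
#'   variance, e.g. single-frame replicas).
#' @export
ligand_rmsd_test <- function(wt, mut) {
  per_replica <- function(rep) {
    assert_that(!is.null(rep$ligand), "replica lacks ligand coordinates")
    prot <- rep$protein; lig <- rep$ligand
    nf <- dim(prot)[1]
    ref <- prot[1, , ]
    ref_lig <- lig[1, , , drop = TRUE]
    if (is.null(dim(ref_lig))) ref_lig <- matrix(ref_lig, ncol = 3)
    vals <- vapply(seq_len(nf), function(f) {
      fit <- kabsch_superpose(prot[f, , ], ref)
      lf <- lig[f, , , drop = TRUE]
      if (is.null(dim(lf))) lf <- matrix(lf, ncol = 3)
      moved <- sweep(lf %*% t(fit$rotation), 2, fit$translation, `+`)
      coord_rmsd(moved, ref_lig)
    }, numeric(1))
    mean(vals)
  }
  rw <- vapply(wt, per_replica, numeric(1))
  rm <- vapply(mut, per_replica, numeric(1))
  assert_that(length(rw) >= 2L && length(rm) >= 2L,
              "need at least 2 replicas per condition")
  v1 <- stats::var(rw); v2 <- stats::var(rm)
  # zero-variance up to floating noise (e.g. single-frame replicas)
  tol <- 1e-20 * max(1, mean(rw)^2, mean(rm)^2)
  if (v1 <= tol && v2 <= tol) {
    same <- abs(mean(rw) - mean(rm)) <= 1e-10
    return(list(mean_rmsd_wt = rw, mean_rmsd_mut = rm,
                t = if (same) 0 else NA_real_,
                p_two_sided = if (same) 1 else NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(rw, rm, var.equal = TRUE)
  list(mean_rmsd_wt = rw, mean_rmsd_mut = rm, t = unname(tt$statistic),
       p_two_sided = tt$p.value, degenerate = FALSE)
}
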