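test_that("Kirchhoff matrices of small chains match closed-form Laplacians", {
  # 3 residues on a line, 3.8 A apart, cutoff 7: path graph P3
  chain <- cbind(c(0, 3.8, 7.6), 0, 0)
  m <- build_gnm(chain, cutoff = 7, gamma = 1)
  expect_equal(gnm_spectrum(m)$eigenvalues, c(0, 1, 3), tolerance = 1e-12)
  # gamma scales the non-zero spectrum linearly
  m2 <- build_gnm(chain, cutoff = 7, gamma = 2.5)
  expect_equal(gnm_spectrum(m2)$eigenvalues, 2.5 * c(0, 1, 3), tolerance = 1e-12)
  # equilateral triangle inside the cutoff: complete graph K3
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 1.5 * sqrt(3), 0))
  expect_equal(gnm_spectrum(build_gnm(tri, cutoff = 7))$eigenvalues,
               c(0, 3, 3), tolerance = 1e-12)
  # cutoff below the minimum distance: empty graph, N zero modes
  s <- gnm_spectrum(build_gnm(chain, cutoff = 1))
  expect_equal(s$n_zero_modes, 3L)
  expect_error(build_gnm(chain, cutoff = 0), "positive")
})

test_that("Kirchhoff matrices are PSD with zero modes counting graph components", {
  set.seed(61)
  for (i in 1:10) {
    coords <- matrix(rnorm(30 * 3, 0, 6), ncol = 3)
    cutoff <- runif(1, 4, 9)
    m <- build_gnm(coords, cutoff = cutoff)
    expect_equal(m$matrix, t(m$matrix))
    expect_equal(rowSums(m$matrix), rep(0, 30), tolerance = 1e-12,
                 ignore_attr = TRUE)
    offdiag <- m$matrix[row(m$matrix) != col(m$matrix)]
    expect_true(all(offdiag %in% c(0, -1)))
    s <- gnm_spectrum(m)
    expect_true(all(s$eigenvalues >= 0))
    expect_equal(s$n_zero_modes, contact_components(coords, cutoff))
  }
})

test_that("trajectory spectra respect stride and rigid/fixed-topology structure", {
  ref <- reference_chain(12)
  rigid <- array(rep(ref, each = 6), c(6, 12, 3))
  res <- gnm_spectra_over_trajectory(rigid, stride = 2)
  expect_equal(length(res$spectra), 3L)
  for (s in res$spectra) {
    expect_equal(s$eigenvalues, res$spectra[[1]]$eigenvalues, tolerance = 1e-12)
  }
  # stride = F: exactly one spectrum
  one <- gnm_spectra_over_trajectory(rigid, stride = 6)
  expect_equal(length(one$spectra), 1L)
  # tiny fluctuations preserve the contact topology: pooled spectrum
  # concentrates at the reference topology's eigenvalues
  set.seed(62)
  wob <- rigid + array(rnorm(length(rigid), 0, 0.01), dim(rigid))
  pooled <- gnm_spectra_over_trajectory(wob, stride = 1, cutoff = 6.5)$pooled
  ref_eigs <- gnm_spectrum(build_gnm(ref, cutoff = 6.5))$nonzero
  expect_equal(matrix(pooled, nrow = length(ref_eigs)),
               matrix(rep(ref_eigs, 6), nrow = length(ref_eigs)),
               tolerance = 0.05)
})

test_that("bootstrap eigenvalue densities integrate to one, overlap sensibly, and are deterministic", {
  set.seed(63)
  vals <- rgamma(120, 4, 1)
  same <- bootstrap_eigs(list(wt = vals, mut = vals), n_boot = 200, seed = 9)
  f <- same$density$wt
  grid <- same$grid
  expect_equal(sum(diff(grid) * (head(f, -1) + tail(f, -1)) / 2), 1,
               tolerance = 1e-3)
  expect_gte(same$overlap["wt", "mut"], 0.95)
  # disjoint supports: overlap near zero
  far <- bootstrap_eigs(list(wt = rnorm(50, 0, 0.05), mut = rnorm(50, 100, 0.05)),
                        n_boot = 50, seed = 9)
  expect_lt(far$overlap["wt", "mut"], 0.01)
  # determinism: identical draws for identical seeds
  a <- bootstrap_eigs(list(wt = vals, mut = vals * 1.2), n_boot = 50, seed = 4)
  b <- bootstrap_eigs(list(wt = vals, mut = vals * 1.2), n_boot = 50, seed = 4)
  expect_identical(a$density, b$density)
  expect_error(bootstrap_eigs(list(wt = vals, mut = vals), n_boot = 0, seed = 1),
               "n_boot")
  expect_error(bootstrap_eigs(list(wt = 1:5, mut = vals), n_boot = 10, seed = 1),
               "10 pooled")
})

test_that("ligand RMSD test discriminates drift amplitudes and flags degeneracy", {
  set.seed(64)
  prot_base <- reference_chain(15)
  mk_rep <- function(drift_sd, n_frames = 60) {
    prot <- wiggle_traj(n_frames, prot_base, sd = 0.2)
    lig_base <- matrix(rnorm(9, 0, 1), 3) + rep(colMeans(prot_base), each = 3)
    lig <- array(0, c(n_frames, 3, 3))
    for (f in seq_len(n_frames)) {
      lig[f, , ] <- lig_base + matrix(rnorm(9, 0, drift_sd), 3)
    }
    list(protein = prot, ligand = lig)
  }
  wt <- lapply(1:4, function(i) mk_rep(0.1))
  stable <- ligand_rmsd_test(wt, lapply(1:4, function(i) mk_rep(0.1)))
  expect_gt(stable$p_two_sided, 0.001)
  drift <- ligand_rmsd_test(wt, lapply(1:4, function(i) mk_rep(1.5)))
  expect_lt(drift$p_two_sided, 0.01)
  expect_gt(mean(drift$mean_rmsd_mut), mean(drift$mean_rmsd_wt))
  # single frame per replica: zero RMSD, degenerate
  single <- lapply(1:2, function(i) {
    r <- mk_rep(0.1, n_frames = 1)
    r$protein <- r$protein[1, , , drop = FALSE]
    r$ligand <- r$ligand[1, , , drop = FALSE]
    r
  })
  deg <- ligand_rmsd_test(single, single)
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_sided, 1)
  no_lig <- list(list(protein = wt[[1]]$protein, ligand = NULL))
  expect_error(ligand_rmsd_test(no_lig, no_lig), "ligand")
})
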