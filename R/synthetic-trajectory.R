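#' Synthetic trajectory-ensemble specification
#'
#' Conditions for the elastic-network trajectory sampler: a reference
#' chain, contact cutoff and spring constant, thermal energy, replica and
#' frame counts, a mutation site whose incident spring constants are
#' rescaled in the mutant condition, and an Ornstein-Uhlenbeck drift model
#' for an optional bound ligand.
#'
#' @param n_residues Chain length (default 40).
#' @param cutoff Contact cutoff in Å (default 7).
#' @param gamma Spring constant (default 1).
#' @param kT Thermal energy in units of `gamma * Å^2` (default 1).
#' @param n_replicas Replicas per condition (default 5).
#' @param n_frames Frames per replica (default 500).
#' @param mutation_site Residue index perturbed in the mutant (default
#'   `n_residues %/% 2`).
#' @param perturbation Multiplicative change to spring constants incident
#'   to the mutation site (> 0; 1 = no effect; default 0.25, a localized
#'   softening).
#' @param ligand_n_atoms Ligand atom count (0 disables the ligand;
#'   default 0).
#' @param ligand_tau,ligand_sigma Ornstein-Uhlenbeck relaxation (frames)
#'   and stationary displacement scale (Å) of the ligand drift model
#'   (defaults 20, 0.5).
#' @param seed Integer seed (required at generation time).
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues = 40L, cutoff = 7, gamma = 1, kT = 1,
                            n_replicas = 5L, n_frames = 500L,
                            mutation_site = NULL, perturbation = 0.25,
                            ligand_n_atoms = 0L, ligand_tau = 20,
                            ligand_sigma = 0.5, seed = NULL) {
  assert_that(is_count(n_residues) && n_residues >= 3, "n_residues must be >= 3")
  assert_that(is_count(n_replicas) && n_replicas >= 2, "n_replicas must be >= 2")
  assert_that(is_count(n_frames) && n_frames >= 2, "n_frames must be >= 2")
  assert_that(perturbation > 0, "perturbation must be positive")
  assert_that(kT >= 0, "kT must be non-negative")
  if (is.null(mutation_site)) mutation_site <- as.integer(n_residues %/% 2)
  assert_that(mutation_site >= 1 && mutation_site <= n_residues,
              "mutation_site out of range")
  structure(as.list(environment()), class = "trajectory_spec")
}

#' Reference chain coordinates
#'
#' Deterministic compact helical chain with ~3.8 Å consecutive-residue
#' spacing, giving a connected contact graph at the default 7 Å cutoff.
#'
#' @param n_residues Chain length.
#' @return `N x 3` coordinate matrix (Å).
#' @export
reference_chain <- function(n_residues) {
  i <- seq_len(n_residues)
  # helix with rise 1.7 Å/residue and radius tuned to ~3.8 Å Ca-Ca spacing
  theta <- i * 100 * pi / 180
  r <- 2.3
  cbind(r * cos(theta), r * sin(theta), 1.7 * i)
}

#' Moore-Penrose pseudo-inverse of a symmetric PSD matrix
#' @noRd
psd_pinv <- function(K, tol_rel = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  tol <- tol_rel * max(e$values)
  inv <- ifelse(e$values > tol, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

#' Generate elastic-network trajectory ensembles
#'
#' Samples equilibrium frames of a Gaussian network: displacements about
#' the reference are drawn independently per Cartesian axis with
#' covariance `kT * pinv(K)` (eigendecomposition sampling over non-zero
#' modes), where `K` is the Kirchhoff matrix with the spring constant
#' folded in. The mutant condition uses a Kirchhoff whose springs incident
#' to the mutation site are rescaled by `perturbation`. Optional ligand
#' atoms follow an Ornstein-Uhlenbeck drift about a pose near the chain
#' center. Deterministic given `spec$seed`.
#'
#' @param spec A [trajectory_spec()] with `seed` set.
#' @param conditions Which conditions to generate (default both).
#' @return Named list per condition, each with `condition`, `replicas`
#'   (list of `F x N x 3` arrays), `residue_ids`, `reference`, `model`
#'   (the condition's `kirchhoff_model`), and `ligand` (list of
#'   `F x M x 3` arrays, or `NULL`).
#' @export
gen_gnm_trajectory <- function(spec, conditions = c("wildtype", "mutant")) {
  assert_that(inherits(spec, "trajectory_spec"), "spec must be a trajectory_spec")
  assert_that(!is.null(spec$seed), "spec$seed must be set")
  ref <- reference_chain(spec$n_residues)
  base_model <- build_gnm(ref, cutoff = spec$cutoff, gamma = spec$gamma)
  assert_that(gnm_spectrum(base_model)$n_zero_modes == 1L,
              "contact graph of the reference chain must be connected")
  n <- spec$n_residues
  out <- list()
  for (cond in conditions) {
    weights <- NULL
    if (cond == "mutant" && spec$perturbation != 1) {
      weights <- matrix(1, n, n)
      weights[spec$mutation_site, ] <- spec$perturbation
      weights[, spec$mutation_site] <- spec$perturbation
    }
    model <- build_gnm(ref, cutoff = spec$cutoff, gamma = spec$gamma,
                       weights = weights)
    e <- eigen(model$matrix, symmetric = TRUE)
    tol <- 1e-8 * max(e$values)
    keep <- e$values > tol
    V <- e$vectors[, keep, drop = FALSE]
    sdev <- sqrt(spec$kT / e$values[keep])
    cond_offset <- match(cond, c("wildtype", "mutant"))
    set.seed(as.integer((spec$seed + 104729L * cond_offset) %% .Machine$integer.max))
    replicas <- vector("list", spec$n_replicas)
    ligands <- if (spec$ligand_n_atoms > 0) vector("list", spec$n_replicas) else NULL
    lig_ref <- NULL
    if (spec$ligand_n_atoms > 0) {
      center <- colMeans(ref)
      lig_ref <- sweep(matrix(stats::rnorm(spec$ligand_n_atoms * 3, 0, 1.5),
                              ncol = 3), 2, center, `+`)
    }
    for (r in seq_len(spec$n_replicas)) {
      fr <- array(0, c(spec$n_frames, n, 3))
      for (ax in 1:3) {
        z <- matrix(stats::rnorm(spec$n_frames * sum(keep)), spec$n_frames) *
          rep(sdev, each = spec$n_frames)
        fr[, , ax] <- sweep(tcrossprod(z, V), 2, ref[, ax], `+`)
      }
      replicas[[r]] <- fr
      if (!is.null(ligands)) {
        lg <- array(0, c(spec$n_frames, spec$ligand_n_atoms, 3))
        # OU displacement shared by all ligand atoms (rigid drift)
        phi <- exp(-1 / spec$ligand_tau)
        innov_sd <- spec$ligand_sigma * sqrt(1 - phi^2)
        disp <- matrix(0, spec$n_frames, 3)
        disp[1, ] <- stats::rnorm(3, 0, spec$ligand_sigma)
        for (f in 2:spec$n_frames) {
          disp[f, ] <- phi * disp[f - 1, ] + stats::rnorm(3, 0, innov_sd)
        }
        for (f in seq_len(spec$n_frames)) {
          lg[f, , ] <- sweep(lig_ref, 2, disp[f, ], `+`)
        }
        ligands[[r]] <- lg
      }
    }
    out[[cond]] <- list(condition = cond, replicas = replicas,
                        residue_ids = seq_len(n), reference = ref,
                        model = model, ligand = ligands)
  }
  out
}
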