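#' Pipeline configuration
#'
#' @param filter A [filter_config()].
#' @param codon_scores_path Path to the codon activity-score TSV (with a
#'   `# threshold=` header or `score_threshold` given).
#' @param score_threshold Hyperactivity threshold override (optional).
#' @param panel_size_mb Targeted panel territory in Mb (default 0.5).
#' @param gnm_cutoff,gnm_gamma Elastic-network parameters (defaults 7 Å, 1).
#' @param gnm_stride Frame stride for trajectory spectra (default 100).
#' @param n_boot Bootstrap iterations for eigenvalue densities
#'   (default 1000).
#' @param include_unknown Count unscored pathway missense variants toward
#'   case positivity (default TRUE).
#' @param exclude_variants Protein changes to ignore (see
#'   [case_nrf2_status()]).
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            codon_scores_path = NULL,
                            score_threshold = NULL,
                            panel_size_mb = 0.5,
                            gnm_cutoff = 7, gnm_gamma = 1, gnm_stride = 100L,
                            n_boot = 1000L,
                            include_unknown = TRUE,
                            exclude_variants = character(0),
                            seed = 1L,
                            out_dir = ".") {
  assert_that(inherits(filter, "filter_config"), "filter must be a filter_config")
  assert_that(panel_size_mb > 0, "panel_size_mb must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `filter` key holds [filter_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  y <- yaml::read_yaml(path)
  filt <- do.call(filter_config, y$filter %||% list())
  y$filter <- NULL
  do.call(pipeline_config, c(list(filter = filt), y))
}

#' Run the ctDNA analysis pipeline end to end
#'
#' Triage (panel-of-normals removal, hard/evidence filters, NRF2
#' classification, case status), burden metrics, and cohort statistics on
#' one MAF + clinical table; optionally the trajectory comparison on
#' multi-model PDB ensembles. Writes the filtered MAF, per-variant and
#' per-case NRF2 calls, burden TSV, co-occurrence statistics TSV,
#' trajectory TSVs, and a JSON summary with a provenance block (input
#' hashes, seed, thresholds). Outputs are identical for identical inputs
#' and seed.
#'
#' @param config A [pipeline_config()].
#' @param maf_path MAF-like TSV of somatic variants.
#' @param clinical_path Clinical TSV (`case_id`, covariates,
#'   `cfdna_ng_ml`).
#' @param trajectory_paths Optional named list of multi-model PDB paths,
#'   e.g. `list(wildtype = "wt.pdb", mutant = c("m1.pdb", ...))`; each
#'   condition may list several replica files.
#' @return List with `triage`, `burden`, `cooccurrence`, `trajectory`
#'   (or `NULL`), `summary` (the JSON summary as a list), and `files`
#'   (paths written).
#' @export
run_pipeline <- function(config, maf_path, clinical_path,
                         trajectory_paths = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- read_maf(maf_path)
  clinical <- read_clinical(clinical_path)
  assert_that(!is.null(config$codon_scores_path),
              "config$codon_scores_path is required")
  scores <- read_codon_scores(config$codon_scores_path,
                              threshold = config$score_threshold)

  tri <- triage_variants(variants, scores, config = config$filter,
                         include_unknown = config$include_unknown,
                         exclude_variants = config$exclude_variants)
  # burden on the pre-pathogenicity (but post-PoN) detected set, and on the
  # filtered set, since either convention appears in practice
  post_pon <- remove_panel_of_normals(variants)
  burden_all <- burden_table(post_pon, clinical, config$panel_size_mb,
                             pathogenic_mask = rep(FALSE, nrow(post_pon)))
  patho_mask <- !tri$variants$silent &
    tri$variants$nrf2_call != "not_pathway" |
    tri$variants$tier == "oncogenic_evidence" & !tri$variants$silent
  burden_filt <- burden_table(tri$variants, clinical, config$panel_size_mb,
                              pathogenic_mask = patho_mask)
  burden <- data.frame(case_id = burden_all$case_id,
                       raw_count_detected = burden_all$raw_count,
                       per_mb_detected = burden_all$per_mb,
                       raw_count_filtered = burden_filt$raw_count,
                       per_mb_filtered = burden_filt$per_mb,
                       ctdna_ng_ml = burden_filt$ctdna_ng_ml,
                       stringsAsFactors = FALSE)

  # gene-level co-occurrence over pathogenic/likely-pathogenic calls
  patho <- tri$variants[tri$variants$tier == "oncogenic_evidence" &
                          !tri$variants$silent, , drop = FALSE]
  cooc <- NULL
  if (nrow(patho)) {
    genes <- sort(unique(patho$gene))
    mat <- sapply(genes, function(g) {
      clinical$case_id %in% patho$case_id[patho$gene == g]
    })
    if (length(genes) >= 2L && is.matrix(mat)) {
      rownames(mat) <- clinical$case_id
      cooc <- pairwise_cooccurrence(mat)
    }
  }

  trajectory <- NULL
  if (!is.null(trajectory_paths)) {
    trajectory <- run_trajectory_comparison(trajectory_paths, config)
  }

  files <- list(
    filtered_maf = file.path(config$out_dir, "filtered.maf.tsv"),
    nrf2_variants = file.path(config$out_dir, "nrf2_variant_calls.tsv"),
    nrf2_cases = file.path(config$out_dir, "nrf2_case_status.tsv"),
    burden = file.path(config$out_dir, "burden.tsv"),
    summary = file.path(config$out_dir, "summary.json"))
  write_maf(tri$variants, files$filtered_maf)
  write_tsv(tri$variants[, c("case_id", "gene", "protein_change",
                             "consequence", "vaf", "nrf2_call")],
            files$nrf2_variants)
  write_tsv(tri$case_status, files$nrf2_cases)
  write_tsv(burden, files$burden)
  if (!is.null(cooc)) {
    files$cooccurrence <- file.path(config$out_dir, "cooccurrence.tsv")
    write_tsv(cooc, files$cooccurrence)
  }

  pathway_variants <- tri$variants[tri$variants$nrf2_call != "not_pathway", ,
                                   drop = FALSE]
  n_pos <- sum(tri$case_status$status == "positive")
  summary <- list(
    n_cases = nrow(clinical),
    n_variants_input = nrow(variants),
    n_variants_filtered = nrow(tri$variants),
    n_pathway_mutated_cases = length(unique(pathway_variants$case_id)),
    n_nrf2_positive_cases = n_pos,
    nrf2_positive_fraction = n_pos / nrow(clinical),
    provenance = list(
      inputs = list(maf = unname(tools::md5sum(maf_path)),
                    clinical = unname(tools::md5sum(clinical_path))),
      seed = config$seed,
      thresholds = unclass(config$filter),
      score_threshold = scores$threshold))
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(triage = tri, burden = burden, cooccurrence = cooc,
       trajectory = trajectory, summary = summary, files = files)
}

#' Trajectory comparison stage of the pipeline
#'
#' Reads per-condition multi-model PDB replicas, superposes all frames
#' onto a shared reference (first frame of the first wild-type replica),
#' and computes RMSF differential tests, the symmetrized Hausdorff
#' distance matrix with Ward clustering, pooled elastic-network spectra
#' with bootstrap densities and overlap, and (when ligand atoms are
#' present) the ligand RMSD stability test.
#'
#' @param trajectory_paths Named list of PDB path vectors per condition;
#'   the first name is treated as the reference condition.
#' @param config A [pipeline_config()].
#' @return List with `rmsf`, `hausdorff`, `clustering`, `bootstrap`,
#'   `ligand` components.
#' @export
run_trajectory_comparison <- function(trajectory_paths, config) {
  conds <- names(trajectory_paths)
  assert_that(length(conds) >= 2L, "need at least two conditions")
  ens <- lapply(trajectory_paths, function(paths) {
    lapply(paths, read_multimodel_pdb)
  })
  reference <- ens[[1]][[1]]$frames[1, , ]
  aligned <- lapply(ens, function(reps) {
    lapply(reps, function(r) superpose_frames(r$frames, reference))
  })
  rmsf <- lapply(aligned, function(reps) lapply(reps, rmsf_profile))
  rmsf_cmp <- compare_rmsf(rmsf[[1]], rmsf[[2]])
  all_reps <- do.call(c, aligned)
  labels <- unlist(lapply(conds, function(cn) {
    paste0(cn, "_rep", seq_along(aligned[[cn]]))
  }))
  D <- hausdorff_matrix(all_reps, labels = labels)
  hc <- ward_cluster(D)
  pooled <- lapply(aligned, function(reps) {
    unlist(lapply(reps, function(fr) {
      gnm_spectra_over_trajectory(fr, stride = config$gnm_stride,
                                  cutoff = config$gnm_cutoff,
                                  gamma = config$gnm_gamma)$pooled
    }))
  })
  boot <- bootstrap_eigs(pooled, n_boot = config$n_boot, seed = config$seed)
  ligand <- NULL
  has_ligand <- all(vapply(ens, function(reps) {
    all(vapply(reps, function(r) !is.null(r$ligand), logical(1)))
  }, logical(1)))
  if (has_ligand) {
    pack <- function(cn) {
      lapply(seq_along(ens[[cn]]), function(i) {
        list(protein = ens[[cn]][[i]]$frames, ligand = ens[[cn]][[i]]$ligand)
      })
    }
    ligand <- ligand_rmsd_test(pack(conds[1]), pack(conds[2]))
  }
  list(rmsf = rmsf_cmp, hausdorff = D, clustering = hc, bootstrap = boot,
       ligand = ligand)
}
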