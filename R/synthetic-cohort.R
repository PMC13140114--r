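#' Synthetic cohort specification
#'
#' Defines the study conditions emulated by the cohort generator: cohort
#' size and NRF2-pathway mutation prevalence, SMARCA4 co-occurrence
#' coupling, Beta-distributed somatic VAFs with low-VAF oncogenic drivers,
#' near-0.5-VAF germline contaminants, sequencing read support, and
#' low-read PCR-artifact variants.
#'
#' @param n_cases Cohort size (default 73).
#' @param nrf2_prevalence NRF2-pathway mutation prevalence (default 0.18).
#' @param smarca4_cooccurrence_or Odds ratio coupling SMARCA4 mutation to
#'   NRF2 status (default 8).
#' @param smarca4_base_rate SMARCA4 mutation probability in NRF2-negative
#'   cases (default 0.05).
#' @param vaf_shape1,vaf_shape2 Beta parameters for somatic driver VAFs
#'   (default Beta(2, 40): median around 4%, range matching observed
#'   1.9-30% driver VAFs).
#' @param mean_depth Mean deduplicated read depth (default 1500).
#' @param background_rate Mean count of non-pathway somatic passenger
#'   variants per case (Poisson; default 3).
#' @param artifact_rate Mean count of PCR-artifact variants per case, each
#'   with 1-4 supporting reads (Poisson; default 2).
#' @param germline_rate Mean count of germline contaminant variants per
#'   case, with VAF near 0.5 and population frequency above the pruning
#'   threshold (Poisson; default 0.5).
#' @param panel_size_mb Targeted panel territory in Mb (default 0.5).
#' @param seed Integer seed (required at generation time).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 73L, nrf2_prevalence = 0.18,
                        smarca4_cooccurrence_or = 8,
                        smarca4_base_rate = 0.05,
                        vaf_shape1 = 2, vaf_shape2 = 40,
                        mean_depth = 1500,
                        background_rate = 3,
                        artifact_rate = 2,
                        germline_rate = 0.5,
                        panel_size_mb = 0.5,
                        seed = NULL) {
  assert_that(is_count(n_cases) && n_cases >= 1, "n_cases must be >= 1")
  assert_that(is_prob(nrf2_prevalence), "nrf2_prevalence must be in [0,1]")
  assert_that(is_prob(smarca4_base_rate), "smarca4_base_rate must be in [0,1]")
  assert_that(smarca4_cooccurrence_or > 0, "odds ratio must be positive")
  assert_that(artifact_rate >= 0 && germline_rate >= 0 && background_rate >= 0,
              "contamination rates must be non-negative")
  assert_that(panel_size_mb > 0, "panel_size_mb must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

# consequence mix of pathway driver events, mirroring the observed blend of
# hotspot missense, truncating/frameshift KEAP1/CUL3 events and rare
# unscored missense variants
.pathway_event_types <- data.frame(
  gene        = c("NFE2L2", "NFE2L2", "KEAP1", "KEAP1", "KEAP1", "CUL3"),
  consequence = c("missense", "inframe_ins", "missense", "nonsense",
                  "frameshift", "nonsense"),
  scored      = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  prob        = c(0.30, 0.05, 0.30, 0.12, 0.15, 0.08),
  stringsAsFactors = FALSE
)

# hotspot codons used for scored events; unscored missense draws a codon
# outside this set
.scored_codons <- list(
  NFE2L2 = c(18L, 24L, 29L, 31L, 77L, 79L, 80L),
  KEAP1  = c(278L, 323L, 334L, 480L, 511L, 554L)
)

#' Synthetic codon activity-score table
#'
#' Builds a synthetic stand-in for the codon-level NRF2 activity score
#' table: hotspot codons of the generator score above the hyperactivity
#' threshold.
#'
#' @param threshold Hyperactivity threshold (default 0).
#' @param seed Integer seed for the score noise.
#' @return A [codon_score_table()].
#' @export
synthetic_codon_scores <- function(threshold = 0, seed = 11L) {
  set.seed(seed)
  genes <- rep(names(.scored_codons), lengths(.scored_codons))
  codons <- unlist(.scored_codons, use.names = FALSE)
  # three replicate scores per codon, clearly above the threshold
  df <- data.frame(gene = rep(genes, each = 3L),
                   codon = rep(codons, each = 3L))
  score <- threshold + 1.5 + stats::rnorm(nrow(df), 0, 0.2)
  codon_score_table(df$gene, df$codon, score, threshold)
}

#' Generate a synthetic ctDNA cohort
#'
#' Draws clinical covariates, NRF2-pathway driver variants at the given
#' prevalence (all in male ever-smokers, mirroring the observed
#' exclusivity), a SMARCA4 column coupled by odds ratio, background
#' somatic passengers, PCR artifacts (1-4 supporting reads), germline
#' contaminants (VAF near 0.5, population frequency above the pruning
#' threshold), and panel-of-normals-flagged artifacts. Truth labels record
#' the variant class each row was generated as, enabling recovery tests.
#'
#' @param spec A [cohort_spec()]; `spec$seed` must be set.
#' @return List with `cases` (clinical data frame), `variants` (canonical
#'   variant data frame with a `truth` column: `pathway`, `background`,
#'   `artifact`, `germline`, `pon_artifact`), and `scores` (the matching
#'   synthetic codon score table).
#' @export
gen_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  assert_that(!is.null(spec$seed), "spec$seed must be set")
  set.seed(as.integer(spec$seed))
  n <- spec$n_cases
  scores <- synthetic_codon_scores(threshold = 0, seed = spec$seed + 1L)

  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(53, 20) / 73)
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(11, 32, 30) / 73)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.03, 0.04, 0.35, 0.58))
  histology <- sample(c("LUAD", "LUSC", "NSCLC_NOS"), n, replace = TRUE,
                      prob = c(32, 29, 12) / 73)
  cfdna <- exp(stats::rnorm(n, log(15), 0.9)) + 1.5  # right-skewed ng/ml

  # pathway-positive cases restricted to male ever-smokers
  eligible <- sex == "male" & smoking != "never"
  target_p <- spec$nrf2_prevalence
  p_eligible <- min(1, target_p * n / max(1, sum(eligible)))
  nrf2_pos <- eligible & stats::runif(n) < p_eligible

  # SMARCA4 coupled to NRF2 status by odds ratio
  p0 <- spec$smarca4_base_rate
  odds1 <- spec$smarca4_cooccurrence_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  smarca4 <- stats::runif(n) < ifelse(nrf2_pos, p1, p0)

  cases <- data.frame(case_id = sprintf("case%03d", seq_len(n)),
                      sex = sex, age = round(stats::rnorm(n, 70, 8)),
                      stage = stage, smoking = smoking, histology = histology,
                      cfdna_ng_ml = cfdna,
                      panel_size_mb = spec$panel_size_mb,
                      truth_nrf2 = nrf2_pos, truth_smarca4 = smarca4,
                      stringsAsFactors = FALSE)

  draw_reads <- function(vaf) {
    depth <- stats::rpois(length(vaf), spec$mean_depth)
    alt <- stats::rbinom(length(vaf), depth, vaf)
    pmax(alt, 2L)  # detected drivers carry at least the caller's strand floor
  }
  mk <- function(case_id, gene, consequence, codon, vaf, alt_reads, fathmm,
                 clinvar, pop_freq, in_pon, truth) {
    k <- length(case_id)
    data.frame(case_id = case_id, timepoint = "diagnosis", gene = gene,
               chrom = "chr1", pos = sample.int(2e8, k), ref = "A", alt = "T",
               cdna_change = NA_character_,
               protein_change = ifelse(is.na(codon), NA_character_,
                                       sprintf("p.X%dY", codon)),
               codon = codon, consequence = consequence, vaf = vaf,
               alt_reads = as.integer(alt_reads),
               fathmm = fathmm, clinvar_class = clinvar, pop_freq = pop_freq,
               in_pon = in_pon, truth = truth, stringsAsFactors = FALSE)
  }

  blocks <- list()
  # pathway drivers
  pos_ids <- cases$case_id[nrf2_pos]
  if (length(pos_ids)) {
    type <- sample(nrow(.pathway_event_types), length(pos_ids), replace = TRUE,
                   prob = .pathway_event_types$prob)
    et <- .pathway_event_types[type, ]
    codon <- integer(length(pos_ids))
    for (i in seq_along(pos_ids)) {
      codon[i] <- if (et$scored[i]) {
        sample(.scored_codons[[et$gene[i]]], 1L)
      } else if (et$consequence[i] == "missense") {
        sample(setdiff(100:600, .scored_codons$KEAP1), 1L)
      } else sample(100:600, 1L)
    }
    vaf <- stats::rbeta(length(pos_ids), spec$vaf_shape1, spec$vaf_shape2)
    blocks$pathway <- mk(pos_ids, et$gene, et$consequence, codon, vaf,
                         draw_reads(vaf), fathmm = 0.995,
                         clinvar = "likely_oncogenic", pop_freq = NA_real_,
                         in_pon = FALSE, truth = "pathway")
  }
  # background somatic passengers in common NSCLC genes
  bg_genes <- c("TP53", "CSMD3", "NF1", "LRP1B", "KRAS", "STK11", "SMARCA4",
                "EGFR", "PIK3CA", "FAT1")
  n_bg <- stats::rpois(n, spec$background_rate)
  # force a SMARCA4 passenger where the truth label says so
  if (any(smarca4)) {
    vaf <- stats::rbeta(sum(smarca4), spec$vaf_shape1, spec$vaf_shape2)
    blocks$smarca4 <- mk(cases$case_id[smarca4], "SMARCA4", "nonsense",
                         NA_integer_, vaf, draw_reads(vaf), fathmm = 0.995,
                         clinvar = "likely_oncogenic", pop_freq = NA_real_,
                         in_pon = FALSE, truth = "background")
  }
  if (sum(n_bg)) {
    ids <- rep(cases$case_id, n_bg)
    vaf <- stats::rbeta(length(ids), spec$vaf_shape1, spec$vaf_shape2)
    onc <- stats::runif(length(ids)) < 0.5
    blocks$background <- mk(ids,
                            sample(setdiff(bg_genes, "SMARCA4"), length(ids), TRUE),
                            sample(c("missense", "nonsense", "silent"),
                                   length(ids), TRUE, prob = c(0.6, 0.2, 0.2)),
                            NA_integer_, vaf, draw_reads(vaf),
                            fathmm = ifelse(onc, 0.995, stats::runif(length(ids), 0, 0.9)),
                            clinvar = ifelse(onc, "likely_oncogenic", "other"),
                            pop_freq = NA_real_, in_pon = FALSE,
                            truth = "background")
  }
  # PCR artifacts: 1-4 supporting reads, no evidence annotations
  n_art <- stats::rpois(n, spec$artifact_rate)
  if (sum(n_art)) {
    ids <- rep(cases$case_id, n_art)
    reads <- sample(1:4, length(ids), replace = TRUE)
    vaf <- pmin(reads / stats::rpois(length(ids), spec$mean_depth), 1)
    blocks$artifact <- mk(ids, sample(bg_genes, length(ids), TRUE), "missense",
                          NA_integer_, vaf, reads,
                          fathmm = stats::runif(length(ids), 0, 0.9),
                          clinvar = "other", pop_freq = NA_real_,
                          in_pon = FALSE, truth = "artifact")
  }
  # germline contaminants: VAF near 0.5, present in population databases
  n_germ <- stats::rpois(n, spec$germline_rate)
  if (sum(n_germ)) {
    ids <- rep(cases$case_id, n_germ)
    vaf <- pmin(pmax(stats::rnorm(length(ids), 0.5, 0.03), 0), 1)
    blocks$germline <- mk(ids, sample(bg_genes, length(ids), TRUE), "missense",
                          NA_integer_, vaf, draw_reads(vaf),
                          fathmm = stats::runif(length(ids), 0, 0.9),
                          clinvar = "other",
                          pop_freq = stats::runif(length(ids), 1e-4, 1e-2),
                          in_pon = FALSE, truth = "germline")
  }
  # recurrent platform artifacts caught by the panel of normals
  n_pon <- stats::rpois(n, spec$artifact_rate / 2)
  if (sum(n_pon)) {
    ids <- rep(cases$case_id, n_pon)
    vaf <- stats::rbeta(length(ids), 2, 60)
    blocks$pon <- mk(ids, sample(bg_genes, length(ids), TRUE), "missense",
                     NA_integer_, vaf, draw_reads(vaf),
                     fathmm = stats::runif(length(ids), 0, 0.9),
                     clinvar = "other", pop_freq = NA_real_,
                     in_pon = TRUE, truth = "pon_artifact")
  }
  variants <- do.call(rbind, blocks)
  rownames(variants) <- NULL
  validate_variants(variants)
  list(cases = cases, variants = variants, scores = scores)
}
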