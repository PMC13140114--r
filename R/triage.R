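#' @name variant_table
#' @title Somatic variant tables
#'
#' @description
#' Variants are carried as plain data frames with one row per somatic call
#' (a MAF-like layout). [validate_variants()] checks the canonical columns
#' and invariants; all triage operations accept and return such data frames
#' with row order preserved.
#'
#' Canonical columns: `case_id`, `timepoint` (`diagnosis`/`followup`/
#' `progression`), `gene`, `chrom`, `pos` (1-based inclusive), `ref`, `alt`,
#' `cdna_change`, `protein_change`, `codon` (integer or `NA`), `consequence`
#' (one of [consequence_levels()]), `vaf` (fraction in `[0,1]`), `alt_reads`
#' (deduplicated alt-supporting reads), optional `reads_plus`/`reads_minus`
#' strand split, `fathmm` (`[0,1]` or `NA`), `clinvar_class` (one of
#' [clinvar_levels()]), `pop_freq` (`[0,1]` or `NA`), `in_pon` (logical).
NULL

NRF2_PATHWAY_GENES <- c("NFE2L2", "KEAP1", "CUL3")

#' Allowed variant consequence categories
#' @return Character vector of consequence levels.
#' @export
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "inframe_ins", "inframe_del",
    "splice", "silent", "other")
}

#' Allowed ClinVar evidence classes
#' @return Character vector of ClinVar class levels.
#' @export
clinvar_levels <- function() {
  c("oncogenic", "likely_oncogenic", "drug_response", "other", "absent")
}

#' Validate a somatic variant table
#'
#' @param variants Data frame in the canonical layout (see [variant_table]).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_variants <- function(variants) {
  assert_that(is.data.frame(variants), "variants must be a data frame")
  required <- c("case_id", "gene", "consequence", "vaf", "alt_reads")
  missing <- setdiff(required, names(variants))
  assert_that(length(missing) == 0L,
              paste("variant table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(variants) == 0L) return(invisible(variants))
  assert_that(all(variants$consequence %in% consequence_levels()),
              "unknown consequence values in variant table")
  vaf_ok <- is.na(variants$vaf) | (variants$vaf >= 0 & variants$vaf <= 1)
  assert_that(all(vaf_ok), "vaf must be a fraction in [0,1] (convert percent at read time)")
  assert_that(all(!is.na(variants$alt_reads) & variants$alt_reads >= 0),
              "alt_reads must be non-negative")
  if (all(c("reads_plus", "reads_minus") %in% names(variants))) {
    sp <- variants$reads_plus; sm <- variants$reads_minus
    ok <- is.na(sp) | is.na(sm) |
      (variants$alt_reads >= sp & variants$alt_reads >= sm)
    assert_that(all(ok), "alt_reads must be >= each per-strand count")
  }
  if ("pos" %in% names(variants)) {
    assert_that(all(is.na(variants$pos) | variants$pos >= 1), "pos must be >= 1")
  }
  if ("clinvar_class" %in% names(variants)) {
    assert_that(all(variants$clinvar_class %in% clinvar_levels()),
                "unknown clinvar_class values")
  }
  invisible(variants)
}

#' Remove panel-of-normals variants
#'
#' First step of the post-calling cascade: drops every variant flagged as
#' present in the platform-specific panel of normal samples (recurrent
#' technical artifacts and germline leakage).
#'
#' @param variants Canonical variant data frame with an `in_pon` column.
#' @return The rows with `in_pon = FALSE`, order preserved.
#' @export
remove_panel_of_normals <- function(variants) {
  validate_variants(variants)
  if (nrow(variants) == 0L) return(variants)
  assert_that("in_pon" %in% names(variants),
              "variants must carry an in_pon flag")
  assert_that(!anyNA(variants$in_pon), "in_pon must not contain NA")
  variants[!variants$in_pon, , drop = FALSE]
}

#' Evidence tier of a variant
#'
#' A variant counts as carrying oncogenic evidence when its FATHMM score
#' meets the threshold or its ClinVar class is oncogenic, likely oncogenic,
#' or drug response; otherwise it is a variant of unknown significance.
#'
#' @param variants Canonical variant data frame (columns `fathmm`,
#'   `clinvar_class`; either may be `NA`/absent).
#' @param config A [filter_config()].
#' @return Character vector, one of `"oncogenic_evidence"` or `"vus"` per row.
#' @export
evidence_tier <- function(variants, config = filter_config()) {
  validate_variants(variants)
  n <- nrow(variants)
  if (n == 0L) return(character(0))
  fathmm <- if ("fathmm" %in% names(variants)) variants$fathmm else rep(NA_real_, n)
  clinvar <- if ("clinvar_class" %in% names(variants)) variants$clinvar_class
             else rep("absent", n)
  clinvar[is.na(clinvar)] <- "absent"
  onc <- (!is.na(fathmm) & fathmm >= config$fathmm_threshold) |
    clinvar %in% c("oncogenic", "likely_oncogenic", "drug_response")
  ifelse(onc, "oncogenic_evidence", "vus")
}

#' Apply the hard and evidence-based variant filters
#'
#' Retains a variant when either (a) it is a VUS with at least
#' `min_reads_vus` unique supporting reads and VAF below `max_vaf_vus`, or
#' (b) it carries oncogenic evidence and has at least `min_reads_oncogenic`
#' supporting reads. Variants seen in population databases above
#' `pop_freq_threshold` are then removed as putative germline. When the
#' optional strand-split columns are present, a per-strand minimum of 2
#' reads is additionally enforced (matching the caller's strand rule).
#' Silent variants are retained (flagged in the `silent` column) so that
#' mutational-burden computation can include them; downstream pathogenicity
#' steps exclude them.
#'
#' @param variants Canonical variant data frame (post panel-of-normals).
#' @param config A [filter_config()].
#' @param enforce_strand Apply the per-strand minimum when strand counts are
#'   present (default TRUE; rows with `NA` strand counts are exempt).
#' @return The retained rows with added columns `tier` and `silent`.
#' @export
apply_hard_filters <- function(variants, config = filter_config(),
                               enforce_strand = TRUE) {
  validate_variants(variants)
  if (nrow(variants) == 0L) {
    variants$tier <- character(0)
    variants$silent <- logical(0)
    return(variants)
  }
  tier <- evidence_tier(variants, config)
  vaf <- variants$vaf
  keep_vus <- tier == "vus" &
    variants$alt_reads >= config$min_reads_vus &
    !is.na(vaf) & vaf < config$max_vaf_vus
  keep_onc <- tier == "oncogenic_evidence" &
    variants$alt_reads >= config$min_reads_oncogenic
  keep <- keep_vus | keep_onc
  if (enforce_strand && all(c("reads_plus", "reads_minus") %in% names(variants))) {
    sp <- variants$reads_plus; sm <- variants$reads_minus
    strand_ok <- is.na(sp) | is.na(sm) | (sp >= 2L & sm >= 2L)
    keep <- keep & strand_ok
  }
  pop <- if ("pop_freq" %in% names(variants)) variants$pop_freq else rep(NA_real_, nrow(variants))
  keep <- keep & (is.na(pop) | pop <= config$pop_freq_threshold)
  out <- variants[keep, , drop = FALSE]
  out$tier <- tier[keep]
  out$silent <- out$consequence == "silent"
  out
}

#' Classify a variant's predicted relation to NRF2 activity
#'
#' Classification rules for NRF2-pathway (NFE2L2/KEAP1/CUL3) variants:
#' * genes outside the pathway (or silent variants) are `not_pathway`;
#' * NFE2L2 truncating/frameshift events inside the Neh2 domain (the
#'   KEAP1-binding N-terminus; codon window configurable) destroy rather
#'   than stabilize NRF2 and are `likely_lof`;
#' * KEAP1/CUL3 nonsense or frameshift (loss of the negative regulator) are
#'   `likely_activating`;
#' * missense or in-frame events at a codon whose mean activity score
#'   exceeds the hyperactivity threshold are `activating`;
#' * missense/in-frame events at unscored codons are
#'   `putative_activating_unknown`.
#'
#' @param variants Canonical variant data frame (post-filter; `gene`,
#'   `consequence`, `codon` used).
#' @param scores A [codon_score_table()].
#' @param neh2_window Integer codon range of the NFE2L2 Neh2 domain
#'   (default `c(1, 86)`).
#' @return Data frame with columns `call` (factor over the five classes)
#'   and `rationale`, one row per input variant.
#' @export
classify_nrf2 <- function(variants, scores, neh2_window = c(1L, 86L)) {
  validate_variants(variants)
  assert_that(inherits(scores, "codon_score_table"),
              "scores must be a codon_score_table")
  assert_that(length(neh2_window) == 2L && neh2_window[1] <= neh2_window[2],
              "neh2_window must be an increasing codon pair")
  n <- nrow(variants)
  call <- character(n)
  rationale <- character(n)
  codon <- if ("codon" %in% names(variants)) variants$codon else rep(NA_integer_, n)
  truncating <- c("nonsense", "frameshift")
  changing <- c("missense", "inframe_ins", "inframe_del")
  for (i in seq_len(n)) {
    gene <- variants$gene[i]
    cons <- variants$consequence[i]
    if (!gene %in% NRF2_PATHWAY_GENES) {
      call[i] <- "not_pathway"; rationale[i] <- "gene outside NFE2L2/KEAP1/CUL3"
    } else if (cons == "silent") {
      call[i] <- "not_pathway"; rationale[i] <- "silent"
    } else if (gene == "NFE2L2" && cons %in% truncating &&
               !is.na(codon[i]) &&
               codon[i] >= neh2_window[1] && codon[i] <= neh2_window[2]) {
      call[i] <- "likely_lof"
      rationale[i] <- sprintf("NFE2L2 %s in Neh2 domain (codon %d) abolishes KEAP1 binding interface",
                              cons, codon[i])
    } else if (gene %in% c("KEAP1", "CUL3") && cons %in% truncating) {
      call[i] <- "likely_activating"
      rationale[i] <- sprintf("%s %s: loss of NRF2 negative regulator", gene, cons)
    } else if (cons %in% changing) {
      ms <- codon_mean_score(scores, gene, codon[i])
      if (is.na(ms)) {
        call[i] <- "putative_activating_unknown"
        rationale[i] <- "codon absent from activity-score table"
      } else if (ms > scores$threshold) {
        call[i] <- "activating"
        rationale[i] <- sprintf("mean codon activity score %.3g exceeds hyperactivity threshold %.3g",
                                ms, scores$threshold)
      } else {
        call[i] <- "putative_activating_unknown"
        rationale[i] <- sprintf("mean codon activity score %.3g below hyperactivity threshold", ms)
      }
    } else {
      call[i] <- "putative_activating_unknown"
      rationale[i] <- sprintf("pathway %s of uncertain effect", cons)
    }
  }
  data.frame(call = factor(call, levels = nrf2_call_levels()),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' NRF2 call categories
#' @return Character vector of call levels.
#' @export
nrf2_call_levels <- function() {
  c("activating", "likely_activating", "putative_activating_unknown",
    "likely_lof", "not_pathway")
}

#' Case-level NRF2 pathway status
#'
#' A case is NRF2-positive when it carries at least one activating or
#' likely-activating variant; putative-activating variants at unscored
#' codons count toward positivity by default (the cohort's rare KEAP1
#' variants of this kind were subsequently confirmed functional). A case
#' whose only pathway variant is a likely-LOF event is negative.
#'
#' @param variants Canonical variant data frame with a `case_id` column.
#' @param calls Output of [classify_nrf2()] for the same rows.
#' @param include_unknown Count `putative_activating_unknown` as positive
#'   (default TRUE).
#' @param exclude_variants Optional character vector of `gene p.X` protein
#'   changes (e.g. `"KEAP1 p.M147V"`) to ignore, for variants ruled out by
#'   external functional evidence.
#' @return Data frame with columns `case_id` and `status`
#'   (`"positive"`/`"negative"`), one row per case present in `variants`.
#' @export
case_nrf2_status <- function(variants, calls, include_unknown = TRUE,
                             exclude_variants = character(0)) {
  validate_variants(variants)
  assert_that(nrow(calls) == nrow(variants),
              "calls must have one row per variant")
  positive_calls <- c("activating", "likely_activating")
  if (include_unknown) positive_calls <- c(positive_calls, "putative_activating_unknown")
  callv <- as.character(calls$call)
  if (length(exclude_variants) && "protein_change" %in% names(variants)) {
    key <- paste(variants$gene, variants$protein_change)
    callv[key %in% exclude_variants] <- "not_pathway"
  }
  cases <- unique(variants$case_id)
  pos <- vapply(cases, function(cid) {
    any(callv[variants$case_id == cid] %in% positive_calls)
  }, logical(1))
  data.frame(case_id = cases,
             status = ifelse(pos, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full triage cascade
#'
#' Convenience wrapper: panel-of-normals removal, hard/evidence filters,
#' NRF2 classification, and case-level status in one call.
#'
#' @inheritParams apply_hard_filters
#' @inheritParams classify_nrf2
#' @inheritParams case_nrf2_status
#' @return List with elements `variants` (retained rows with `tier`,
#'   `silent`, `nrf2_call` columns), `case_status`, and `config`.
#' @export
triage_variants <- function(variants, scores, config = filter_config(),
                            include_unknown = TRUE,
                            exclude_variants = character(0),
                            neh2_window = c(1L, 86L)) {
  v <- remove_panel_of_normals(variants)
  v <- apply_hard_filters(v, config)
  calls <- classify_nrf2(v, scores, neh2_window = neh2_window)
  v$nrf2_call <- as.character(calls$call)
  status <- case_nrf2_status(v, calls, include_unknown = include_unknown,
                             exclude_variants = exclude_variants)
  list(variants = v, case_status = status, config = config)
}
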