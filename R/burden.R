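#' Blood-based tumor mutational burden
#'
#' Counts mutations detected in ctDNA for one case/timepoint over a
#' targeted panel and normalizes per megabase of targeted territory.
#' The input is the post-QC variant set of a single case/timepoint; silent
#' variants are included (burden is computed before pathogenicity
#' filtering). Both the raw count (comparable to whole-exome counts over
#' the same genes) and the per-Mb density are returned.
#'
#' @param variants Canonical variant data frame for one case/timepoint.
#' @param panel_size_mb Megabases of targeted territory (> 0).
#' @param timepoint Optional timepoint label carried into the result.
#' @return List with `raw_count`, `per_mb`, `timepoint`.
#' @export
compute_btmb <- function(variants, panel_size_mb, timepoint = NA_character_) {
  validate_variants(variants)
  assert_that(is.numeric(panel_size_mb) && length(panel_size_mb) == 1L &&
                is.finite(panel_size_mb) && panel_size_mb > 0,
              "panel_size_mb must be a single positive number")
  raw_count <- nrow(variants)
  list(raw_count = raw_count,
       per_mb = raw_count / panel_size_mb,
       timepoint = timepoint)
}

#' ctDNA concentration from cfDNA and mean VAF
#'
#' Estimates the tumor-derived fraction of circulating DNA as the product
#' of the total plasma cfDNA concentration and the mean VAF over the
#' case's pathogenic/likely-pathogenic variants at that timepoint.
#'
#' @param cfdna_ng_ml Plasma cfDNA concentration (ng/ml) at the timepoint;
#'   `NA` when not measured.
#' @param pathogenic_variants Canonical variant data frame restricted to
#'   the case's pathogenic variants at the timepoint (may have zero rows).
#' @return ng/ml value; `0` when there are no pathogenic variants; `NA`
#'   (explicit absent, not zero) when the cfDNA measurement is missing.
#'   Variants without a recorded VAF are excluded from the mean; when no
#'   pathogenic variant carries a VAF the result is `NA`.
#' @export
ctdna_concentration <- function(cfdna_ng_ml, pathogenic_variants) {
  validate_variants(pathogenic_variants)
  if (is.na(cfdna_ng_ml)) return(NA_real_)
  assert_that(cfdna_ng_ml > 0, "cfDNA concentration must be positive when present")
  if (nrow(pathogenic_variants) == 0L) return(0)
  vafs <- pathogenic_variants$vaf[!is.na(pathogenic_variants$vaf)]
  if (length(vafs) == 0L) return(NA_real_)
  cfdna_ng_ml * mean(vafs)
}

#' Recurrent circulating mutations across timepoints
#'
#' Matches filtered oncogenic-evidence variants of one case between the
#' diagnosis sample and a later sample. The match key is
#' `(gene, protein_change)`; when the protein change is absent the genomic
#' key `(chrom, pos, ref, alt)` is used instead.
#'
#' @param diagnosis_variants,later_variants Canonical variant data frames
#'   for the two timepoints of one case.
#' @return The rows of `later_variants` whose key also occurs at diagnosis.
#' @export
detect_recurrent <- function(diagnosis_variants, later_variants) {
  validate_variants(diagnosis_variants)
  validate_variants(later_variants)
  key <- function(v) {
    n <- nrow(v)
    if (n == 0L) return(character(0))
    pc <- if ("protein_change" %in% names(v)) v$protein_change else rep(NA_character_, n)
    genomic <- if (all(c("chrom", "pos", "ref", "alt") %in% names(v))) {
      paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    } else rep(NA_character_, n)
    use_pc <- !is.na(pc) & nzchar(pc)
    ifelse(use_pc, paste(v$gene, pc), genomic)
  }
  later_keys <- key(later_variants)
  later_variants[later_keys %in% key(diagnosis_variants), , drop = FALSE]
}

#' Per-case burden summary table
#'
#' @param variants Canonical variant data frame over many cases (one
#'   timepoint, post-QC).
#' @param clinical Clinical data frame with `case_id` and a cfDNA column
#'   for the timepoint (`cfdna_ng_ml`).
#' @param panel_size_mb Megabases of targeted territory.
#' @param pathogenic_mask Logical vector marking pathogenic rows of
#'   `variants` (used for mean-VAF ctDNA estimation); defaults to
#'   non-silent rows.
#' @return Data frame with one row per case: `raw_count`, `per_mb`,
#'   `ctdna_ng_ml`.
#' @export
burden_table <- function(variants, clinical, panel_size_mb,
                         pathogenic_mask = NULL) {
  validate_variants(variants)
  assert_that(all(c("case_id") %in% names(clinical)),
              "clinical table needs a case_id column")
  if (is.null(pathogenic_mask)) pathogenic_mask <- variants$consequence != "silent"
  out <- lapply(clinical$case_id, function(cid) {
    v <- variants[variants$case_id == cid, , drop = FALSE]
    b <- compute_btmb(v, panel_size_mb)
    cf <- clinical$cfdna_ng_ml[match(cid, clinical$case_id)]
    patho <- variants[variants$case_id == cid & pathogenic_mask, , drop = FALSE]
    ct <- if (is.null(cf) || length(cf) == 0L) NA_real_ else ctdna_concentration(cf, patho)
    data.frame(case_id = cid, raw_count = b$raw_count, per_mb = b$per_mb,
               ctdna_ng_ml = ct, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
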