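#' Variant filter thresholds
#'
#' Bundles the post-calling filter thresholds used by the triage cascade.
#' Variants of unknown significance (VUS) are held to hard read-support and
#' allele-frequency limits, while variants carrying oncogenic evidence
#' (FATHMM or ClinVar) are retained down to a lower read-support floor.
#' Population-database pruning removes putative germline calls above a
#' frequency threshold.
#'
#' @param min_reads_vus Minimum unique alt-supporting reads for a VUS
#'   (default 5).
#' @param max_vaf_vus Exclusive upper bound on the variant allele frequency
#'   of a retained VUS, as a fraction (default 0.45; removes likely germline
#'   heterozygous calls).
#' @param min_reads_oncogenic Minimum unique alt-supporting reads for a
#'   variant with oncogenic evidence (default 2).
#' @param fathmm_threshold FATHMM score at or above which a variant counts
#'   as oncogenic evidence (default 0.99).
#' @param pop_freq_threshold Population allele frequency above which a
#'   variant is removed as putative germline (default 1e-5, i.e. 1:100,000).
#' @param min_vaf_report Minimum VAF for a variant to be reportable
#'   (default 0.01, the assay detection floor).
#'
#' @return An object of class `filter_config` (a validated list).
#' @export
filter_config <- function(min_reads_vus = 5L,
                          max_vaf_vus = 0.45,
                          min_reads_oncogenic = 2L,
                          fathmm_threshold = 0.99,
                          pop_freq_threshold = 1e-5,
                          min_vaf_report = 0.01) {
  assert_that(is_count(min_reads_vus), "min_reads_vus must be a non-negative integer")
  assert_that(is_count(min_reads_oncogenic),
              "min_reads_oncogenic must be a non-negative integer")
  assert_that(min_reads_vus >= min_reads_oncogenic,
              "min_reads_vus must be >= min_reads_oncogenic")
  assert_that(is_prob(max_vaf_vus), "max_vaf_vus must be in [0,1]")
  assert_that(is_prob(fathmm_threshold), "fathmm_threshold must be in [0,1]")
  assert_that(is_prob(pop_freq_threshold), "pop_freq_threshold must be in [0,1]")
  assert_that(is_prob(min_vaf_report), "min_vaf_report must be in [0,1]")
  structure(list(min_reads_vus = as.integer(min_reads_vus),
                 max_vaf_vus = max_vaf_vus,
                 min_reads_oncogenic = as.integer(min_reads_oncogenic),
                 fathmm_threshold = fathmm_threshold,
                 pop_freq_threshold = pop_freq_threshold,
                 min_vaf_report = min_vaf_report),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Variant filter configuration\n")
  cat(sprintf("  VUS:       >= %d unique reads, VAF < %.2f\n",
              x$min_reads_vus, x$max_vaf_vus))
  cat(sprintf("  Oncogenic: >= %d unique reads (FATHMM >= %.2f or ClinVar class)\n",
              x$min_reads_oncogenic, x$fathmm_threshold))
  cat(sprintf("  Population pruning: pop_freq > %g removed\n", x$pop_freq_threshold))
  invisible(x)
}
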