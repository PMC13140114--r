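test_that("panel-of-normals removal keeps exactly the unflagged records in order", {
  v <- bind_variants(make_variant(pos = 1L, in_pon = TRUE),
                     make_variant(pos = 2L, in_pon = FALSE),
                     make_variant(pos = 3L, in_pon = TRUE),
                     make_variant(pos = 4L, in_pon = FALSE))
  out <- remove_panel_of_normals(v)
  expect_equal(out$pos, c(2L, 4L))
  expect_equal(nrow(remove_panel_of_normals(v[0, ])), 0L)
  all_pon <- v; all_pon$in_pon <- TRUE
  expect_equal(nrow(remove_panel_of_normals(all_pon)), 0L)
})

test_that("evidence tier combines FATHMM and ClinVar criteria", {
  v <- bind_variants(
    make_variant(fathmm = 0.995, clinvar_class = "absent"),
    make_variant(fathmm = NA_real_, clinvar_class = "likely_oncogenic"),
    make_variant(fathmm = NA_real_, clinvar_class = "drug_response"),
    make_variant(fathmm = 0.5, clinvar_class = "other"),
    make_variant(fathmm = 0.99, clinvar_class = "absent"),   # boundary: >= threshold
    make_variant(fathmm = NA_real_, clinvar_class = "absent"))
  expect_equal(evidence_tier(v),
               c("oncogenic_evidence", "oncogenic_evidence", "oncogenic_evidence",
                 "vus", "oncogenic_evidence", "vus"))
})

test_that("hard filters apply the VUS and evidence rules plus population pruning", {
  cfg <- filter_config()
  vus4 <- make_variant(alt_reads = 4L, vaf = 0.10)             # VUS, too few reads
  onc2 <- make_variant(alt_reads = 2L, vaf = 0.021, fathmm = 0.995)
  vus_high <- make_variant(alt_reads = 10L, vaf = 0.50)        # germline-range VAF
  onc_pop <- make_variant(alt_reads = 20L, fathmm = 0.995, pop_freq = 2e-5)
  vus_ok <- make_variant(alt_reads = 6L, vaf = 0.10, pos = 7L)
  v <- bind_variants(vus4, onc2, vus_high, onc_pop, vus_ok)
  out <- apply_hard_filters(v, cfg)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$alt_reads, c(2L, 6L))
  expect_equal(out$tier[out$alt_reads == 2L], "oncogenic_evidence")
  # boundary: VAF exactly at the cap is excluded; pop_freq at threshold kept
  at_cap <- make_variant(alt_reads = 10L, vaf = 0.45)
  expect_equal(nrow(apply_hard_filters(at_cap, cfg)), 0L)
  at_pop <- make_variant(alt_reads = 20L, fathmm = 0.995, pop_freq = 1e-5)
  expect_equal(nrow(apply_hard_filters(at_pop, cfg)), 1L)
  # silent variants retained and flagged when they meet the read/VAF rules
  sil <- make_variant(consequence = "silent", alt_reads = 8L, vaf = 0.1)
  out_sil <- apply_hard_filters(sil, cfg)
  expect_true(out_sil$silent)
  expect_error(validate_variants(make_variant(alt_reads = -1L)), "non-negative")
})

test_that("strand-level minimum applies only when strand counts are present", {
  v <- make_variant(alt_reads = 10L, vaf = 0.1)
  v$reads_plus <- 9L; v$reads_minus <- 1L
  expect_equal(nrow(apply_hard_filters(v)), 0L)
  v$reads_minus <- 2L
  expect_equal(nrow(apply_hard_filters(v)), 1L)
  v$reads_plus <- NA_integer_
  expect_equal(nrow(apply_hard_filters(v)), 1L)   # missing split exempt
})

test_that("filtering is idempotent, monotone in min_reads_vus, and matches a per-record oracle", {
  set.seed(101)
  n <- 400
  v <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(case_id = sprintf("c%02d", sample(20, 1)),
                 pos = i,
                 consequence = sample(consequence_levels(), 1),
                 vaf = round(runif(1), 3),
                 alt_reads = sample(0:30, 1),
                 fathmm = if (runif(1) < 0.5) NA_real_ else round(runif(1), 3),
                 clinvar_class = sample(clinvar_levels(), 1),
                 pop_freq = if (runif(1) < 0.7) NA_real_ else 10^runif(1, -7, -3),
                 in_pon = runif(1) < 0.1)
  }))
  cfg <- filter_config()
  once <- apply_hard_filters(remove_panel_of_normals(v), cfg)
  twice <- apply_hard_filters(once, cfg)
  expect_equal(twice, once)
  # monotonicity: raising the VUS read threshold never enlarges the result
  for (thr in c(5L, 8L, 12L)) {
    kept <- apply_hard_filters(v, filter_config(min_reads_vus = thr))
    if (thr > 5L) expect_true(nrow(kept) <= nrow(prev))
    prev <- kept
  }
  # brute-force re-evaluation of the written predicate, record by record
  post_pon <- v[!v$in_pon, ]
  oracle_keep <- vapply(seq_len(nrow(post_pon)), function(i) {
    r <- post_pon[i, ]
    onc <- (!is.na(r$fathmm) && r$fathmm >= 0.99) ||
      r$clinvar_class %in% c("oncogenic", "likely_oncogenic", "drug_response")
    keep <- if (onc) r$alt_reads >= 2 else r$alt_reads >= 5 && r$vaf < 0.45
    keep && (is.na(r$pop_freq) || r$pop_freq <= 1e-5)
  }, logical(1))
  got <- apply_hard_filters(post_pon, cfg)
  expect_equal(got$pos, post_pon$pos[oracle_keep])
})

test_that("NRF2 classification follows the gene/consequence/score rules", {
  sc <- test_scores()
  v <- bind_variants(
    make_variant(gene = "NFE2L2", consequence = "missense", codon = 77L),
    make_variant(gene = "KEAP1", consequence = "frameshift", codon = 413L),
    make_variant(gene = "KEAP1", consequence = "missense", codon = 609L),
    make_variant(gene = "NFE2L2", consequence = "frameshift", codon = 28L),
    make_variant(gene = "NFE2L2", consequence = "frameshift", codon = 500L),
    make_variant(gene = "CUL3", consequence = "nonsense", codon = 751L),
    make_variant(gene = "TP53", consequence = "missense", codon = 175L),
    make_variant(gene = "KEAP1", consequence = "silent", codon = 278L),
    make_variant(gene = "KEAP1", consequence = "inframe_del", codon = 278L))
  calls <- classify_nrf2(v, sc)
  expect_equal(as.character(calls$call),
               c("activating", "likely_activating", "putative_activating_unknown",
                 "likely_lof",
                 "putative_activating_unknown",  # NFE2L2 frameshift outside Neh2
                 "likely_activating", "not_pathway", "not_pathway", "activating"))
  expect_match(calls$rationale[8], "silent")
  # a codon scored below the threshold is not called activating
  low <- codon_score_table("NFE2L2", 77L, -1, threshold = 0)
  call_low <- classify_nrf2(make_variant(gene = "NFE2L2", consequence = "missense",
                                         codon = 77L), low)
  expect_equal(as.character(call_low$call), "putative_activating_unknown")
  # Neh2 window is configurable
  wide <- classify_nrf2(v[4, ], sc, neh2_window = c(1L, 20L))
  expect_equal(as.character(wide$call), "putative_activating_unknown")
})

test_that("every filtered pathway variant receives exactly one call", {
  set.seed(7)
  v <- do.call(rbind, lapply(1:100, function(i) {
    make_variant(gene = sample(c("NFE2L2", "KEAP1", "CUL3"), 1),
                 consequence = sample(consequence_levels(), 1),
                 codon = sample(c(NA_integer_, 1:700), 1),
                 pos = i)
  }))
  calls <- classify_nrf2(v, test_scores())
  expect_equal(nrow(calls), nrow(v))
  expect_false(anyNA(calls$call))
})

test_that("case status aggregates calls with the LOF and unknown rules", {
  sc <- test_scores()
  lof_only <- make_variant(case_id = "A", gene = "NFE2L2",
                           consequence = "frameshift", codon = 28L)
  unk <- make_variant(case_id = "B", gene = "KEAP1", consequence = "missense",
                      codon = 609L, protein_change = "p.T609K")
  none <- make_variant(case_id = "C", gene = "TP53", consequence = "missense")
  v <- bind_variants(lof_only, unk, none)
  calls <- classify_nrf2(v, sc)
  st <- case_nrf2_status(v, calls)
  expect_equal(st$status[st$case_id == "A"], "negative")
  expect_equal(st$status[st$case_id == "B"], "positive")
  expect_equal(st$status[st$case_id == "C"], "negative")
  st2 <- case_nrf2_status(v, calls, include_unknown = FALSE)
  expect_equal(st2$status[st2$case_id == "B"], "negative")
  st3 <- case_nrf2_status(v, calls, exclude_variants = "KEAP1 p.T609K")
  expect_equal(st3$status[st3$case_id == "B"], "negative")
})
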