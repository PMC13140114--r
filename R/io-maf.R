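#' Read a MAF-like somatic variant TSV
#'
#' Reads a tab-separated mutation table and maps the MAF dialect columns
#' onto the canonical layout. Required columns: `Hugo_Symbol`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`, `HGVSc`, `HGVSp`,
#' `t_alt_count`, `VAF`. Optional: `Tumor_Sample_Barcode` (case id),
#' `Timepoint`, `Codon`, `FATHMM`, `CLINVAR_CLASS`, `POP_AF`, `IN_PON`,
#' `READS_PLUS`, `READS_MINUS`.
#'
#' VAF columns in percent (as clinical reports print them) are converted
#' to fractions: conversion is automatic when any value exceeds 1.5, or
#' forced via `vaf_percent`.
#'
#' @param path TSV path.
#' @param vaf_percent `NA` (auto-detect), `TRUE` (input is percent), or
#'   `FALSE` (input is fraction).
#' @return Canonical variant data frame (see [variant_table]).
#' @export
read_maf <- function(path, vaf_percent = NA) {
  assert_that(file.exists(path), paste("no such file:", path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = c("NA", ""))
  required <- c("Hugo_Symbol", "Variant_Classification", "t_alt_count", "VAF")
  missing <- setdiff(required, names(raw))
  assert_that(length(missing) == 0L,
              paste0("MAF file ", path, " lacks columns: ",
                     paste(missing, collapse = ", ")))
  class_map <- c(Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
                 Frame_Shift_Del = "frameshift", Frame_Shift_Ins = "frameshift",
                 In_Frame_Ins = "inframe_ins", In_Frame_Del = "inframe_del",
                 Splice_Site = "splice", Silent = "silent")
  consequence <- unname(class_map[raw$Variant_Classification])
  # canonical lowercase names pass through unchanged
  direct <- raw$Variant_Classification %in% consequence_levels()
  consequence[direct] <- raw$Variant_Classification[direct]
  bad <- is.na(consequence)
  if (any(bad)) {
    consequence[bad] <- "other"
  }
  vaf <- as.numeric(raw$VAF)
  if (is.na(vaf_percent)) vaf_percent <- any(vaf > 1.5, na.rm = TRUE)
  if (isTRUE(vaf_percent)) vaf <- vaf / 100
  pick <- function(col, default) if (col %in% names(raw)) raw[[col]] else default
  n <- nrow(raw)
  out <- data.frame(
    case_id = as.character(pick("Tumor_Sample_Barcode", sprintf("case%03d", seq_len(n)))),
    timepoint = as.character(pick("Timepoint", rep("diagnosis", n))),
    gene = raw$Hugo_Symbol,
    chrom = as.character(pick("Chromosome", NA_character_)),
    pos = as.integer(pick("Start_Position", NA_integer_)),
    ref = as.character(pick("Reference_Allele", NA_character_)),
    alt = as.character(pick("Tumor_Seq_Allele2", NA_character_)),
    cdna_change = as.character(pick("HGVSc", NA_character_)),
    protein_change = as.character(pick("HGVSp", NA_character_)),
    codon = as.integer(pick("Codon", NA_integer_)),
    consequence = consequence,
    vaf = vaf,
    alt_reads = as.integer(raw$t_alt_count),
    fathmm = as.numeric(pick("FATHMM", NA_real_)),
    clinvar_class = as.character(pick("CLINVAR_CLASS", "absent")),
    pop_freq = as.numeric(pick("POP_AF", NA_real_)),
    in_pon = as.logical(pick("IN_PON", FALSE)),
    stringsAsFactors = FALSE)
  out$clinvar_class[is.na(out$clinvar_class)] <- "absent"
  out$in_pon[is.na(out$in_pon)] <- FALSE
  if ("READS_PLUS" %in% names(raw)) out$reads_plus <- as.integer(raw$READS_PLUS)
  if ("READS_MINUS" %in% names(raw)) out$reads_minus <- as.integer(raw$READS_MINUS)
  # infer codon from HGVSp when not given explicitly
  need <- is.na(out$codon) & !is.na(out$protein_change)
  if (any(need)) {
    m <- regmatches(out$protein_change[need],
                    regexpr("[0-9]+", out$protein_change[need]))
    got <- lengths(regmatches(out$protein_change[need],
                              gregexpr("[0-9]+", out$protein_change[need]))) > 0
    out$codon[need][got] <- as.integer(m)
  }
  validate_variants(out)
  out
}

#' Write a canonical variant table as MAF-like TSV
#'
#' Inverse of [read_maf()]: canonical columns are mapped back to the MAF
#' dialect names; VAF is written as a fraction at full precision.
#'
#' @param variants Canonical variant data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  validate_variants(variants)
  g <- function(col, default) if (col %in% names(variants)) variants[[col]] else
    rep(default, nrow(variants))
  out <- data.frame(
    Hugo_Symbol = variants$gene,
    Chromosome = g("chrom", NA_character_),
    Start_Position = g("pos", NA_integer_),
    Reference_Allele = g("ref", NA_character_),
    Tumor_Seq_Allele2 = g("alt", NA_character_),
    Variant_Classification = variants$consequence,
    HGVSc = g("cdna_change", NA_character_),
    HGVSp = g("protein_change", NA_character_),
    Codon = g("codon", NA_integer_),
    t_alt_count = variants$alt_reads,
    VAF = variants$vaf,
    Tumor_Sample_Barcode = variants$case_id,
    Timepoint = g("timepoint", NA_character_),
    FATHMM = g("fathmm", NA_real_),
    CLINVAR_CLASS = g("clinvar_class", "absent"),
    POP_AF = g("pop_freq", NA_real_),
    IN_PON = g("in_pon", FALSE),
    stringsAsFactors = FALSE)
  extra <- intersect(c("tier", "silent", "nrf2_call", "truth"), names(variants))
  for (col in extra) out[[toupper(col)]] <- variants[[col]]
  write_tsv(out, path)
}

#' Write a data frame as TSV at full numeric precision
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  for (col in names(x)[num]) {
    v <- x[[col]]
    if (is.integer(v)) next
    x[[col]] <- vapply(v, function(z) {
      if (is.na(z)) NA_character_ else format(z, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a clinical case table
#'
#' TSV with one row per case: `case_id` plus clinical covariates (`sex`,
#' `age`, `stage`, `smoking`, `histology`, `cfdna_ng_ml`, `panel_size_mb`,
#' and optionally per-timepoint cfDNA columns `cfdna_<timepoint>`).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  assert_that("case_id" %in% names(df),
              paste0("clinical table ", path, " lacks a case_id column"))
  df
}
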