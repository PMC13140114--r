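#' Codon-level NRF2 activity score table
#'
#' Holds per-(gene, codon) NRF2 transcriptional activity scores together
#' with the hyperactivity threshold: a missense/in-frame variant whose
#' codon's mean score exceeds the threshold is considered NRF2 activating.
#' The score itself is derived from downstream NRF2 target-gene expression
#' in an external tumor compendium and is consumed here as a table.
#'
#' @param gene Character vector of HUGO symbols.
#' @param codon Integer vector of codon indices (same length).
#' @param score Numeric score per row; multiple rows per (gene, codon) are
#'   allowed and averaged at query time.
#' @param threshold Finite numeric hyperactivity threshold.
#' @return An object of class `codon_score_table`.
#' @export
codon_score_table <- function(gene, codon, score, threshold) {
  assert_that(length(gene) == length(codon) && length(codon) == length(score),
              "gene, codon and score must have equal length")
  assert_that(is.numeric(threshold) && length(threshold) == 1L && is.finite(threshold),
              "threshold must be a single finite number")
  assert_that(all(is.finite(score)), "scores must be finite")
  structure(list(entries = data.frame(gene = as.character(gene),
                                      codon = as.integer(codon),
                                      score = as.numeric(score),
                                      stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "codon_score_table")
}

#' Mean activity score of a codon
#'
#' @param scores A [codon_score_table()].
#' @param gene HUGO symbol.
#' @param codon Codon index (`NA` allowed).
#' @return Mean score over entries for the (gene, codon), or `NA` when the
#'   codon is absent from the table.
#' @export
codon_mean_score <- function(scores, gene, codon) {
  assert_that(inherits(scores, "codon_score_table"),
              "scores must be a codon_score_table")
  if (is.na(codon)) return(NA_real_)
  hit <- scores$entries$gene == gene & scores$entries$codon == codon
  if (!any(hit)) return(NA_real_)
  mean(scores$entries$score[hit])
}

#' Read a codon score table from TSV
#'
#' Expects columns `gene`, `codon`, `score`; the hyperactivity threshold is
#' passed separately or read from a `# threshold=<x>` header comment line.
#'
#' @param path TSV file path.
#' @param threshold Hyperactivity threshold; if `NULL`, parsed from a
#'   `# threshold=` comment in the file header.
#' @return A [codon_score_table()].
#' @export
read_codon_scores <- function(path, threshold = NULL) {
  assert_that(file.exists(path), paste("no such file:", path))
  if (is.null(threshold)) {
    head_lines <- readLines(path, n = 5L)
    m <- regmatches(head_lines, regexpr("#\\s*threshold\\s*=\\s*[-0-9.eE+]+", head_lines))
    assert_that(length(m) > 0, "threshold not given and no '# threshold=' header found")
    threshold <- as.numeric(sub(".*=\\s*", "", m[[1]]))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_that(all(c("gene", "codon", "score") %in% names(df)),
              "codon score TSV needs columns gene, codon, score")
  codon_score_table(df$gene, df$codon, df$score, threshold)
}

#' @export
print.codon_score_table <- function(x, ...) {
  cat(sprintf("Codon activity score table: %d entries over %d genes, threshold %.4g\n",
              nrow(x$entries), length(unique(x$entries$gene)), x$threshold))
  invisible(x)
}
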