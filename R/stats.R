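#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood convention (the sum of
#' hypergeometric point probabilities not exceeding the observed table's,
#' with a small relative tolerance for ties), plus the sample odds ratio
#' `ad/bc` (`Inf`/`0` allowed). Degenerate tables with an all-zero margin
#' return `p = 1` by convention.
#'
#' @param a,b,c,d Non-negative integer counts; rows are groups, columns
#'   outcomes, i.e. the table is `rbind(c(a, b), c(c, d))`.
#' @return List with `p_two_sided`, `odds_ratio` (sample `ad/bc`), and the
#'   input `table`.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == floor(counts)),
              "counts must be non-negative integers")
  tab <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  or_sample <- (a * d) / (b * c)  # 0/0 -> NaN for doubly degenerate tables
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(p_two_sided = 1, odds_ratio = or_sample, table = tab))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p_two_sided = min(p, 1), odds_ratio = or_sample, table = tab)
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' For every unordered gene pair in a cases-by-genes presence matrix,
#' builds the 2x2 joint-presence table and applies [fisher_exact()].
#' Direction is `co_occurrence` when the sample odds ratio exceeds 1 and
#' `exclusivity` when below 1; raw p-values are reported (no adjustment),
#' with optional Benjamini-Hochberg correction.
#'
#' @param mutation_matrix Logical (or 0/1) matrix, rows = cases, named
#'   columns = genes, restricted to pathogenic/likely-pathogenic calls.
#' @param adjust Apply Benjamini-Hochberg across pairs (default FALSE).
#' @return Data frame with one row per pair: `gene_a`, `gene_b`, counts
#'   `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`, `p`,
#'   `direction` (`NA` for constant columns), and `p_adj` when requested.
#' @export
pairwise_cooccurrence <- function(mutation_matrix, adjust = FALSE) {
  m <- as.matrix(mutation_matrix)
  assert_that(!is.null(colnames(m)), "mutation_matrix needs gene column names")
  storage.mode(m) <- "logical"
  genes <- colnames(m)
  assert_that(length(genes) >= 2L, "need at least two genes")
  pairs <- utils::combn(genes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    xa <- m[, ga]; xb <- m[, gb]
    n11 <- sum(xa & xb); n10 <- sum(xa & !xb)
    n01 <- sum(!xa & xb); n00 <- sum(!xa & !xb)
    ft <- fisher_exact(n11, n10, n01, n00)
    constant <- length(unique(xa)) == 1L || length(unique(xb)) == 1L
    direction <- if (constant || !is.finite(ft$odds_ratio) && is.nan(ft$odds_ratio)) {
      NA_character_
    } else if (ft$odds_ratio > 1) "co_occurrence"
    else if (ft$odds_ratio < 1) "exclusivity" else NA_character_
    data.frame(gene_a = ga, gene_b = gb, n_both = n11, n_a_only = n10,
               n_b_only = n01, n_neither = n00,
               odds_ratio = ft$odds_ratio, p = ft$p_two_sided,
               direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples: exact p-value by
#' enumeration for small tie-free samples, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `U` (statistic for `x`), `p_two_sided`, and
#'   `rank_biserial` effect size (`2*U/(n_x*n_y) - 1`).
#' @export
mann_whitney_u <- function(x, y) {
  assert_that(length(x) >= 1L && length(y) >= 1L, "both samples must be non-empty")
  assert_that(is.numeric(x) && is.numeric(y) && !anyNA(x) && !anyNA(y),
              "samples must be numeric without NA")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, p_two_sided = min(wt$p.value, 1),
       rank_biserial = 2 * U / (length(x) * length(y)) - 1)
}

#' Paired correlation test
#'
#' Pearson or Spearman correlation with a t-approximation p-value.
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p_two_sided`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(length(x) == length(y), "samples must be paired")
  assert_that(length(x) >= 3L, "need at least 3 pairs")
  assert_that(!anyNA(x) && !anyNA(y), "NA not allowed")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for zero-variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_two_sided = ct$p.value, method = method)
}

#' ROC curve, AUC, and Youden-optimal cut-point
#'
#' Builds the ROC curve over all distinct score thresholds with the
#' decision rule "score >= cutpoint is positive", computes the trapezoidal
#' AUC (equal to the Mann-Whitney probability with midrank ties), and
#' selects the cut-point maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward the lowest threshold (the
#' sensitivity-maximizing convention, appropriate for ordinal marker
#' scales such as IHC intensity classes 0-3).
#'
#' @param scores Numeric marker values, one per case.
#' @param labels Logical (or 0/1) true condition per case; both classes
#'   must be represented.
#' @return List with `roc_points` (data frame `threshold`, `fpr`, `tpr`),
#'   `auc`, `cutpoint`, `youden_j`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  assert_that(length(scores) == length(labels) && !anyNA(scores) && !anyNA(labels),
              "scores and labels must be paired and NA-free")
  n1 <- sum(labels); n0 <- sum(!labels)
  assert_that(n1 >= 1L && n0 >= 1L, "both classes must be represented")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  # curve from (0,0) (threshold above max) to (1,1) (threshold at/below min)
  roc_points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- trapz(roc_points$fpr, roc_points$tpr)
  j <- tpr - fpr
  jmax <- max(j)
  cut_idx <- which(j >= jmax - 1e-12)
  cutpoint <- min(thr[cut_idx])  # lowest threshold among J maximizers
  sens <- sum(scores >= cutpoint & labels) / n1
  spec <- sum(scores < cutpoint & !labels) / n0
  acc <- (sum(scores >= cutpoint & labels) + sum(scores < cutpoint & !labels)) /
    length(labels)
  list(roc_points = roc_points, auc = auc, cutpoint = cutpoint,
       youden_j = sens + spec - 1, sensitivity = sens, specificity = spec,
       accuracy = acc)
}
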