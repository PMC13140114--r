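# Builders and independent oracles shared across the suite.

make_variant <- function(case_id = "case001", gene = "KEAP1",
                         consequence = "missense", codon = NA_integer_,
                         vaf = 0.05, alt_reads = 10L, fathmm = NA_real_,
                         clinvar_class = "absent", pop_freq = NA_real_,
                         in_pon = FALSE, protein_change = NA_character_,
                         timepoint = "diagnosis", chrom = "chr1",
                         pos = 1000L, ref = "A", alt = "T") {
  data.frame(case_id = case_id, timepoint = timepoint, gene = gene,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             cdna_change = NA_character_, protein_change = protein_change,
             codon = codon, consequence = consequence, vaf = vaf,
             alt_reads = as.integer(alt_reads), fathmm = fathmm,
             clinvar_class = clinvar_class, pop_freq = pop_freq,
             in_pon = in_pon, stringsAsFactors = FALSE)
}

bind_variants <- function(...) do.call(rbind, list(...))

test_scores <- function(threshold = 0) {
  codon_score_table(gene = c("NFE2L2", "NFE2L2", "KEAP1", "KEAP1", "KEAP1"),
                    codon = c(77L, 24L, 278L, 323L, 480L),
                    score = threshold + c(1.2, 1.4, 1.1, 1.3, 1.5),
                    threshold = threshold)
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "nrf2ctdna")
  stopifnot(nzchar(p))
  p
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p
# (minimum-likelihood convention), independent of stats::fisher.test
fisher_oracle <- function(a, b, c, d, tol = 1e-7) {
  m <- a + b; n2 <- c + d; k <- a + c
  x <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + tol)])
}

# brute-force double-loop directed Hausdorff
brute_hausdorff <- function(A, B) {
  best_outer <- -Inf
  for (i in seq_len(dim(A)[1])) {
    best_inner <- Inf
    for (j in seq_len(dim(B)[1])) {
      best_inner <- min(best_inner, coord_rmsd(A[i, , ], B[j, , ]))
    }
    best_outer <- max(best_outer, best_inner)
  }
  best_outer
}

# connected components of a contact graph by breadth-first search
contact_components <- function(coords, cutoff) {
  d <- as.matrix(stats::dist(coords))
  adj <- d > 0 & d <= cutoff
  n <- nrow(adj)
  comp <- rep(0L, n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  k
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small trajectory of gaussian wiggle around a non-degenerate base
wiggle_traj <- function(n_frames, base, sd = 0.3) {
  fr <- array(stats::rnorm(n_frames * length(base), 0, sd),
              c(n_frames, nrow(base), 3))
  fr + rep(base, each = n_frames)
}

base_points <- function(n = 6, seed = 99) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, 0, 4), ncol = 3)
}
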