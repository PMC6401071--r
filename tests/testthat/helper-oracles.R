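# Independent brute-force oracles, kept free of the code paths they check.

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations to the first group (doubled smaller tail, capped at 1 --
# the same two-sided convention as the exact Wilcoxon test).
brute_force_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Two-sample KS statistic by direct ECDF comparison on the pooled grid.
brute_force_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Cumulative hypergeometric P(X >= k) by direct summation.
brute_force_hyper_p <- function(k, top_n, universe, m) {
  i <- k:min(top_n, m)
  sum(choose(top_n, i) * choose(universe - top_n, m - i)) /
    choose(universe, m)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating the hypergeometric
# support and summing outcomes no more probable than the observed table.
brute_force_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the textbook formula.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}

# Expected cDNA region distribution by exhaustive enumeration of every
# genomic base in the transcript span, each mapped through the coordinate
# machine and classified.
enumerate_region_distribution <- function(annotation, transcript_id) {
  tx <- annotation$transcripts
  i <- match(transcript_id, tx$transcript_id)
  pos <- seq(tx$tx_start[i], tx$tx_end[i] - 1)
  cd <- genomic_to_cdna(annotation, rep(transcript_id, length(pos)), pos)
  region <- classify_cdna_region(annotation, rep(transcript_id, length(pos)),
                                 cd$cdna)
  c(UTR5 = mean(region == "UTR5"), CDS = mean(region == "CDS"),
    UTR3 = mean(region == "UTR3"))
}

# Literal ssGSEA running sum: walk the descending-expression list, tracking
# the weighted in-set and uniform out-of-set cumulative distributions.
ssgsea_running_sum <- function(x, gene_set, alpha) {
  genes <- names(x)
  ord <- order(-x, genes)
  in_set <- genes[ord] %in% gene_set
  rnk <- rank(x, ties.method = "average")[ord]
  w <- ifelse(in_set, rnk^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / sum(!in_set)
  sum(p_in - p_out)
}

# One toy annotation reused across files: two genes on chr1 (one per strand,
# with introns), one single-exon gene, plus a chr2 gene.
toy_annotation <- function() {
  ct <- chromosome_table(c("chr1", "chr2"), c(1e6, 1e6))
  exons <- tibble::tibble(
    transcript_id = c("tA", "tA", "tB", "tB", "tC", "tD"),
    gene = c("A", "A", "B", "B", "C", "D"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "-", "-", "+", "+"),
    start = c(100, 300, 5000, 5300, 20000, 100),
    end = c(200, 450, 5200, 5450, 20600, 700)
  )
  cds <- tibble::tibble(
    transcript_id = c("tA", "tB", "tC", "tD"),
    cds_start = c(150, 5100, 20100, 200),
    cds_end = c(400, 5400, 20400, 600)
  )
  fusescan:::build_annotation(exons, cds, ct)
}
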