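#' Read subtype signature gene lists
#'
#' One file per subtype, one gene symbol per line; the file name (minus
#' extension) is the subtype name.
#'
#' @param dir Directory of signature files.
#' @return Named list of character vectors.
#' @export
read_signatures <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|grp)$", full.names = TRUE)
  if (length(files) == 0) abort("No signature files found.")
  sigs <- purrr::map(files, readLines)
  names(sigs) <- sub("\\.[^.]+$", "", basename(files))
  sigs
}

#' Single-sample gene-set enrichment raw score
#'
#' Rank-based running-sum statistic for one sample: genes are ordered by
#' expression (descending; average ranks for ties feed the weights), and the
#' score is the sum over the list of the difference between the weighted
#' in-set cumulative distribution (weights = rank^`alpha` for in-set genes)
#' and the uniform out-of-set cumulative distribution. With `alpha = 0` this
#' reduces to the classic unweighted Kolmogorov-Smirnov running sum.
#'
#' Writing `r_g` for a gene's (tie-averaged, ascending) expression rank and
#' `w_g = r_g^alpha` for its weight, the sum telescopes to the closed form
#' `sum_{g in S} w_g r_g / W - sum_{g not in S} r_g / (N - m)`, which is what
#' the implementation evaluates; a fully tied profile scores exactly 0.
#'
#' @param x Named numeric expression vector (one sample).
#' @param gene_set Character vector of set genes.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Raw enrichment score (signed scalar).
#' @export
ssgsea_raw_score <- function(x, gene_set, alpha = 0.25) {
  genes <- names(x)
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  if (m == 0) abort("Gene set does not intersect the expression universe.")
  N <- length(x)
  if (m == N) {
    warn("Gene set equals the expression universe; score defined as 0.")
    return(0)
  }
  # average ranks (high expression = high rank) serve both as the cumulative
  # term (N + 1 - position, tie-averaged) and, raised to alpha, as weights;
  # tied genes then share one value and a flat profile scores exactly 0
  rnk <- rank(x, ties.method = "average")
  w <- rnk^alpha
  sum(w[in_set] * rnk[in_set]) / sum(w[in_set]) -
    sum(rnk[!in_set]) / (N - m)
}

#' Normalize raw ssGSEA scores against size-matched random sets
#'
#' Divides the raw score by the mean absolute raw score of `n_perm` gene sets
#' of the same size drawn uniformly without replacement from the universe
#' (signs of normalized scores stay interpretable). Deterministic under
#' `seed`.
#'
#' @param raw Raw score(s) for the sample (numeric vector, one per set).
#' @param x Named expression vector of the sample.
#' @param set_size Size of the gene set(s) being normalized.
#' @param n_perm Number of random sets (default 1000).
#' @param alpha Rank-weight exponent.
#' @param seed Integer seed.
#' @return Normalized score(s), same length as `raw`.
#' @export
normalize_scores <- function(raw, x, set_size, n_perm = 1000, alpha = 0.25,
                             seed = 1L) {
  null_mean <- ssgsea_null_mean(x, set_size, n_perm, alpha, seed)
  if (null_mean == 0) abort("Degenerate universe: null mean score is 0.")
  raw / null_mean
}

# mean |raw score| over n_perm random same-size sets, via the closed form
ssgsea_null_mean <- function(x, set_size, n_perm, alpha, seed) {
  N <- length(x)
  rnk <- rank(x, ties.method = "average")
  w <- rnk^alpha
  a <- rnk
  tot <- sum(a)
  withr::with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      s <- sample.int(N, set_size)
      sum(w[s] * a[s]) / sum(w[s]) - (tot - sum(a[s])) / (N - set_size)
    }, numeric(1))
    mean(abs(null))
  })
}

#' Assign molecular subtypes by ssGSEA
#'
#' Scores each of four subtype signatures in every sample, normalizes against
#' 1,000 size-matched random gene sets, and assigns each sample the subtype
#' with the highest normalized score. Ties are broken by the fixed signature
#' order and flagged. Signature genes missing from the expression universe
#' are dropped with a message.
#'
#' @param expression Expression tibble (`gene` + sample columns).
#' @param signatures Named list of >= 1 gene vectors (canonically the four
#'   subtype signatures).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param n_perm Random sets per normalization (default 1000).
#' @param seed Integer seed.
#' @return A `subtype_scores` tibble: `sample`, one `raw_*` and `norm_*`
#'   column per signature, `subtype`, `tie`.
#' @export
assign_subtypes <- function(expression, signatures, alpha = 0.25,
                            n_perm = 1000, seed = 1L) {
  em <- expr_as_matrix(expression)
  sigs <- purrr::map(signatures, function(s) {
    missing <- setdiff(s, rownames(em))
    if (length(missing) > 0) {
      inform(sprintf("%d signature gene(s) missing from universe; dropped.",
                     length(missing)))
    }
    intersect(s, rownames(em))
  })
  if (any(lengths(sigs) == 0)) abort("A signature has no genes in the universe.")
  sizes <- lengths(sigs)
  samples <- colnames(em)
  rows <- purrr::map(seq_along(samples), function(j) {
    x <- em[, j]
    names(x) <- rownames(em)
    raw <- purrr::map_dbl(sigs, ~ suppressWarnings(ssgsea_raw_score(x, .x, alpha)))
    norm <- purrr::map_dbl(seq_along(sigs), function(k) {
      tryCatch(
        normalize_scores(raw[k], x, sizes[k], n_perm, alpha,
                         seed = derive_seed(seed, j * 17L + as.integer(k))),
        error = function(e) 0   # flat profile: all null scores 0, call it a tie
      )
    })
    names(norm) <- names(sigs)
    best <- which(norm == max(norm))
    tibble(sample = samples[j],
           !!!setNames(as.list(raw), paste0("raw_", names(sigs))),
           !!!setNames(as.list(norm), paste0("norm_", names(sigs))),
           subtype = names(sigs)[best[1]],
           tie = length(best) > 1)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$tie)) {
    inform(sprintf("%d sample(s) with tied subtype scores; first in order kept.",
                   sum(out$tie)))
  }
  class(out) <- c("subtype_scores", class(out))
  out
}

#' Fusion burden by subtype enrichment (top decile)
#'
#' Tests whether samples in the highest decile of fusion burden (burden at or
#' above the 90th percentile, ties included) are enriched for the
#' immunoreactive or proliferative subtypes, with a two-sided Fisher exact
#' test on the 2x2 table {top decile vs rest} x {immunoreactive or
#' proliferative vs differentiated or mesenchymal}.
#'
#' @param burdens Tibble with `sample` and `n` (per-sample fusion counts),
#'   e.g. `burden_summary(calls)$per_sample`.
#' @param subtypes Tibble with `sample` and `subtype`, e.g. from
#'   [assign_subtypes()].
#' @return Tibble: `odds_ratio`, `p_value`, table margins.
#' @export
burden_subtype_enrichment <- function(burdens, subtypes) {
  d <- inner_join(burdens, subtypes, by = "sample")
  if (nrow(d) < 20) abort("At least 20 samples required.")
  cut <- quantile(d$n, 0.9, type = 7)
  top <- d$n >= cut
  hi_sub <- d$subtype %in% c("immunoreactive", "proliferative")
  tab <- matrix(c(sum(top & hi_sub), sum(top & !hi_sub),
                  sum(!top & hi_sub), sum(!top & !hi_sub)),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Empty margin in burden-subtype table.")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         n_top = sum(top), n_rest = sum(!top),
         burden_cutoff = unname(cut))
}
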