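#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows distinct n pull rename
#'   row_number across count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile rnorm runif rbinom rnbinom rlnorm rbeta
#'   wilcox.test ks.test chisq.test fisher.test p.adjust phyper loess predict
#'   setNames complete.cases
#' @importFrom utils head tail
NULL

# Add-one corrected empirical (permutation) p-value, never below 1/(n+1).
# Two-sided p uses the absolute deviation from the permutation mean as the
# test statistic, which stays well calibrated for discrete (count-valued)
# statistics where doubling the smaller tail over-counts tie mass.
empirical_p <- function(observed, null, tail = c("upper", "lower", "two.sided")) {
  tail <- match.arg(tail)
  n <- length(null)
  switch(tail,
    upper = (1 + sum(null >= observed)) / (n + 1),
    lower = (1 + sum(null <= observed)) / (n + 1),
    two.sided = {
      m <- mean(null)
      (1 + sum(abs(null - m) >= abs(observed - m))) / (n + 1)
    }
  )
}

# Ratio of group means with a pseudocount, the fold-change convention used
# throughout (FPKM scale, unlogged).
fold_change <- function(pos, neg, eps = 0.01) {
  (mean(pos) + eps) / (mean(neg) + eps)
}

# Derive a stage seed from a global seed without exceeding .Machine$integer.max.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}
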