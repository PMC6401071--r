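#' Build anchor windows
#'
#' An anchor gene is a gene involved in a fusion; its window contains every
#' other gene on the same chromosome whose span midpoint lies within
#' `half_width` of the anchor's midpoint. Distances are signed (neighbor
#' midpoint minus anchor midpoint). Anchors absent from the annotation are
#' skipped with a warning; anchors with no in-range neighbor are retained as
#' a row with `NA` neighbor.
#'
#' @param annotation A `fusion_annotation`.
#' @param anchors Character vector of anchor gene symbols.
#' @param half_width Window half-width in bp (default 1e6, i.e. a 2 Mb
#'   window).
#' @return Tibble: `anchor`, `neighbor`, `distance`.
#' @export
build_anchor_windows <- function(annotation, anchors, half_width = 1e6) {
  g <- annotation$genes
  missing <- setdiff(anchors, g$gene)
  if (length(missing) > 0) {
    warn(sprintf("%d anchor(s) absent from annotation; skipped.",
                 length(missing)))
    anchors <- setdiff(anchors, missing)
  }
  anchors <- unique(anchors)
  purrr::map(anchors, function(a) {
    i <- match(a, g$gene)
    nb <- g[g$chrom == g$chrom[i] & g$gene != a, ]
    d <- nb$midpoint - g$midpoint[i]
    keep <- abs(d) <= half_width
    if (!any(keep)) {
      return(tibble(anchor = a, neighbor = NA_character_,
                    distance = NA_real_))
    }
    tibble(anchor = a, neighbor = nb$gene[keep], distance = d[keep])
  }) |> dplyr::bind_rows()
}

#' Fusion-status fold changes for window neighbors
#'
#' For each (anchor, neighbor) pair, compares the neighbor's expression in
#' samples carrying a fusion in the anchor against the remaining samples:
#' fold change as ratio of group means with pseudocount 0.01 and a two-sided
#' Wilcoxon rank-sum p-value. Anchors with fewer than `min_positives`
#' fusion-positive samples are skipped (count reported via the
#' `skipped_anchors` attribute).
#'
#' @param expression Expression tibble (`gene` + sample columns).
#' @param windows Output of [build_anchor_windows()].
#' @param status Fusion-status matrix from [fusion_status_matrix()].
#' @param min_positives Minimum fusion-positive samples per anchor.
#' @return Tibble: `anchor`, `neighbor`, `distance`, `n_pos`, `fold`,
#'   `log2_fold`, `p`.
#' @export
neighbor_fold_changes <- function(expression, windows, status,
                                  min_positives = 3) {
  em <- expr_as_matrix(expression)
  w <- filter(windows, !is.na(.data$neighbor),
              .data$anchor %in% rownames(status),
              .data$neighbor %in% rownames(em))
  n_pos_anchor <- rowSums(status[, colnames(status), drop = FALSE] > 0)
  eligible <- names(n_pos_anchor)[n_pos_anchor >= min_positives]
  skipped <- length(setdiff(unique(w$anchor), eligible))
  w <- filter(w, .data$anchor %in% eligible)
  rows <- purrr::map(seq_len(nrow(w)), function(r) {
    s <- status[w$anchor[r], ] > 0
    x <- em[w$neighbor[r], names(s)]
    pos <- x[s]; neg <- x[!s]
    f <- fold_change(pos, neg)
    p <- suppressWarnings(
      wilcox.test(pos, neg, alternative = "two.sided")$p.value)
    tibble(anchor = w$anchor[r], neighbor = w$neighbor[r],
           distance = w$distance[r], n_pos = sum(s), fold = f,
           log2_fold = log2(f), p = p)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_anchors") <- skipped
  out
}

# log2 fold changes of each eligible anchor's neighbors for the observed
# status and for n_rand independent label permutations per anchor.
pair_logfolds <- function(em, windows, status, min_positives, n_rand, eps = 0.01) {
  anchors <- unique(windows$anchor)
  obs <- list(); null <- list(); meta <- list()
  for (a in anchors) {
    wa <- windows[windows$anchor == a, ]
    s <- status[a, ] > 0
    if (sum(s) < min_positives) next
    E <- em[wa$neighbor, names(s), drop = FALSE]
    np <- sum(s); nn <- sum(!s)
    rs <- rowSums(E)
    pos_obs <- as.numeric(E %*% s)
    obs[[a]] <- log2((pos_obs / np + eps) / ((rs - pos_obs) / nn + eps))
    P <- vapply(seq_len(n_rand), function(r) sample(s), logical(length(s)))
    pos_sum <- E %*% P
    null[[a]] <- log2((pos_sum / np + eps) / ((rs - pos_sum) / nn + eps))
    meta[[a]] <- wa
  }
  w <- dplyr::bind_rows(meta)
  list(windows = w, obs = unlist(obs, use.names = FALSE),
       null = do.call(rbind, null))
}

loess_curve <- function(distance, log2_fold, grid, span) {
  keep <- is.finite(log2_fold)
  fit <- suppressWarnings(
    loess(log2_fold[keep] ~ distance[keep], span = span, degree = 1,
          family = "gaussian",
          control = stats::loess.control(surface = "interpolate")))
  predict(fit, newdata = grid)
}

#' Aggregate regional dysregulation profile with a randomization null
#'
#' Smooths the per-pair log2 fold changes over signed distance with loess
#' (local linear, tricube weights) and builds a pointwise null envelope by
#' independently permuting each anchor's fusion-status labels across samples
#' `n_rand` times and recomputing the smoothed curve. The per-pair permuted
#' log2 folds are retained for [call_dysregulated_genes()], so one resampling
#' machinery underlies both the envelope and the per-pair p-values.
#'
#' @inheritParams neighbor_fold_changes
#' @param span Loess span (default 0.3).
#' @param n_rand Number of label randomizations (default 200; at least 100
#'   for a stable envelope).
#' @param seed Integer seed.
#' @param grid_n Number of grid points for the smoothed curve.
#' @param envelope Pointwise envelope quantiles.
#' @return A `regional_profile` object: `pairs` (per-pair tibble), `curve`
#'   (tibble `distance`, `observed`, `lo`, `hi`), plus the permuted per-pair
#'   null and parameters.
#' @export
aggregate_profile <- function(expression, windows, status, span = 0.3,
                              n_rand = 200, seed = 1L, min_positives = 3,
                              grid_n = 81, envelope = c(0.025, 0.975)) {
  if (n_rand < 1) abort("A randomization null is required (n_rand >= 1).")
  if (n_rand < 100) warn("Fewer than 100 randomizations: envelope unstable.")
  em <- expr_as_matrix(expression)
  w <- filter(windows, !is.na(.data$neighbor),
              .data$anchor %in% rownames(status),
              .data$neighbor %in% rownames(em))
  pl <- withr::with_seed(seed, pair_logfolds(em, w, status, min_positives,
                                             n_rand))
  if (length(pl$obs) < 50) {
    warn("Fewer than 50 (anchor, neighbor) pairs: profile unstable.")
  }
  # grid spans the observed distances (loess does not extrapolate)
  grid <- seq(min(pl$windows$distance), max(pl$windows$distance),
              length.out = grid_n)
  observed <- loess_curve(pl$windows$distance, pl$obs, grid, span)
  null_curves <- vapply(seq_len(n_rand), function(r) {
    loess_curve(pl$windows$distance, pl$null[, r], grid, span)
  }, numeric(grid_n))
  lo <- apply(null_curves, 1, quantile, envelope[1], na.rm = TRUE)
  hi <- apply(null_curves, 1, quantile, envelope[2], na.rm = TRUE)

  pairs <- pl$windows
  pairs$log2_fold <- as.numeric(pl$obs)
  pairs$fold <- 2^pairs$log2_fold   # pseudocount-adjusted ratio of means
  structure(
    list(pairs = pairs,
         curve = tibble(distance = grid, observed = observed, lo = lo, hi = hi),
         null_logfold = pl$null, n_rand = n_rand, seed = seed, span = span,
         envelope = envelope, min_positives = min_positives),
    class = "regional_profile"
  )
}

#' @export
print.regional_profile <- function(x, ...) {
  outside <- with(x$curve, mean(observed > hi | observed < lo, na.rm = TRUE))
  cat(sprintf(
    "<regional_profile> %d pairs / %d anchors; %d randomizations; %.0f%% of curve outside envelope\n",
    nrow(x$pairs), length(unique(x$pairs$anchor)), x$n_rand, 100 * outside))
  invisible(x)
}

#' Call dysregulated neighbor genes
#'
#' Per (anchor, neighbor) pair, the observed |log2 fold| is studentized by
#' that pair's own label-permutation standard deviation (genes differ widely
#' in fold-change dispersion, e.g. genes whose expression tracks molecular
#' subtype, so raw folds are not comparable across pairs), and the
#' studentized statistic is compared against the pooled permutation
#' distribution of studentized |log2 fold| across that anchor's neighbors —
#' the same label permutations computed by [aggregate_profile()]. Pooling
#' within the anchor gives the p-value resolution Benjamini-Hochberg needs
#' across thousands of pairs while keeping the null exchangeable (neighbors
#' share the status vector and have independent noise). Pairs with
#' `q <` threshold are reported grouped by neighbor gene.
#'
#' @param profile A `regional_profile` from [aggregate_profile()].
#' @param q_threshold BH q-value threshold (default 0.05).
#' @return List: `pairs` (all pairs with `p` and `q`), `called_pairs`
#'   (significant pairs), `genes` (tibble `neighbor`, `n_anchors`, `anchors`,
#'   `min_q`, deduplicated by neighbor).
#' @export
call_dysregulated_genes <- function(profile, q_threshold = 0.05) {
  if (is.null(profile$null_logfold) || profile$n_rand < 1) {
    abort("A randomization null is required; rerun aggregate_profile().")
  }
  pairs <- profile$pairs
  null_sd <- apply(profile$null_logfold, 1, stats::sd)
  null_sd[null_sd == 0] <- Inf              # degenerate pair: never called
  z_obs <- abs(pairs$log2_fold) / null_sd
  z_null <- abs(profile$null_logfold) / null_sd
  p <- numeric(nrow(pairs))
  for (a in unique(pairs$anchor)) {
    sel <- which(pairs$anchor == a)
    pooled <- as.numeric(z_null[sel, , drop = FALSE])
    for (i in sel) {
      p[i] <- empirical_p(z_obs[i], pooled, "upper")
    }
  }
  pairs$p <- p
  pairs$q <- p.adjust(p, method = "BH")
  called <- filter(pairs, .data$q < q_threshold)
  genes <- if (nrow(called) == 0) {
    tibble(neighbor = character(), n_anchors = integer(),
           anchors = character(), min_q = numeric())
  } else {
    called |>
      group_by(neighbor = .data$neighbor) |>
      summarise(n_anchors = dplyr::n_distinct(.data$anchor),
                anchors = paste(sort(unique(.data$anchor)), collapse = ","),
                min_q = min(.data$q), .groups = "drop") |>
      arrange(.data$min_q)
  }
  list(pairs = pairs, called_pairs = called, genes = genes)
}

#' Top-decile fold-change threshold
#'
#' The 90th percentile (linear interpolation) of all per-pair fold changes,
#' and the neighbor genes whose fold exceeds it — the export surface for
#' external pathway-enrichment tools.
#'
#' @param pairs Per-pair tibble with `fold` (and optionally `neighbor`).
#' @return List: `cutoff`, `genes` (neighbors strictly above the cutoff).
#' @export
top_decile_threshold <- function(pairs) {
  folds <- if (is.data.frame(pairs)) pairs$fold else pairs
  if (length(folds) < 10) abort("At least 10 pairs required.")
  cutoff <- unname(quantile(folds, 0.9, type = 7))
  genes <- if (is.data.frame(pairs) && "neighbor" %in% names(pairs)) {
    unique(pairs$neighbor[pairs$fold > cutoff])
  } else character(0)
  list(cutoff = cutoff, genes = genes)
}

#' Per-chromosome observed vs expected fusion breakpoint ratio
#'
#' Tabular counterpart of a genome-wide fusion-density track: observed
#' breakpoint counts per chromosome against the expectation proportional to
#' chromosome length.
#'
#' @param calls Fusion call tibble.
#' @param chrom_table Chromosome table.
#' @return Tibble: `chrom`, `observed`, `expected`, `ratio`.
#' @export
chromosome_fusion_summary <- function(calls, chrom_table) {
  obs <- count(tibble(chrom = c(calls$chrom5, calls$chrom3)), .data$chrom,
               name = "observed")
  chrom_table |>
    left_join(obs, by = "chrom") |>
    mutate(observed = tidyr::replace_na(.data$observed, 0L),
           expected = sum(.data$observed) * .data$length / sum(.data$length),
           ratio = .data$observed / .data$expected) |>
    select("chrom", "observed", "expected", "ratio")
}
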