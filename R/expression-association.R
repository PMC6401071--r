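#' Read an FPKM expression matrix
#'
#' Tab-separated, genes in rows, first column `gene`, remaining columns one
#' per sample.
#'
#' @param path Path to the TSV.
#' @return Tibble with a `gene` column and one numeric column per sample.
#' @export
read_fpkm_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(gene = "c", .default = "d"),
                       progress = FALSE)
  if (names(x)[1] != "gene") names(x)[1] <- "gene"
  if (anyDuplicated(x$gene)) abort("Duplicate gene ids in expression matrix.")
  if (any(purrr::map_lgl(x[-1], ~ any(.x < 0, na.rm = TRUE)))) {
    abort("Negative FPKM values.")
  }
  x
}

#' Read a GISTIC-style thresholded copy-number matrix
#'
#' @param path TSV with `gene` column and integer states in -2..2.
#' @return Tibble.
#' @export
read_gistic_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(gene = "c", .default = "d"),
                       progress = FALSE)
  if (names(x)[1] != "gene") names(x)[1] <- "gene"
  vals <- unlist(x[-1])
  if (!all(vals %in% -2:2)) abort("Copy-number states must be integers in -2..2.")
  x
}

# Internal: expression tibble -> numeric matrix (genes x samples).
expr_as_matrix <- function(expression) {
  m <- as.matrix(expression[-1])
  rownames(m) <- expression$gene
  m
}

#' Binary fusion-status indicator matrix
#'
#' Entry `[g, s]` is 1 iff sample `s` carries at least one (filtered) fusion
#' call with gene `g` as either partner. Calls whose samples are absent from
#' `samples` are ignored with a warning.
#'
#' @param calls Fusion call tibble.
#' @param samples Character vector of expression sample ids.
#' @param genes Character vector of gene ids (rows of the result).
#' @return Integer matrix `length(genes)` x `length(samples)`.
#' @export
fusion_status_matrix <- function(calls, samples, genes) {
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  long <- dplyr::bind_rows(
    tibble(sample = calls$sample, gene = calls$gene5),
    tibble(sample = calls$sample, gene = calls$gene3)
  )
  missing_s <- setdiff(unique(long$sample), samples)
  if (length(missing_s) > 0) {
    warn(sprintf("%d call sample(s) absent from expression matrix; ignored.",
                 length(missing_s)))
  }
  long <- filter(long, .data$sample %in% samples, .data$gene %in% genes)
  m[cbind(match(long$gene, genes), match(long$sample, samples))] <- 1L
  m
}

#' Per-gene fusion-status differential expression
#'
#' For each gene with at least `min_positives` fusion-positive samples,
#' compares FPKM between fusion-positive and fusion-negative samples with a
#' two-sided Wilcoxon rank-sum test (exact when both groups have <= 25
#' samples and no ties; normal approximation with tie correction otherwise),
#' then applies Benjamini-Hochberg FDR across the tested genes. Fold change
#' is the ratio of group means with pseudocount 0.01. Genes with identical
#' values in all samples get `p = 1` and are flagged `constant`.
#'
#' @param expression Expression tibble (`gene` + sample columns).
#' @param status Fusion-status matrix from [fusion_status_matrix()].
#' @param min_positives Minimum fusion-positive group size (default 3).
#' @return Tibble sorted by `q`: `gene`, `n_pos`, `n_neg`, `fold`, `p`, `q`,
#'   `constant`.
#' @export
fusion_expression_test <- function(expression, status, min_positives = 3) {
  if (min_positives < 2) abort("min_positives must be >= 2.")
  em <- expr_as_matrix(expression)
  common <- intersect(rownames(em), rownames(status))
  samples <- intersect(colnames(em), colnames(status))
  em <- em[common, samples, drop = FALSE]
  st <- status[common, samples, drop = FALSE] > 0

  n_pos <- rowSums(st)
  test_genes <- common[n_pos >= min_positives & n_pos <= length(samples) - 2]
  rows <- purrr::map(test_genes, function(gn) {
    x <- em[gn, ]
    pos <- x[st[gn, ]]
    neg <- x[!st[gn, ]]
    constant <- length(unique(x)) == 1
    p <- if (constant) 1 else {
      exact <- length(pos) <= 25 && length(neg) <= 25 && !any(duplicated(x))
      suppressWarnings(
        wilcox.test(pos, neg, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value
      )
    }
    tibble(gene = gn, n_pos = length(pos), n_neg = length(neg),
           fold = fold_change(pos, neg), p = p, constant = constant)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gene = character(), n_pos = integer(), n_neg = integer(),
                  fold = numeric(), p = numeric(), q = numeric(),
                  constant = logical()))
  }
  out$q <- p.adjust(out$p, method = "BH")
  arrange(out, .data$q, .data$p, .data$gene) |>
    select("gene", "n_pos", "n_neg", "fold", "p", "q", "constant")
}

#' Enrichment of fusion genes among highly expressed ('active') genes
#'
#' Given a reference ranking of the expression universe (most expressed
#' first), tests whether fusion-involved genes are over-represented among the
#' top `n` 'active' genes with a cumulative hypergeometric test
#' `P(X >= k)`, for each `n` in `top_n`.
#'
#' @param fusion_genes Character vector of genes involved in fusions.
#' @param ranking Character vector: the universe, ranked by expression
#'   (descending).
#' @param top_n Integer vector of active-set sizes.
#' @return Tibble: `top_n`, `k` (overlap), `m` (fusion genes in universe),
#'   `p_value`.
#' @export
active_gene_enrichment <- function(fusion_genes, ranking,
                                   top_n = c(200, 500, 1000, 2000)) {
  outside <- setdiff(fusion_genes, ranking)
  if (length(outside) > 0) {
    warn(sprintf("%d fusion gene(s) outside the ranking universe; excluded.",
                 length(outside)))
    fusion_genes <- intersect(fusion_genes, ranking)
  }
  fusion_genes <- unique(fusion_genes)
  top_n <- top_n[top_n <= length(ranking)]
  if (length(top_n) == 0) abort("No top_n value within the universe size.")
  N <- length(ranking); m <- length(fusion_genes)
  purrr::map(top_n, function(n) {
    k <- length(intersect(fusion_genes, head(ranking, n)))
    tibble(top_n = n, k = k, m = m,
           p_value = phyper(k - 1, n, N - n, m, lower.tail = FALSE))
  }) |> dplyr::bind_rows()
}

#' Association between fusion status and copy-number states
#'
#' Compares the GISTIC state distribution over fused (gene, sample) pairs
#' with the background distribution, by resampling equally many random
#' (gene, sample) pairs `n_perm` times. Per-state two-sided empirical
#' p-values with add-one correction.
#'
#' @param calls Fusion call tibble.
#' @param copy_number Copy-number tibble (`gene` + sample columns).
#' @param n_perm Number of resamples (default 1e4).
#' @param seed Integer seed.
#' @return `enrichment_result` tibble: one row per state, with observed and
#'   null proportions, fold enrichment and permutation p.
#' @export
copy_number_association <- function(calls, copy_number, n_perm = 1e4,
                                    seed = 1L) {
  cm <- expr_as_matrix(copy_number)
  long <- dplyr::bind_rows(
    tibble(sample = calls$sample, gene = calls$gene5),
    tibble(sample = calls$sample, gene = calls$gene3)
  ) |>
    filter(.data$gene %in% rownames(cm), .data$sample %in% colnames(cm)) |>
    distinct()
  if (nrow(long) == 0) abort("No fused (gene, sample) pairs overlap the matrix.")
  obs_states <- cm[cbind(match(long$gene, rownames(cm)),
                         match(long$sample, colnames(cm)))]
  k <- length(obs_states)
  states <- -2:2
  obs_prop <- purrr::map_dbl(states, ~ mean(obs_states == .x))

  null_prop <- withr::with_seed(seed, {
    draws <- matrix(sample(cm, k * n_perm, replace = TRUE), nrow = k)
    vapply(states, function(s) colMeans(draws == s), numeric(n_perm))
  })

  res <- purrr::map(seq_along(states), function(i) {
    new_enrichment_result(
      observed = obs_prop[i], null_mean = mean(null_prop[, i]),
      p_value = empirical_p(obs_prop[i], null_prop[, i], "two.sided"),
      n_perm = n_perm, seed = seed,
      statistic = sprintf("cn_state_%+d", states[i]),
      extra = list(state = states[i], n_pairs = k)
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("enrichment_result", class(out))
  out
}
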