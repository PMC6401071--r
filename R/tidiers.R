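#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' `enrichment_result` tibbles are already one-row-per-statistic; `tidy()`
#' returns them with the standard column subset and `glance()` a one-row
#' summary of the most significant statistic.
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(x)[, c("statistic", "observed", "null_mean", "fold_enrichment",
                   "p_value", "n_perm")]
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  i <- which.min(x$p_value)
  tibble(n_statistics = nrow(x), min_p = x$p_value[i],
         top_statistic = x$statistic[i], n_perm = x$n_perm[i])
}

#' Tidy a burden summary
#' @param x A `burden_summary`.
#' @param ... Unused.
#' @return `tidy()`: per-sample counts; `glance()`: cohort quartiles.
#' @export
tidy.burden_summary <- function(x, ...) x$per_sample

#' @rdname tidy.burden_summary
#' @export
glance.burden_summary <- function(x, ...) {
  tibble(n_samples = nrow(x$per_sample), median = x$median, q25 = x$q25,
         q75 = x$q75, min = x$min, max = x$max)
}

#' Tidy a regional profile
#' @param x A `regional_profile`.
#' @param ... Unused.
#' @return `tidy()`: the per-pair tibble; `glance()`: pair/anchor counts and
#'   the fraction of the smoothed curve outside the null envelope.
#' @export
tidy.regional_profile <- function(x, ...) as_tibble(x$pairs)

#' @rdname tidy.regional_profile
#' @export
glance.regional_profile <- function(x, ...) {
  outside <- mean(x$curve$observed > x$curve$hi |
                    x$curve$observed < x$curve$lo, na.rm = TRUE)
  tibble(n_pairs = nrow(x$pairs),
         n_anchors = dplyr::n_distinct(x$pairs$anchor),
         n_rand = x$n_rand, span = x$span, frac_outside_envelope = outside)
}

#' Tidy subtype scores
#' @param x A `subtype_scores` tibble.
#' @param ... Unused.
#' @return `tidy()`: long tibble of normalized scores; `glance()`: subtype
#'   counts.
#' @export
tidy.subtype_scores <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("norm_"),
                        names_to = "signature", values_to = "normalized_score",
                        names_prefix = "norm_") |>
    select("sample", "signature", "normalized_score", "subtype")
}

#' @rdname tidy.subtype_scores
#' @export
glance.subtype_scores <- function(x, ...) {
  count(as_tibble(x), .data$subtype, name = "n_samples") |>
    tidyr::pivot_wider(names_from = "subtype", values_from = "n_samples")
}
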