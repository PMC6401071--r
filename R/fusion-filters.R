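defuse_required_cols <- c("sample", "gene5", "gene3", "chrom5", "pos5",
                          "strand5", "chrom3", "pos3", "strand3", "probability")

#' Read a defuse-style fusion call table
#'
#' Tab-separated, one predicted fusion per row. Mandatory columns: `sample`,
#' `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`, `strand3`,
#' `probability`. Optional: `transcript5`, `transcript3`, `cdna5`, `cdna3`,
#' and the flags `adjacent`, `read_through`, `interchromosomal` (recomputed
#' from coordinates when absent; `interchromosomal` always reconciled with
#' `chrom5 != chrom3`). Rows with probabilities outside `[0, 1]` or missing
#' coordinates are rejected with a line-numbered warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble of fusion calls.
#' @export
read_defuse_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing <- setdiff(defuse_required_cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- mutate(x,
              .line = row_number() + 1L,   # header is line 1
              pos5 = suppressWarnings(as.numeric(.data$pos5)),
              pos3 = suppressWarnings(as.numeric(.data$pos3)),
              probability = suppressWarnings(as.numeric(.data$probability)))
  for (opt in c("cdna5", "cdna3")) {
    if (opt %in% names(x)) x[[opt]] <- suppressWarnings(as.numeric(x[[opt]]))
  }
  bad <- is.na(x$probability) | x$probability < 0 | x$probability > 1 |
    is.na(x$pos5) | is.na(x$pos3) |
    is.na(x$sample) | is.na(x$gene5) | is.na(x$gene3)
  if (any(bad)) {
    warn(sprintf("Rejected %d malformed row(s) at line(s): %s",
                 sum(bad), paste(head(x$.line[bad], 10), collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  x$interchromosomal <- x$chrom5 != x$chrom3
  for (flag in c("adjacent", "read_through")) {
    if (flag %in% names(x)) {
      x[[flag]] <- as.logical(x[[flag]])
    }
  }
  select(x, -".line")
}

#' Write a fusion call table
#' @param calls Fusion call tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_defuse_table <- function(calls, path) {
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Filter fusion calls by classifier probability
#'
#' Retains calls with `probability >= threshold` (inclusive). The default
#' 0.81 is the classifier operating point established for ovarian samples.
#'
#' @param calls Fusion call tibble.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return Filtered tibble.
#' @export
filter_by_probability <- function(calls, threshold = 0.81) {
  assert_scalar_prob(threshold, "threshold")
  filter(calls, .data$probability >= threshold)
}

#' Subtract a panel of normals
#'
#' Removes any tumor call whose partner pair also occurs in the normal-sample
#' predictions; such recurrent events are treated as systematic false
#' positives. `match = "pair"` (default) matches unordered gene-symbol pairs;
#' `match = "breakpoint"` additionally requires both genomic breakpoints to
#' coincide.
#'
#' @param calls Tumor fusion call tibble.
#' @param normals Normal-sample fusion call tibble.
#' @param match `"pair"` or `"breakpoint"`.
#' @return Filtered tumor calls.
#' @export
subtract_panel_of_normals <- function(calls, normals,
                                      match = c("pair", "breakpoint")) {
  match <- match.arg(match)
  if (nrow(normals) == 0) return(calls)
  key <- function(d) {
    pair <- paste(pmin(d$gene5, d$gene3), pmax(d$gene5, d$gene3), sep = "|")
    if (match == "pair") return(pair)
    swap <- d$gene5 > d$gene3
    paste(pair, ifelse(swap, d$pos3, d$pos5), ifelse(swap, d$pos5, d$pos3))
  }
  filter(calls, !(key(calls) %in% key(normals)))
}

#' Per-sample fusion burden summary
#'
#' Counts filtered calls per sample and summarizes the cohort: median,
#' interquartile range (linear interpolation), minimum and maximum.
#'
#' @param calls Fusion call tibble with a `sample` column.
#' @return A `burden_summary` list: `per_sample` tibble (`sample`, `n`) and
#'   scalars `median`, `q25`, `q75`, `min`, `max`.
#' @export
burden_summary <- function(calls) {
  if (nrow(calls) == 0) abort("Empty call set.")
  per_sample <- count(calls, .data$sample, name = "n")
  q <- quantile(per_sample$n, c(0.25, 0.5, 0.75), type = 7)
  structure(
    list(per_sample = per_sample,
         median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]),
         min = min(per_sample$n), max = max(per_sample$n)),
    class = "burden_summary"
  )
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf(
    "<burden_summary> %d samples; median %.4g (IQR %.4g-%.4g, range %g-%g)\n",
    nrow(x$per_sample), x$median, x$q25, x$q75, x$min, x$max))
  invisible(x)
}

#' Classify fusion calls by rearrangement geometry
#'
#' Fractions of calls that are interchromosomal vs intrachromosomal, adjacent
#' (no third gene between the partners' spans) and read-through (adjacent,
#' same strand, with the 5' partner upstream of the 3' partner in the
#' direction of transcription). Calls with partner genes that cannot be
#' resolved in the annotation are counted as `unknown`.
#'
#' @param calls Fusion call tibble.
#' @param annotation A `fusion_annotation`.
#' @return Tibble: `class`, `count`, `fraction`, with `partition` marking the
#'   chromosomal partition vs adjacency classes.
#' @export
classify_rearrangements <- function(calls, annotation) {
  g <- annotation$genes
  i5 <- match(calls$gene5, g$gene)
  i3 <- match(calls$gene3, g$gene)
  unknown <- is.na(i5) | is.na(i3)
  if (any(unknown)) {
    inform(sprintf("%d call(s) with unresolvable partner genes counted as unknown.",
                   sum(unknown)))
  }
  inter <- calls$chrom5 != calls$chrom3

  # adjacency, vectorized over resolvable same-chromosome pairs
  adj <- rep(FALSE, nrow(calls))
  res <- which(!unknown & !inter)
  if (length(res) > 0) {
    adj[res] <- purrr::map_lgl(res, function(k) {
      are_adjacent(annotation, calls$gene5[k], calls$gene3[k])
    })
  }
  same_strand <- !unknown & g$strand[i5] == g$strand[i3]
  upstream <- !unknown & ifelse(g$strand[i5] == "+",
                                g$start[i5] < g$start[i3],
                                g$start[i5] > g$start[i3])
  read_through <- adj & same_strand & upstream

  n <- nrow(calls)
  out <- dplyr::bind_rows(
    tibble(partition = "chromosomal",
           class = c("intrachromosomal", "interchromosomal", "unknown"),
           count = c(sum(!inter & !unknown), sum(inter & !unknown), sum(unknown))),
    tibble(partition = "adjacency",
           class = c("adjacent", "read_through", "non_adjacent", "unknown"),
           count = c(sum(adj), sum(read_through), sum(!adj & !unknown),
                     sum(unknown)))
  ) |>
    group_by(.data$partition) |>
    mutate(fraction = .data$count /
             sum(.data$count[.data$class != "read_through"])) |>
    ungroup()
  out
}
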