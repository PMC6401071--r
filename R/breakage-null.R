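#' Expected intrachromosomal fraction under uniform breakage and repair
#'
#' The fusion-generation null models a rearrangement as two breakpoints drawn
#' independently and uniformly over the whole genomic space, then rejoined.
#' The probability that both fall on the same chromosome is
#' \eqn{\sum_i L_i^2 / (\sum_i L_i)^2}. `method = "simulation"` estimates the
#' same quantity by drawing `n_perm` literal breakpoint pairs.
#'
#' @param chrom_table Chromosome table tibble (`chrom`, `length`).
#' @param method `"analytic"` (closed form, default) or `"simulation"`.
#' @param n_perm Number of simulated pairs for `method = "simulation"`.
#' @param seed Integer seed for the simulation.
#' @return A single number in (0, 1].
#' @export
#' @examples
#' expected_intrachromosomal_fraction(hg19_chromosomes()) # ~= 0.0497
expected_intrachromosomal_fraction <- function(chrom_table,
                                               method = c("analytic", "simulation"),
                                               n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (nrow(chrom_table) == 0) abort("Empty chromosome table.")
  L <- chrom_table$length
  if (method == "analytic") {
    return(sum(L^2) / sum(L)^2)
  }
  withr::with_seed(seed, {
    cum <- cumsum(L)
    draw_chrom <- function(n) findInterval(runif(n, 0, sum(L)), cum) + 1L
    mean(draw_chrom(n_perm) == draw_chrom(n_perm))
  })
}

new_enrichment_result <- function(observed, null_mean, p_value, n_perm, seed,
                                  statistic = "statistic", extra = list()) {
  out <- tibble(
    statistic = statistic,
    observed = observed,
    null_mean = null_mean,
    fold_enrichment = observed / null_mean,
    p_value = p_value,
    n_perm = n_perm,
    seed = seed
  )
  if (length(extra) > 0) out <- dplyr::bind_cols(out, as_tibble(extra))
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Permutation test for intrachromosomal fusion enrichment
#'
#' Compares the observed fraction of same-chromosome fusion calls with the
#' uniform breakage-and-repair null. Under that null the same-chromosome count
#' among `n` independent breakpoint pairs is exactly Binomial(`n`, `p`) with
#' `p` the closed-form expected fraction, so each permutation's null fraction
#' is drawn from that distribution. The p-value carries the add-one
#' correction: `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param calls Fusion call tibble with `chrom5`, `chrom3` columns.
#' @param chrom_table Chromosome table.
#' @param n_perm Number of permutations (default 1e5, matching a reportable
#'   floor of 1e-5).
#' @param seed Integer seed.
#' @return An `enrichment_result` tibble (observed fraction, null mean, fold
#'   enrichment, permutation p, `n_perm`, `seed`).
#' @export
intrachromosomal_enrichment <- function(calls, chrom_table, n_perm = 1e5,
                                        seed = 1L) {
  if (nrow(calls) == 0) abort("No fusion calls.")
  if (n_perm < 1000) warn("Fewer than 1,000 permutations: p-values unreliable.")
  observed <- mean(calls$chrom5 == calls$chrom3)
  p0 <- expected_intrachromosomal_fraction(chrom_table)
  n <- nrow(calls)
  null_frac <- withr::with_seed(seed, rbinom(n_perm, n, p0) / n)
  new_enrichment_result(
    observed = observed, null_mean = mean(null_frac),
    p_value = empirical_p(observed, null_frac, "upper"),
    n_perm = n_perm, seed = seed, statistic = "intrachromosomal_fraction"
  )
}

# ---------------------------------------------------------------------------
# Per-transcript breakage masses
#
# For a breakpoint uniform over a transcript's genomic span, every exonic base
# maps to one cDNA base and every intronic base projects to its donor-side
# junction. The induced cDNA region distribution is therefore exact interval
# arithmetic: exonic mass per region equals the region's cDNA length, and each
# intron contributes its full genomic length at one junction position.
# ---------------------------------------------------------------------------
breakage_masses <- function(annotation, transcript_ids = NULL) {
  tx <- annotation$transcripts |> filter(.data$coding)
  if (!is.null(transcript_ids)) {
    tx <- filter(tx, .data$transcript_id %in% transcript_ids)
  }
  if (nrow(tx) == 0) abort("No coding transcripts in annotation.")
  ex <- semi_join(annotation$exons, tx, by = "transcript_id") |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(cum = cumsum(.data$end - .data$start),
           total = sum(.data$end - .data$start)) |>
    ungroup()

  introns <- ex |>
    group_by(.data$transcript_id) |>
    mutate(ilen = .data$start - dplyr::lag(.data$end),
           cum_before = dplyr::lag(.data$cum)) |>
    ungroup() |>
    filter(!is.na(.data$ilen), .data$ilen > 0) |>
    select("transcript_id", "ilen", "cum_before", "cum", "total") |>
    left_join(select(tx, "transcript_id", "strand", "utr5_length",
                     "cds_length", "cdna_length"),
              by = "transcript_id") |>
    mutate(
      donor_cdna = ifelse(.data$strand == "+", .data$cum_before - 1,
                          .data$total - .data$cum_before - 1),
      region = ifelse(.data$donor_cdna < .data$utr5_length, "UTR5",
                      ifelse(.data$donor_cdna < .data$utr5_length + .data$cds_length,
                             "CDS", "UTR3")),
      rel_cds = ifelse(.data$region == "CDS",
                       (.data$donor_cdna - .data$utr5_length) / .data$cds_length,
                       NA_real_)
    ) |>
    select("transcript_id", "ilen", "donor_cdna", "region", "rel_cds")

  intron_reg <- introns |>
    group_by(.data$transcript_id, .data$region) |>
    summarise(mass = sum(.data$ilen), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "mass",
                       values_fill = 0)
  for (r in c("UTR5", "CDS", "UTR3")) {
    if (!r %in% names(intron_reg)) intron_reg[[r]] <- 0
  }

  m <- tx |>
    select("transcript_id", "gene", "utr5_length", "cds_length", "utr3_length",
           "cdna_length", "tx_start", "tx_end") |>
    left_join(intron_reg, by = "transcript_id") |>
    mutate(across(c("UTR5", "CDS", "UTR3"), ~ tidyr::replace_na(.x, 0)),
           span = .data$tx_end - .data$tx_start,
           mass_utr5 = .data$utr5_length + .data$UTR5,
           mass_cds = .data$cds_length + .data$CDS,
           mass_utr3 = .data$utr3_length + .data$UTR3) |>
    select("transcript_id", "gene", "span", "utr5_length", "cds_length",
           "utr3_length", "mass_utr5", "mass_cds", "mass_utr3")
  stopifnot(all(abs(m$mass_utr5 + m$mass_cds + m$mass_utr3 - m$span) < 1e-6))
  list(masses = m,
       cds_introns = filter(introns, .data$region == "CDS") |>
         select("transcript_id", "ilen", "rel_cds"))
}

#' Expected cDNA breakpoint distribution under random genomic breakage
#'
#' For breakpoints uniform over transcript genomic spans (transcript chosen
#' uniformly from `transcript_ids`, then a base uniform within its span,
#' intron mass projecting onto donor junctions), returns the expected
#' proportions over 5'UTR / CDS / 3'UTR and the expected binned density of
#' relative CDS position. Computed by exact interval arithmetic;
#' `method = "simulation"` draws literal breakpoints instead.
#'
#' @param annotation A `fusion_annotation`.
#' @param transcript_ids Optional transcript subset (e.g. the fused
#'   transcripts); default all coding transcripts.
#' @param n_bins Number of bins for the relative-CDS-position density.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_perm Breakpoints to draw when simulating.
#' @param seed Seed for simulation.
#' @return List with `regions` (tibble: region, proportion), `cds_density`
#'   (tibble: bin midpoint, density over `[0,1)`), and the per-transcript
#'   `masses` used as the null.
#' @export
expected_region_distribution <- function(annotation, transcript_ids = NULL,
                                         n_bins = 20,
                                         method = c("analytic", "simulation"),
                                         n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  bm <- breakage_masses(annotation, transcript_ids)
  m <- bm$masses
  if (method == "analytic") {
    probs <- cbind(m$mass_utr5, m$mass_cds, m$mass_utr3) / m$span
    regions <- tibble(
      region = c("UTR5", "CDS", "UTR3"),
      proportion = colMeans(probs)
    )
    # relative-CDS density, conditional on landing in the CDS
    cds_w <- m$mass_cds / m$span
    uniform_w <- (m$cds_length / m$span) / sum(cds_w)   # spread over [0,1)
    breaks <- seq(0, 1, length.out = n_bins + 1)
    dens <- rep(sum(uniform_w), n_bins) / n_bins
    if (nrow(bm$cds_introns) > 0) {
      ci <- bm$cds_introns |>
        left_join(select(m, "transcript_id", "span"), by = "transcript_id") |>
        mutate(w = (.data$ilen / .data$span) / sum(cds_w))
      bin <- pmin(findInterval(ci$rel_cds, breaks), n_bins)
      for (i in seq_along(bin)) dens[bin[i]] <- dens[bin[i]] + ci$w[i]
    }
    dens <- dens / sum(dens) * n_bins            # density scale on [0,1)
    cds_density <- tibble(mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                          density = dens)
  } else {
    draws <- withr::with_seed(seed, {
      ids <- m$transcript_id[sample.int(nrow(m), n_perm, replace = TRUE)]
      tx <- annotation$transcripts
      i <- match(ids, tx$transcript_id)
      pos <- floor(runif(n_perm, tx$tx_start[i], tx$tx_end[i]))
      cd <- genomic_to_cdna(annotation, ids, pos)
      cd$region <- classify_cdna_region(annotation, ids, cd$cdna)
      cd
    })
    regions <- tibble(region = c("UTR5", "CDS", "UTR3")) |>
      left_join(count(draws, region = .data$region), by = "region") |>
      mutate(proportion = tidyr::replace_na(.data$n, 0L) / nrow(draws)) |>
      select("region", "proportion")
    in_cds <- draws$region == "CDS"
    rel <- relative_cds_position(annotation, draws$transcript_id[in_cds],
                                 draws$cdna[in_cds])
    h <- graphics::hist(rel, breaks = seq(0, 1, length.out = n_bins + 1),
                        plot = FALSE)
    cds_density <- tibble(mid = h$mids, density = h$density)
  }
  list(regions = regions, cds_density = cds_density, masses = m,
       cds_introns = bm$cds_introns)
}

# Draw n relative CDS positions from the expected (null) distribution.
sample_expected_cds_positions <- function(expected, n, seed = 1L) {
  m <- expected$masses
  withr::with_seed(seed, {
    w_tx <- m$mass_cds / m$span                  # transcript picked uniformly,
    pick <- sample.int(nrow(m), n, replace = TRUE, prob = w_tx)  # then | CDS
    out <- numeric(n)
    for (k in seq_len(n)) {
      i <- pick[k]
      ci <- expected$cds_introns[expected$cds_introns$transcript_id ==
                                   m$transcript_id[i], ]
      tot <- m$mass_cds[i]
      if (nrow(ci) > 0 && runif(1) < sum(ci$ilen) / tot) {
        out[k] <- sample(ci$rel_cds, 1, prob = ci$ilen)
      } else {
        out[k] <- runif(1)
      }
    }
    out
  })
}

#' Observed breakpoint region profile
#'
#' Counts and proportions of fusion breakpoints over 5'UTR / CDS / 3'UTR,
#' split by partner end (the 5' partner's breakpoint ends its transcript
#' contribution; the 3' partner's starts it).
#'
#' @param calls Fusion call tibble with `transcript5`, `transcript3`, `cdna5`,
#'   `cdna3` (recomputed from genomic positions when absent).
#' @param annotation A `fusion_annotation`.
#' @return A `region_profile` tibble: `end`, `region`, `count`, `proportion`.
#' @export
region_profile <- function(calls, annotation) {
  calls <- resolve_cdna(calls, annotation)
  long <- dplyr::bind_rows(
    tibble(end = "5p", transcript_id = calls$transcript5, cdna = calls$cdna5),
    tibble(end = "3p", transcript_id = calls$transcript3, cdna = calls$cdna3)
  ) |>
    filter(!is.na(.data$cdna))
  coding <- annotation$transcripts$transcript_id[annotation$transcripts$coding]
  dropped <- sum(!long$transcript_id %in% coding)
  if (dropped > 0) {
    inform(sprintf("%d breakpoint(s) on non-coding/unknown transcripts excluded.",
                   dropped))
    long <- filter(long, .data$transcript_id %in% coding)
  }
  long$region <- classify_cdna_region(annotation, long$transcript_id, long$cdna)
  out <- tidyr::expand_grid(end = c("5p", "3p"),
                            region = c("UTR5", "CDS", "UTR3")) |>
    left_join(count(long, .data$end, .data$region), by = c("end", "region")) |>
    mutate(count = tidyr::replace_na(.data$n, 0L)) |>
    select(-"n") |>
    group_by(.data$end) |>
    mutate(proportion = .data$count / sum(.data$count)) |>
    ungroup()
  class(out) <- c("region_profile", class(out))
  out
}

# Ensure calls carry transcript ids and cDNA breakpoint positions; recompute
# from genomic coordinates where absent. Calls whose breakpoints cannot be
# resolved keep NA cdna.
resolve_cdna <- function(calls, annotation) {
  g <- annotation$genes
  for (side in c("5", "3")) {
    tcol <- paste0("transcript", side)
    ccol <- paste0("cdna", side)
    gcol <- paste0("gene", side)
    pcol <- paste0("pos", side)
    if (!tcol %in% names(calls) || any(is.na(calls[[tcol]]))) {
      calls[[tcol]] <- g$transcript_id[match(calls[[gcol]], g$gene)]
    }
    if (!ccol %in% names(calls)) calls[[ccol]] <- NA_real_
    need <- which(is.na(calls[[ccol]]) & !is.na(calls[[tcol]]))
    if (length(need) > 0) {
      tx <- annotation$transcripts
      i <- match(calls[[tcol]][need], tx$transcript_id)
      inside <- !is.na(i) & calls[[pcol]][need] >= tx$tx_start[i] &
        calls[[pcol]][need] < tx$tx_end[i]
      ok <- need[inside]
      if (length(ok) > 0) {
        calls[[ccol]][ok] <- genomic_to_cdna(
          annotation, calls[[tcol]][ok], calls[[pcol]][ok])$cdna
      }
    }
  }
  calls
}

#' Permutation test for breakpoint region enrichment
#'
#' Tests whether observed breakpoints are enriched or depleted in each of
#' 5'UTR / CDS / 3'UTR relative to random genomic breakage. The null redraws
#' each breakpoint uniformly over its own transcript's genomic span
#' (conditioning on the observed transcripts isolates positional bias from
#' gene-selection bias); per permutation the redraw samples each transcript's
#' exact induced region distribution. Two-sided empirical p-values with
#' add-one correction, so both enrichment and depletion are detectable.
#'
#' @inheritParams region_profile
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @return An `enrichment_result` tibble with one row per region.
#' @export
region_enrichment_test <- function(calls, annotation, n_perm = 1e4, seed = 1L) {
  if (n_perm < 1000) warn("Fewer than 1,000 permutations: p-values unreliable.")
  calls <- resolve_cdna(calls, annotation)
  long <- dplyr::bind_rows(
    tibble(transcript_id = calls$transcript5, cdna = calls$cdna5),
    tibble(transcript_id = calls$transcript3, cdna = calls$cdna3)
  )
  coding <- annotation$transcripts$transcript_id[annotation$transcripts$coding]
  excluded <- sum(is.na(long$cdna) | !long$transcript_id %in% coding)
  long <- filter(long, !is.na(.data$cdna), .data$transcript_id %in% coding)
  if (nrow(long) == 0) abort("No resolvable breakpoints.")
  long$region <- classify_cdna_region(annotation, long$transcript_id, long$cdna)
  obs <- c(UTR5 = sum(long$region == "UTR5"), CDS = sum(long$region == "CDS"),
           UTR3 = sum(long$region == "UTR3"))

  bm <- breakage_masses(annotation, unique(long$transcript_id))$masses
  i <- match(long$transcript_id, bm$transcript_id)
  p1 <- bm$mass_utr5[i] / bm$span[i]
  p2 <- p1 + bm$mass_cds[i] / bm$span[i]
  nb <- nrow(long)
  null_counts <- withr::with_seed(seed, {
    u <- matrix(runif(nb * n_perm), nrow = nb)
    u5 <- colSums(u < p1)
    cds <- colSums(u >= p1 & u < p2)
    cbind(UTR5 = u5, CDS = cds, UTR3 = nb - u5 - cds)
  })

  res <- purrr::map(c("UTR5", "CDS", "UTR3"), function(r) {
    new_enrichment_result(
      observed = unname(obs[r]), null_mean = mean(null_counts[, r]),
      p_value = empirical_p(obs[r], null_counts[, r], "two.sided"),
      n_perm = n_perm, seed = seed, statistic = paste0("breakpoints_", r),
      extra = list(region = r, n_breakpoints = nb, n_excluded = excluded)
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Positional bias within coding sequences (two-sample KS)
#'
#' Compares observed relative CDS breakpoint positions against the random
#' breakage expectation, separately for the N-terminal (`[0, 0.5)`) and
#' C-terminal (`[0.5, 1)`) halves, using a two-sample Kolmogorov-Smirnov test
#' against a large sample drawn from the expected distribution.
#'
#' @inheritParams region_profile
#' @param expected Output of [expected_region_distribution()] (computed from
#'   the fused transcripts when omitted).
#' @param expected_mult Expected-sample size multiplier (default 10x observed).
#' @param seed Seed for the expected-distribution draw.
#' @return Tibble with rows `overall`, `N-terminal`, `C-terminal`: `n_obs`,
#'   KS `statistic`, `p_value`.
#' @export
cds_positional_test <- function(calls, annotation, expected = NULL,
                                expected_mult = 10, seed = 1L) {
  calls <- resolve_cdna(calls, annotation)
  long <- dplyr::bind_rows(
    tibble(transcript_id = calls$transcript5, cdna = calls$cdna5),
    tibble(transcript_id = calls$transcript3, cdna = calls$cdna3)
  )
  coding <- annotation$transcripts$transcript_id[annotation$transcripts$coding]
  long <- filter(long, !is.na(.data$cdna), .data$transcript_id %in% coding)
  long$region <- classify_cdna_region(annotation, long$transcript_id, long$cdna)
  long <- filter(long, .data$region == "CDS")
  if (nrow(long) == 0) abort("No CDS-resident breakpoints.")
  if (nrow(long) < 8) warn("Fewer than 8 CDS breakpoints: KS test underpowered.")
  obs <- relative_cds_position(annotation, long$transcript_id, long$cdna)
  if (is.null(expected)) {
    expected <- expected_region_distribution(annotation,
                                             unique(long$transcript_id))
  }
  exp_sample <- sample_expected_cds_positions(expected,
                                              max(100, expected_mult * length(obs)),
                                              seed = seed)
  ks_row <- function(label, o, e) {
    if (length(o) == 0 || length(e) == 0) {
      return(tibble(half = label, n_obs = length(o), statistic = NA_real_,
                    p_value = NA_real_))
    }
    k <- suppressWarnings(ks.test(o, e))
    tibble(half = label, n_obs = length(o),
           statistic = unname(k$statistic), p_value = k$p.value)
  }
  dplyr::bind_rows(
    ks_row("overall", obs, exp_sample),
    ks_row("N-terminal", obs[obs < 0.5], exp_sample[exp_sample < 0.5]),
    ks_row("C-terminal", obs[obs >= 0.5], exp_sample[exp_sample >= 0.5])
  )
}

#' Compare two breakpoint region profiles
#'
#' Chi-square homogeneity tests between two cohorts' region count profiles:
#' a k-sample test over the full region-by-cohort contingency table and a
#' 2-sample test (designated region vs the rest, 2x2 with continuity
#' correction).
#'
#' @param profile_a,profile_b `region_profile` tibbles carrying raw counts.
#' @param region Region for the 2-sample test (default `"CDS"`).
#' @return Tibble with rows `k_sample` and `two_sample`: `statistic`, `df`,
#'   `p_value`.
#' @export
compare_region_profiles <- function(profile_a, profile_b, region = "CDS") {
  for (p in list(profile_a, profile_b)) {
    if (!"count" %in% names(p)) abort("Profiles must carry raw counts.")
  }
  ca <- profile_a |> group_by(.data$region) |>
    summarise(count = sum(.data$count), .groups = "drop")
  cb <- profile_b |> group_by(.data$region) |>
    summarise(count = sum(.data$count), .groups = "drop")
  tab <- ca |> rename(a = "count") |>
    inner_join(rename(cb, b = "count"), by = "region")
  m <- as.matrix(tab[, c("a", "b")])
  if (any(suppressWarnings(chisq.test(m))$expected < 5)) {
    warn("Expected cell count < 5: consider an exact test.")
  }
  k <- suppressWarnings(chisq.test(m, correct = FALSE))
  m2 <- rbind(m[tab$region == region, ], colSums(m[tab$region != region, , drop = FALSE]))
  t2 <- suppressWarnings(chisq.test(m2, correct = TRUE))
  tibble(
    test = c("k_sample", "two_sample"),
    region = c(NA_character_, region),
    statistic = c(unname(k$statistic), unname(t2$statistic)),
    df = c(unname(k$parameter), unname(t2$parameter)),
    p_value = c(k$p.value, t2$p.value)
  )
}
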