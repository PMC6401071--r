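#' Configuration for a synthetic fusion cohort
#'
#' Defines every distributional knob of the generator. Defaults emulate the
#' statistical structure of a high-grade serous ovarian cohort: per-tumor
#' fusion burden negative binomial with quartiles (14, 21, 30), 70%
#' intrachromosomal fusions, a scaled 24-chromosome genome with hg19-
#' proportional lengths, 5'-heavy intron sizes (early introns longer), and
#' log-normal FPKM with multiplicative noise. Planted effects (fusion-
#' upregulated genes, regional anchors with linear decay, subtype signature
#' activation) are recorded in the truth manifest.
#'
#' @param seed Integer; fully determines all generated outputs.
#' @param n_tumors,n_normals Sample counts.
#' @param n_chromosomes Number of chromosomes (default 24).
#' @param chrom_lengths Optional numeric vector of lengths; default hg19/10.
#' @param genes_per_chrom Genes placed on each chromosome.
#' @param intergenic_mean Mean intergenic gap (bp, exponential).
#' @param exon_count_range Integer range of exons per gene.
#' @param exon_meanlog,exon_sdlog Log-normal exon length parameters.
#' @param intron_meanlog First-intron log-mean; later introns shrink by
#'   `intron_decay` per position (transcript order), giving the 5'-heavy
#'   intron profile.
#' @param intron_sdlog,intron_decay See above.
#' @param expr_meanlog,expr_sdlog Baseline per-gene FPKM log-normal.
#' @param noise_sdlog Per-observation multiplicative log-normal noise (log
#'   scale sd).
#' @param burden_size,burden_mu Negative-binomial fusion burden per tumor
#'   (defaults give median 21, IQR 14-30).
#' @param intra_prop Probability a generated fusion is intrachromosomal.
#' @param region_weights Optional named weights over `UTR5`, `CDS`, `UTR3`
#'   used to re-draw breakpoint regions; `NULL` (default) keeps breakpoints
#'   uniform over the transcript's genomic span.
#' @param fp_pool_size Number of recurrent false-positive gene pairs shared
#'   with the normals.
#' @param fp_rate Mean number of pool false positives injected per tumor.
#' @param planted_gene_folds Numeric vector: one fusion-upregulated gene is
#'   planted per entry, with that expression fold in fusion-positive samples.
#' @param planted_gene_carriers Tumors carrying a fusion in each planted gene.
#' @param anchor_peak_folds,anchor_decays Planted regional anchors: peak fold
#'   at distance 0 and linear decay length (bp, <= 1e6); one anchor per entry.
#' @param anchor_carriers Tumors carrying a fusion in each planted anchor.
#' @param cn_state_freqs Probabilities of GISTIC states -2..+2.
#' @param cn_fusion_or Odds multiplier coupling state +2 with fused
#'   gene-sample pairs (1 = independent).
#' @param signature_size Genes per subtype signature.
#' @param subtype_effect_log Log-scale activation added to a sample's own
#'   subtype signature genes (default 2).
#' @param subtype_probs Subtype mixing proportions (4 values).
#' @param subtype_burden_ratio Burden mean multiplier for immunoreactive and
#'   proliferative samples (1 = no coupling).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_tumors = 200L, n_normals = 7L,
                          n_chromosomes = 24L, chrom_lengths = NULL,
                          genes_per_chrom = 40L,
                          intergenic_mean = 6e4,
                          exon_count_range = c(2L, 8L),
                          exon_meanlog = log(180), exon_sdlog = 0.5,
                          intron_meanlog = log(4000), intron_sdlog = 0.6,
                          intron_decay = 0.35,
                          expr_meanlog = log(10), expr_sdlog = 1,
                          noise_sdlog = 0.5,
                          burden_size = 4, burden_mu = 23,
                          intra_prop = 0.70,
                          region_weights = NULL,
                          fp_pool_size = 50L, fp_rate = 2,
                          planted_gene_folds = numeric(0),
                          planted_gene_carriers = 20L,
                          anchor_peak_folds = numeric(0),
                          anchor_decays = numeric(0),
                          anchor_carriers = 15L,
                          cn_state_freqs = c(0.02, 0.18, 0.60, 0.17, 0.03),
                          cn_fusion_or = 1,
                          signature_size = 40L,
                          subtype_effect_log = 2,
                          subtype_probs = rep(0.25, 4),
                          subtype_burden_ratio = 1) {
  assert_scalar_prob(intra_prop, "intra_prop")
  if (!is.null(region_weights)) {
    if (!all(c("UTR5", "CDS", "UTR3") %in% names(region_weights)) ||
        any(region_weights < 0)) {
      abort("region_weights must be non-negative and named UTR5/CDS/UTR3.")
    }
  }
  if (length(anchor_peak_folds) != length(anchor_decays)) {
    abort("anchor_peak_folds and anchor_decays must have equal length.")
  }
  if (any(anchor_decays > 1e6)) abort("Anchor decay lengths must be <= 1e6 bp.")
  if (abs(sum(cn_state_freqs) - 1) > 1e-8 || length(cn_state_freqs) != 5) {
    abort("cn_state_freqs must be 5 probabilities summing to 1.")
  }
  if (abs(sum(subtype_probs) - 1) > 1e-8 || length(subtype_probs) != 4) {
    abort("subtype_probs must be 4 probabilities summing to 1.")
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

subtype_names <- c("differentiated", "immunoreactive", "mesenchymal",
                   "proliferative")

#' Simulate a genome and gene annotation
#'
#' Places non-overlapping protein-coding genes sequentially along each
#' chromosome with exponential intergenic gaps. Intron lengths follow a
#' 5'-heavy profile: the log-mean decreases with intron position in
#' transcript order, so early (5') introns are longer on average, which is
#' what projects excess random-breakage mass onto 5' exon junctions in cDNA.
#' Deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `chrom_table` and `annotation` (a `fusion_annotation`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lens <- config$chrom_lengths %||% round(hg19_chromosomes()$length / 10)
  if (length(lens) < config$n_chromosomes) {
    lens <- rep_len(lens, config$n_chromosomes)
  }
  lens <- lens[seq_len(config$n_chromosomes)]
  chrom_table <- chromosome_table(paste0("chr", seq_len(config$n_chromosomes)),
                                  lens)
  withr::with_seed(derive_seed(config$seed, 1L), {
    exon_rows <- list()
    cds_rows <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      pos <- 0
      for (gi in seq_len(config$genes_per_chrom)) {
        gene <- sprintf("g%02d_%03d", ci, gi)
        tid <- paste0(gene, ".t1")
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(seq(config$exon_count_range[1],
                           config$exon_count_range[2]), 1)
        ex_len <- pmax(30, round(rlnorm(n_ex, config$exon_meanlog,
                                        config$exon_sdlog)))
        n_in <- n_ex - 1
        in_len <- if (n_in > 0) {
          pmax(60, round(rlnorm(n_in,
                                config$intron_meanlog -
                                  config$intron_decay * (seq_len(n_in) - 1),
                                config$intron_sdlog)))
        } else numeric(0)
        # lengths are in transcript order; reverse for minus-strand layout
        ex_g <- if (strand == "+") ex_len else rev(ex_len)
        in_g <- if (strand == "+") in_len else rev(in_len)
        gap <- 5e3 + round(stats::rexp(1, 1 / config$intergenic_mean))
        start <- pos + gap
        starts <- start + cumsum(c(0, head(ex_g, -1) + in_g))
        ends <- starts + ex_g
        pos <- ends[n_ex]
        if (pos > lens[ci]) {
          abort(sprintf("Genes exceed chromosome length on chr%d.", ci))
        }
        cdna <- sum(ex_len)
        u5 <- max(1, floor(cdna * runif(1, 0.08, 0.25)))
        u3 <- max(1, floor(cdna * runif(1, 0.15, 0.35)))
        # map cDNA CDS bounds to genomic using local exon arithmetic
        cum_g <- cumsum(ex_g)
        loc <- function(cdna_pos) {      # cDNA -> genomic, local
          if (strand == "+") {
            j <- findInterval(cdna_pos, c(0, cum_g))
            starts[j] + (cdna_pos - c(0, cum_g)[j])
          } else {
            rev_cum <- cumsum(rev(ex_g))
            jr <- findInterval(cdna_pos, c(0, rev_cum))
            j <- n_ex + 1 - jr
            ends[j] - 1 - (cdna_pos - c(0, rev_cum)[jr])
          }
        }
        cds_lo_cdna <- u5
        cds_hi_cdna <- cdna - u3 - 1
        gpos <- c(loc(cds_lo_cdna), loc(cds_hi_cdna))
        cds_rows[[tid]] <- tibble(transcript_id = tid,
                                  cds_start = min(gpos), cds_end = max(gpos) + 1)
        exon_rows[[tid]] <- tibble(transcript_id = tid, gene = gene,
                                   chrom = paste0("chr", ci), strand = strand,
                                   start = starts, end = ends)
      }
    }
    annotation <- build_annotation(dplyr::bind_rows(exon_rows),
                                   dplyr::bind_rows(cds_rows), chrom_table)
    list(chrom_table = chrom_table, annotation = annotation)
  })
}

# Per-transcript genomic segments keyed by the cDNA region a breakpoint in
# them maps to (exon pieces split at CDS bounds; introns assigned wholly to
# their donor-junction region). Used for region-reweighted breakpoint draws.
region_segments <- function(annotation, transcript_id) {
  idx <- transcript_index(annotation, transcript_id)
  tx <- annotation$transcripts[
    annotation$transcripts$transcript_id == transcript_id, ]
  segs <- list()
  k <- length(idx$starts)
  for (j in seq_len(k)) {
    bounds <- sort(unique(pmin(pmax(c(tx$cds_start, tx$cds_end),
                                    idx$starts[j]), idx$ends[j])))
    cuts <- unique(c(idx$starts[j], bounds, idx$ends[j]))
    for (s in seq_len(length(cuts) - 1)) {
      lo <- cuts[s]; hi <- cuts[s + 1]
      if (hi <= lo) next
      cd <- map_one_transcript(idx, lo)$cdna
      segs[[length(segs) + 1]] <- tibble(
        start = lo, end = hi,
        region = classify_cdna_region(annotation, transcript_id, cd))
    }
    if (j < k && idx$starts[j + 1] > idx$ends[j]) {
      cd <- map_one_transcript(idx, idx$ends[j])$cdna   # intronic probe
      segs[[length(segs) + 1]] <- tibble(
        start = idx$ends[j], end = idx$starts[j + 1],
        region = classify_cdna_region(annotation, transcript_id, cd))
    }
  }
  dplyr::bind_rows(segs)
}

draw_breakpoint <- function(annotation, transcript_id, region_weights = NULL) {
  tx <- annotation$transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (is.null(region_weights)) {
    return(floor(runif(1, tx$tx_start[i], tx$tx_end[i])))
  }
  segs <- region_segments(annotation, transcript_id)
  segs$w <- region_weights[segs$region] * (segs$end - segs$start)
  if (sum(segs$w) == 0) segs$w <- segs$end - segs$start
  s <- sample.int(nrow(segs), 1, prob = segs$w)
  floor(runif(1, segs$start[s], segs$end[s]))
}

#' Simulate tumor and normal fusion-call tables
#'
#' Per-tumor counts are negative binomial; partner pairs are intrachromosomal
#' with probability `intra_prop`; breakpoints are uniform over each partner's
#' transcript genomic span (optionally region-reweighted) and mapped through
#' [genomic_to_cdna()]. True calls carry classifier probabilities on
#' `[0.81, 1]`; a designated pool of recurrent false-positive pairs is
#' injected into tumors with lower probabilities and duplicated into the
#' normals table, making panel-of-normals subtraction exactly verifiable.
#' Planted genes and anchors from the config are guaranteed fusion calls in
#' their carrier tumors.
#'
#' @param config A [cohort_config()].
#' @param genome Output of [simulate_genome()].
#' @param burden_mu Optional per-tumor burden means overriding
#'   `config$burden_mu`.
#' @return List: `tumor` and `normal` call tibbles (defuse-like), `truth`
#'   (the true tumor calls), `fp_pool`, and `planted` (gene/anchor carrier
#'   assignments).
#' @export
simulate_fusions <- function(config, genome, burden_mu = NULL) {
  annotation <- genome$annotation
  g <- annotation$genes
  g$rank <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
  samples <- sprintf("T%03d", seq_len(config$n_tumors))
  normals <- sprintf("N%02d", seq_len(config$n_normals))

  withr::with_seed(derive_seed(config$seed, 2L), {
    # planted entities: genes with the most neighbors first for anchors so a
    # decay profile is observable; planted upregulated genes drawn at random
    n_pg <- length(config$planted_gene_folds)
    n_an <- length(config$anchor_peak_folds)
    pool_genes <- sample(g$gene)     # random order, deterministic under seed
    planted_genes <- head(pool_genes, n_pg)
    anchor_genes <- head(setdiff(pool_genes, planted_genes), n_an)

    planted <- dplyr::bind_rows(
      if (n_pg > 0) tidyr::expand_grid(gene = planted_genes, kind = "gene"),
      if (n_an > 0) tidyr::expand_grid(gene = anchor_genes, kind = "anchor")
    )
    carriers <- list()
    planted_calls <- list()
    if (n_pg + n_an > 0) {
      for (r in seq_len(nrow(planted))) {
        ncar <- if (planted$kind[r] == "gene") config$planted_gene_carriers
                else config$anchor_carriers
        carriers[[r]] <- sample(samples, ncar)
      }
      planted$carriers <- carriers
    }

    # false-positive pool: pairs disjoint from planted genes
    fp_univ <- setdiff(g$gene, c(planted_genes, anchor_genes))
    fp_pool <- tibble(
      gene5 = sample(fp_univ, config$fp_pool_size, replace = TRUE),
      gene3 = sample(fp_univ, config$fp_pool_size, replace = TRUE)
    )
    # fix degenerate self-pairs
    same <- fp_pool$gene5 == fp_pool$gene3
    while (any(same)) {
      fp_pool$gene3[same] <- sample(fp_univ, sum(same))
      same <- fp_pool$gene5 == fp_pool$gene3
    }
    fp_pool$pos5 <- purrr::map_dbl(fp_pool$gene5, function(gn) {
      draw_breakpoint(annotation, g$transcript_id[match(gn, g$gene)])
    })
    fp_pool$pos3 <- purrr::map_dbl(fp_pool$gene3, function(gn) {
      draw_breakpoint(annotation, g$transcript_id[match(gn, g$gene)])
    })

    pool_key <- paste(pmin(fp_pool$gene5, fp_pool$gene3),
                      pmax(fp_pool$gene5, fp_pool$gene3))
    pick_partner <- function(gene5) {
      i <- match(gene5, g$gene)
      intra <- runif(1) < config$intra_prop
      cand <- if (intra) {
        setdiff(g$gene[g$chrom == g$chrom[i]], gene5)
      } else {
        g$gene[g$chrom != g$chrom[i]]
      }
      # true calls never coincide with a pool pair, so panel subtraction is
      # exactly the false-positive set
      repeat {
        partner <- sample(cand, 1)
        if (!paste(min(gene5, partner), max(gene5, partner)) %in% pool_key) {
          return(partner)
        }
      }
    }

    make_call <- function(sample_id, gene5, gene3) {
      i5 <- match(gene5, g$gene); i3 <- match(gene3, g$gene)
      p5 <- draw_breakpoint(annotation, g$transcript_id[i5],
                            config$region_weights)
      p3 <- draw_breakpoint(annotation, g$transcript_id[i3],
                            config$region_weights)
      tibble(sample = sample_id, gene5 = gene5, gene3 = gene3,
             transcript5 = g$transcript_id[i5], transcript3 = g$transcript_id[i3],
             chrom5 = g$chrom[i5], pos5 = p5, strand5 = g$strand[i5],
             chrom3 = g$chrom[i3], pos3 = p3, strand3 = g$strand[i3])
    }

    mu <- burden_mu %||% rep(config$burden_mu, config$n_tumors)
    burden <- pmax(1L, rnbinom(config$n_tumors, size = config$burden_size,
                               mu = mu))

    # planted calls per tumor
    planted_by_sample <- if (length(carriers) > 0) {
      split(rep(planted$gene, lengths(carriers)), unlist(carriers))
    } else list()

    calls <- list()
    for (si in seq_along(samples)) {
      sid <- samples[si]
      pg <- planted_by_sample[[sid]] %||% character(0)
      n_random <- max(burden[si] - length(pg), 0L)
      rows <- list()
      for (gn in pg) {
        partner <- pick_partner(gn)
        # planted gene is the 5' partner half the time
        if (runif(1) < 0.5) rows[[length(rows) + 1]] <- make_call(sid, gn, partner)
        else rows[[length(rows) + 1]] <- make_call(sid, partner, gn)
      }
      for (k in seq_len(n_random)) {
        g5 <- sample(g$gene, 1)
        rows[[length(rows) + 1]] <- make_call(sid, g5, pick_partner(g5))
      }
      calls[[si]] <- dplyr::bind_rows(rows)
    }
    truth <- dplyr::bind_rows(calls)
    truth$probability <- 0.81 + 0.19 * rbeta(nrow(truth), 2, 2)

    # inject pool false positives into tumors
    n_fp <- stats::rpois(config$n_tumors, config$fp_rate)
    fp_calls <- purrr::map(seq_along(samples), function(si) {
      if (n_fp[si] == 0) return(NULL)
      idx <- sample.int(nrow(fp_pool), n_fp[si], replace = TRUE)
      i5 <- match(fp_pool$gene5[idx], g$gene)
      i3 <- match(fp_pool$gene3[idx], g$gene)
      tibble(sample = samples[si],
             gene5 = fp_pool$gene5[idx], gene3 = fp_pool$gene3[idx],
             transcript5 = g$transcript_id[i5], transcript3 = g$transcript_id[i3],
             chrom5 = g$chrom[i5], pos5 = fp_pool$pos5[idx], strand5 = g$strand[i5],
             chrom3 = g$chrom[i3], pos3 = fp_pool$pos3[idx], strand3 = g$strand[i3],
             probability = rbeta(n_fp[si], 4, 4))
    }) |> dplyr::bind_rows()

    tumor <- dplyr::bind_rows(truth, fp_calls) |>
      arrange(.data$sample, .data$gene5, .data$gene3, .data$pos5)

    # normals: every pool pair appears at least once
    normal <- purrr::map(seq_len(nrow(fp_pool)), function(r) {
      carriers_n <- sample(normals, 1 + rbinom(1, config$n_normals - 1, 0.3))
      i5 <- match(fp_pool$gene5[r], g$gene)
      i3 <- match(fp_pool$gene3[r], g$gene)
      tibble(sample = carriers_n,
             gene5 = fp_pool$gene5[r], gene3 = fp_pool$gene3[r],
             transcript5 = g$transcript_id[i5], transcript3 = g$transcript_id[i3],
             chrom5 = g$chrom[i5], pos5 = fp_pool$pos5[r], strand5 = g$strand[i5],
             chrom3 = g$chrom[i3], pos3 = fp_pool$pos3[r], strand3 = g$strand[i3],
             probability = rbeta(length(carriers_n), 4, 4))
    }) |> dplyr::bind_rows() |> arrange(.data$sample, .data$gene5)

    finish <- function(d) {
      d <- resolve_cdna(d, annotation)
      r5 <- g$rank[match(d$gene5, g$gene)]
      r3 <- g$rank[match(d$gene3, g$gene)]
      s5 <- g$strand[match(d$gene5, g$gene)]
      up <- ifelse(s5 == "+",
                   g$start[match(d$gene5, g$gene)] < g$start[match(d$gene3, g$gene)],
                   g$start[match(d$gene5, g$gene)] > g$start[match(d$gene3, g$gene)])
      d$interchromosomal <- d$chrom5 != d$chrom3
      d$adjacent <- !d$interchromosomal & abs(r5 - r3) == 1
      d$read_through <- d$adjacent &
        s5 == g$strand[match(d$gene3, g$gene)] & up
      d
    }
    list(tumor = finish(tumor), normal = finish(normal),
         truth = finish(truth), fp_pool = fp_pool,
         planted = if (n_pg + n_an > 0) planted else NULL,
         samples = samples)
  })
}

#' Simulate the expression matrix, copy number and subtype structure
#'
#' Baseline FPKM is log-normal per gene with multiplicative log-normal noise.
#' Planted fusion-upregulated genes are multiplied by their fold in carrier
#' samples. Each planted anchor applies, in its carrier samples, a multiplier
#' `1 + (F - 1) * max(0, 1 - |d| / L)` to every same-chromosome neighbor at
#' midpoint distance `d` (linear decay to 1 at `L`). Subtype signature genes
#' are shifted by `subtype_effect_log` (log scale) in samples of that
#' subtype. GISTIC-like copy-number states are drawn per gene-sample pair,
#' optionally coupling high amplification with fused pairs.
#'
#' @param config A [cohort_config()].
#' @param genome Output of [simulate_genome()].
#' @param fusions Output of [simulate_fusions()].
#' @return List: `expression` (tibble, `gene` + one column per tumor),
#'   `copy_number` (tibble of states -2..2), `signatures` (named list of gene
#'   vectors), `subtypes` (tibble `sample`, `subtype`), and `manifest` (truth
#'   manifest list).
#' @export
simulate_expression <- function(config, genome, fusions) {
  annotation <- genome$annotation
  g <- annotation$genes
  samples <- fusions$samples
  withr::with_seed(derive_seed(config$seed, 3L), {
    G <- nrow(g); S <- length(samples)
    baseline <- rlnorm(G, config$expr_meanlog, config$expr_sdlog)
    expr <- baseline * matrix(exp(rnorm(G * S, 0, config$noise_sdlog)),
                              nrow = G)
    rownames(expr) <- g$gene; colnames(expr) <- samples

    status <- fusion_status_matrix(fusions$truth, samples, g$gene)

    planted_tbl <- fusions$planted
    manifest_genes <- tibble(gene = character(), fold = numeric())
    manifest_anchors <- tibble(gene = character(), peak_fold = numeric(),
                               decay = numeric())
    if (!is.null(planted_tbl)) {
      # effects condition on fusion status: every sample carrying a fusion in
      # the planted gene (designated carriers plus chance random calls) shows
      # the expression effect
      pg <- planted_tbl[planted_tbl$kind == "gene", ]
      if (nrow(pg) > 0) {
        manifest_genes <- tibble(gene = pg$gene,
                                 fold = config$planted_gene_folds)
        for (r in seq_len(nrow(pg))) {
          carriers <- samples[status[pg$gene[r], ] > 0]
          expr[pg$gene[r], carriers] <-
            expr[pg$gene[r], carriers] * config$planted_gene_folds[r]
        }
      }
      pa <- planted_tbl[planted_tbl$kind == "anchor", ]
      if (nrow(pa) > 0) {
        manifest_anchors <- tibble(gene = pa$gene,
                                   peak_fold = config$anchor_peak_folds,
                                   decay = config$anchor_decays)
        for (r in seq_len(nrow(pa))) {
          i <- match(pa$gene[r], g$gene)
          FF <- config$anchor_peak_folds[r]; L <- config$anchor_decays[r]
          nb <- which(g$chrom == g$chrom[i] & g$gene != g$gene[i])
          d <- abs(g$midpoint[nb] - g$midpoint[i])
          mult <- 1 + (FF - 1) * pmax(0, 1 - d / L)
          keep <- mult > 1
          carriers <- samples[status[pa$gene[r], ] > 0]
          if (any(keep) && length(carriers) > 0) {
            expr[nb[keep], carriers] <-
              expr[nb[keep], carriers] * mult[keep]
          }
        }
      }
    }

    # subtype structure
    subtype <- sample(subtype_names, S, replace = TRUE,
                      prob = config$subtype_probs)
    sig_pool <- setdiff(g$gene, c(manifest_genes$gene, manifest_anchors$gene))
    if (length(sig_pool) < 4 * config$signature_size) {
      abort("Too few genes for the configured signature_size.")
    }
    sig_genes <- sample(sig_pool, 4 * config$signature_size)
    signatures <- split(sig_genes,
                        rep(subtype_names, each = config$signature_size))
    for (k in seq_along(subtype_names)) {
      cols <- which(subtype == subtype_names[k])
      if (length(cols) > 0) {
        expr[signatures[[subtype_names[k]]], cols] <-
          expr[signatures[[subtype_names[k]]], cols] *
          exp(config$subtype_effect_log)
      }
    }

    # copy number states
    states <- -2:2
    cn <- matrix(sample(states, G * S, replace = TRUE,
                        prob = config$cn_state_freqs),
                 nrow = G, dimnames = list(g$gene, samples))
    if (config$cn_fusion_or != 1) {
      fused <- which(status > 0)
      p <- config$cn_state_freqs
      odds <- p[5] / (1 - p[5]) * config$cn_fusion_or
      p5 <- odds / (1 + odds)
      p_new <- c(p[1:4] / sum(p[1:4]) * (1 - p5), p5)
      cn[fused] <- sample(states, length(fused), replace = TRUE, prob = p_new)
    }

    manifest <- list(
      planted_genes = manifest_genes,
      planted_anchors = manifest_anchors,
      decay_shape = "linear",
      intra_prop = config$intra_prop,
      region_weights = config$region_weights,
      fp_pool = fusions$fp_pool[, c("gene5", "gene3")],
      subtypes = tibble(sample = samples, subtype = subtype),
      seed = config$seed
    )

    list(
      expression = as_tibble(expr, rownames = "gene"),
      copy_number = as_tibble(cn, rownames = "gene"),
      signatures = signatures,
      subtypes = tibble(sample = samples, subtype = subtype),
      manifest = manifest
    )
  })
}

#' Simulate a complete synthetic fusion cohort
#'
#' Runs [simulate_genome()], [simulate_fusions()] and
#' [simulate_expression()] under one seed and bundles the results.
#'
#' @param config A [cohort_config()].
#' @return A `fusion_cohort` list: `config`, `chrom_table`, `annotation`,
#'   `calls_tumor`, `calls_normal`, `truth`, `expression`, `copy_number`,
#'   `signatures`, `subtypes`, `manifest`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  genome <- simulate_genome(config)
  mu <- NULL
  if (config$subtype_burden_ratio != 1) {
    # draw subtypes first so burden can couple to them; re-used downstream
    sub <- withr::with_seed(derive_seed(config$seed, 9L),
                            sample(subtype_names, config$n_tumors,
                                   replace = TRUE, prob = config$subtype_probs))
    mu <- ifelse(sub %in% c("immunoreactive", "proliferative"),
                 config$burden_mu * config$subtype_burden_ratio,
                 config$burden_mu)
  }
  fusions <- simulate_fusions(config, genome, burden_mu = mu)
  ex <- simulate_expression(config, genome, fusions)
  structure(
    list(config = config, chrom_table = genome$chrom_table,
         annotation = genome$annotation,
         calls_tumor = fusions$tumor, calls_normal = fusions$normal,
         truth = fusions$truth, fp_pool = fusions$fp_pool,
         expression = ex$expression, copy_number = ex$copy_number,
         signatures = ex$signatures, subtypes = ex$subtypes,
         manifest = ex$manifest),
    class = "fusion_cohort"
  )
}

#' @export
print.fusion_cohort <- function(x, ...) {
  cat(sprintf(
    "<fusion_cohort> %d tumors, %d genes, %d true calls (+%d FP rows), seed %d\n",
    x$config$n_tumors, nrow(x$annotation$genes), nrow(x$truth),
    nrow(x$calls_tumor) - nrow(x$truth), x$config$seed))
  invisible(x)
}

# Deterministic GTF writer (exon + per-exon CDS features, 1-based closed).
write_gtf <- function(annotation, path) {
  ex <- annotation$exons |>
    left_join(select(annotation$transcripts, "transcript_id", "cds_start",
                     "cds_end"),
              by = "transcript_id")
  attr_str <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                      ex$gene, ex$gene, ex$transcript_id)
  lines <- sprintf("%s\tfusescan\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start + 1, ex$end, ex$strand, attr_str)
  has_cds <- !is.na(ex$cds_start) &
    pmin(ex$end, ex$cds_end) > pmax(ex$start, ex$cds_start)
  cs <- pmax(ex$start, ex$cds_start)[has_cds]
  ce <- pmin(ex$end, ex$cds_end)[has_cds]
  cds_lines <- sprintf("%s\tfusescan\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                       ex$chrom[has_cds], cs + 1, ce, ex$strand[has_cds],
                       attr_str[has_cds])
  writeLines(c(lines, cds_lines), path)
  invisible(path)
}

#' Write a synthetic cohort to disk as analysis-ready fixture files
#'
#' Emits every input format the downstream readers consume: `genes.gtf`,
#' `chrom.sizes`, `fusions_tumor.tsv`, `fusions_normal.tsv`,
#' `expression.tsv` (FPKM, genes x samples), `copy_number.tsv` (GISTIC-like
#' integer states), `signatures/` (one gene list per subtype) and
#' `manifest.json` (the truth manifest).
#'
#' @param cohort A `fusion_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("Cannot write to directory '%s'.", dir))
  }
  write_gtf(cohort$annotation, file.path(dir, "genes.gtf"))
  readr::write_tsv(cohort$chrom_table, file.path(dir, "chrom.sizes"),
                   col_names = FALSE, progress = FALSE)
  write_defuse_table(cohort$calls_tumor, file.path(dir, "fusions_tumor.tsv"))
  write_defuse_table(cohort$calls_normal, file.path(dir, "fusions_normal.tsv"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$copy_number, file.path(dir, "copy_number.tsv"),
                   progress = FALSE)
  sig_dir <- file.path(dir, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  for (nm in names(cohort$signatures)) {
    writeLines(cohort$signatures[[nm]], file.path(sig_dir, paste0(nm, ".txt")))
  }
  m <- cohort$manifest
  jsonlite::write_json(
    list(planted_genes = m$planted_genes, planted_anchors = m$planted_anchors,
         decay_shape = m$decay_shape, intra_prop = m$intra_prop,
         region_weights = m$region_weights, fp_pool = m$fp_pool,
         subtypes = m$subtypes, seed = m$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
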