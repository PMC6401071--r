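test_that("cohort generation is fully deterministic under seed", {
  cfg <- cohort_config(seed = 5L, n_tumors = 15L, n_chromosomes = 4L,
                       genes_per_chrom = 12L, signature_size = 5L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$calls_tumor, b$calls_tumor)
  expect_identical(a$calls_normal, b$calls_normal)
  expect_identical(a$copy_number, b$copy_number)
  expect_identical(a$subtypes, b$subtypes)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  fusescan:::write_gtf(a$annotation, f1)
  fusescan:::write_gtf(b$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated genomes have the configured shape and 5'-heavy introns", {
  cfg <- cohort_config(seed = 3L, n_chromosomes = 2L, genes_per_chrom = 50L)
  gen <- simulate_genome(cfg)
  expect_equal(nrow(gen$annotation$genes), 100)
  tx <- gen$annotation$transcripts
  expect_true(all(tx$coding))
  expect_true(all(tx$utr5_length + tx$cds_length + tx$utr3_length ==
                    tx$cdna_length))

  # early introns longer than late introns, in transcript order, over many genes
  big <- cached("genome1k", function() {
    simulate_genome(cohort_config(seed = 13L, n_chromosomes = 24L,
                                  genes_per_chrom = 42L))
  })
  ex <- big$annotation$exons |>
    dplyr::group_by(transcript_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(
      n_intron = dplyr::n() - 1,
      first = if (dplyr::n() > 1) {
        if (strand[1] == "+") start[2] - end[1] else
          start[dplyr::n()] - end[dplyr::n() - 1]
      } else NA_real_,
      last = if (dplyr::n() > 1) {
        if (strand[1] == "+") start[dplyr::n()] - end[dplyr::n() - 1] else
          start[2] - end[1]
      } else NA_real_,
      .groups = "drop") |>
    dplyr::filter(n_intron >= 2)
  expect_gt(nrow(ex), 500)
  expect_gt(mean(ex$first), mean(ex$last))

  # infeasible packing errors with the chromosome named
  expect_error(
    simulate_genome(cohort_config(seed = 1L, n_chromosomes = 1L,
                                  chrom_lengths = 2e5, genes_per_chrom = 50L)),
    "chromosome length")
})

test_that("fusion tables honour the intrachromosomal proportion and burden model", {
  cfg <- cohort_config(seed = 9L, n_tumors = 100L, n_chromosomes = 8L,
                       genes_per_chrom = 20L, intra_prop = 1)
  gen <- simulate_genome(cfg)
  fus <- simulate_fusions(cfg, gen)
  expect_true(all(fus$truth$chrom5 == fus$truth$chrom3))

  co <- small_cohort()   # default intra 0.70
  b <- burden_summary(co$truth)
  expect_lte(abs(b$median - 21), 3)
  expect_true(all(co$truth$probability >= 0.81))

  # every false-positive pool pair appears in the normals table
  norm_pairs <- paste(pmin(co$calls_normal$gene5, co$calls_normal$gene3),
                      pmax(co$calls_normal$gene5, co$calls_normal$gene3))
  pool_pairs <- paste(pmin(co$fp_pool$gene5, co$fp_pool$gene3),
                      pmax(co$fp_pool$gene5, co$fp_pool$gene3))
  expect_true(all(pool_pairs %in% norm_pairs))

  # intrachromosomal fraction close to the configured 0.70 at ~2,000 calls
  big <- cached("calls2k", function() {
    cfg2 <- cohort_config(seed = 17L, n_tumors = 100L, n_chromosomes = 12L,
                          genes_per_chrom = 20L)
    simulate_fusions(cfg2, simulate_genome(cfg2))
  })
  expect_gt(nrow(big$truth), 1500)
  expect_lt(abs(mean(big$truth$chrom5 == big$truth$chrom3) - 0.70), 0.03)
})

test_that("planted expression effects follow the stated multipliers", {
  co <- planted_cohort()
  status <- cohort_status(co)
  em <- fusescan:::expr_as_matrix(co$expression)

  # planted gene with fold 8: carrier/non-carrier median ratio within [6, 10]
  pg <- co$manifest$planted_genes
  g8 <- pg$gene[pg$fold == 8][1]
  pos <- status[g8, ] > 0
  ratio <- median(em[g8, pos]) / median(em[g8, !pos])
  expect_gte(ratio, 6)
  expect_lte(ratio, 10)

  # anchor with F = 3, L = 1e6: fold ~3 near d = 0, ~2 at 0.5 Mb, ~1 beyond L
  pa <- co$manifest$planted_anchors
  g <- co$annotation$genes
  a <- pa$gene[1]
  apos <- status[a, ] > 0
  i <- match(a, g$gene)
  nb <- g[g$chrom == g$chrom[i] & g$gene != a, ]
  d <- abs(nb$midpoint - g$midpoint[i])
  expected_mult <- 1 + 2 * pmax(0, 1 - d / 1e6)
  obs_mult <- vapply(nb$gene, function(n) {
    mean(em[n, apos]) / mean(em[n, !apos])
  }, numeric(1))
  # correlation between planted and observed multipliers across the window
  keep <- d < 2e6
  expect_gt(cor(expected_mult[keep], obs_mult[keep]), 0.6)
  near <- which(d < 2e5); far <- which(d > 1.2e6)
  if (length(near) > 0) expect_gt(mean(obs_mult[near]), 2)
  if (length(far) > 0) expect_lt(abs(mean(obs_mult[far]) - 1), 0.35)
})

test_that("zero-effect configs produce no systematic fusion-status fold change", {
  co <- small_cohort()
  status <- cohort_status(co)
  em <- fusescan:::expr_as_matrix(co$expression)
  n_pos <- rowSums(status > 0)
  genes <- names(n_pos)[n_pos >= 5]
  lf <- vapply(genes, function(gn) {
    s <- status[gn, ] > 0
    log2(mean(em[gn, s]) / mean(em[gn, !s]))
  }, numeric(1))
  expect_lt(abs(mean(lf)), 0.15)
})

test_that("single-exon genomes with natural weights give cDNA-proportional regions", {
  # no introns: a uniform genomic breakpoint is uniform in cDNA, so observed
  # region proportions converge to the mean cDNA length fractions
  cfg <- cohort_config(seed = 21L, n_tumors = 100L, n_chromosomes = 6L,
                       genes_per_chrom = 15L, exon_count_range = c(1L, 1L),
                       exon_meanlog = log(1500))
  gen <- simulate_genome(cfg)
  fus <- simulate_fusions(cfg, gen)
  prof <- region_profile(fus$truth, gen$annotation)
  obs <- prof |>
    dplyr::group_by(region) |>
    dplyr::summarise(p = sum(count) / sum(prof$count))
  expected <- expected_region_distribution(gen$annotation)$regions
  m <- dplyr::inner_join(obs, expected, by = "region")
  expect_lt(max(abs(m$p - m$proportion)), 0.03)
})

test_that("region reweighting shifts breakpoints into the requested regions", {
  cfg <- cohort_config(seed = 33L, n_tumors = 60L, n_chromosomes = 4L,
                       genes_per_chrom = 15L,
                       region_weights = c(UTR5 = 3, CDS = 1, UTR3 = 3))
  gen <- simulate_genome(cfg)
  fus <- simulate_fusions(cfg, gen)
  prof <- region_profile(fus$truth, gen$annotation)
  utr <- prof |>
    dplyr::group_by(region) |>
    dplyr::summarise(p = sum(count) / sum(prof$count))
  base <- expected_region_distribution(gen$annotation)$regions
  # UTR share well above the unweighted expectation
  expect_gt(sum(utr$p[utr$region != "CDS"]),
            sum(base$proportion[base$region != "CDS"]) + 0.1)
})

test_that("fixtures round-trip through every reader and list the planted truth", {
  co <- planted_cohort()
  dir <- withr::local_tempdir()
  write_fixture(co, dir)
  expect_setequal(list.files(dir),
                  c("genes.gtf", "chrom.sizes", "fusions_tumor.tsv",
                    "fusions_normal.tsv", "expression.tsv", "copy_number.tsv",
                    "signatures", "manifest.json"))
  calls2 <- read_defuse_table(file.path(dir, "fusions_tumor.tsv"))
  expect_equal(nrow(calls2), nrow(co$calls_tumor))
  expect_equal(calls2$pos5, co$calls_tumor$pos5)
  expr2 <- read_fpkm_matrix(file.path(dir, "expression.tsv"))
  expect_equal(expr2$gene, co$expression$gene)
  cn2 <- read_gistic_matrix(file.path(dir, "copy_number.tsv"))
  expect_equal(dim(cn2), dim(co$copy_number))
  sigs <- read_signatures(file.path(dir, "signatures"))
  expect_setequal(names(sigs),
                  c("differentiated", "immunoreactive", "mesenchymal",
                    "proliferative"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$planted_genes$gene, co$manifest$planted_genes$gene)
  expect_equal(man$intra_prop, 0.70)
  expect_error(suppressWarnings(write_fixture(co, file.path("/proc", "nope"))),
               "irectory")
})

test_that("config validation rejects malformed settings", {
  expect_error(cohort_config(intra_prop = 1.5), "0, 1")
  expect_error(cohort_config(anchor_peak_folds = 3, anchor_decays = c(1e6, 2e5)),
               "equal length")
  expect_error(cohort_config(anchor_peak_folds = 3, anchor_decays = 2e6),
               "1e6")
  expect_error(cohort_config(cn_state_freqs = c(0.5, 0.5)), "5 probabilities")
})
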