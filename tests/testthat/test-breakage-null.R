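test_that("expected intrachromosomal fraction matches the closed form", {
  expect_equal(expected_intrachromosomal_fraction(chromosome_table("c1", 5e6)), 1)
  two <- chromosome_table(c("a", "b"), c(1e6, 1e6))
  expect_equal(expected_intrachromosomal_fraction(two), 0.5)
  hg <- expected_intrachromosomal_fraction(hg19_chromosomes())
  expect_equal(hg, 0.0497, tolerance = 0.01)
  expect_error(expected_intrachromosomal_fraction(hg19_chromosomes()[0, ]),
               "Empty")

  # simulation converges to the closed form within 3 binomial SEs
  withr::with_seed(404, {
    for (k in 1:5) {
      nc <- sample(3:12, 1)
      ct <- chromosome_table(paste0("c", seq_len(nc)),
                             runif(1, 1e6, 2e8) * runif(nc, 0.2, 1))
      p <- expected_intrachromosomal_fraction(ct)
      n <- 1e5
      sim <- expected_intrachromosomal_fraction(ct, "simulation", n_perm = n,
                                                seed = 100 + k)
      expect_lt(abs(sim - p), 3 * sqrt(p * (1 - p) / n))
    }
  })
})

test_that("intrachromosomal enrichment test behaves at the boundaries", {
  one_chrom <- chromosome_table("c1", 1e6)
  calls <- tibble::tibble(chrom5 = rep("c1", 20), chrom3 = rep("c1", 20))
  r <- intrachromosomal_enrichment(calls, one_chrom, n_perm = 2000, seed = 1)
  expect_equal(r$fold_enrichment, 1)
  expect_equal(r$p_value, 1)

  # observed below the null mean: fold < 1 and p > 0.5
  many <- chromosome_table(c("a", "b"), c(1e6, 1e6))
  inter <- tibble::tibble(chrom5 = rep("a", 50), chrom3 = rep("b", 50))
  r2 <- intrachromosomal_enrichment(inter, many, n_perm = 2000, seed = 2)
  expect_lt(r2$fold_enrichment, 1)
  expect_gt(r2$p_value, 0.5)

  # p floor and add-one correction
  expect_gte(r2$p_value, 1 / 2001)
  expect_warning(intrachromosomal_enrichment(calls, one_chrom, n_perm = 10,
                                             seed = 1), "1,000")
  # exact binomial null agrees with a literal two-endpoint simulation
  ct <- chromosome_table(c("a", "b", "c"), c(3e6, 2e6, 1e6))
  p_lit <- expected_intrachromosomal_fraction(ct, "simulation", n_perm = 2e5,
                                              seed = 5)
  expect_lt(abs(p_lit - expected_intrachromosomal_fraction(ct)), 0.005)
})

test_that("expected region distribution equals exhaustive per-base enumeration", {
  ann <- toy_annotation()
  # single-exon gene (tC): utr5/cds/utr3 = 100/300/200 over 600 bases
  e <- expected_region_distribution(ann, "tC")
  expect_equal(e$regions$proportion, c(1 / 6, 1 / 2, 1 / 3))
  expect_equal(sum(e$regions$proportion), 1)

  # enumeration oracle on every toy transcript, both strands
  for (tid in c("tA", "tB", "tC", "tD")) {
    ed <- expected_region_distribution(ann, tid)
    oracle <- enumerate_region_distribution(ann, tid)
    expect_equal(ed$regions$proportion, unname(oracle), tolerance = 1e-12,
                 info = tid)
  }

  # a huge intron inside the CDS raises the CDS share and shifts mass 5'
  ct <- chromosome_table("chr1", 1e7)
  exons <- tibble::tibble(transcript_id = "tI", gene = "I", chrom = "chr1",
                          strand = "+", start = c(0, 5200), end = c(200, 5600))
  cds <- tibble::tibble(transcript_id = "tI", cds_start = 100, cds_end = 5500)
  annI <- fusescan:::build_annotation(exons, cds, ct)
  eI <- expected_region_distribution(annI, "tI")
  oracleI <- enumerate_region_distribution(annI, "tI")
  expect_equal(eI$regions$proportion, unname(oracleI), tolerance = 1e-12)
  expect_gt(eI$regions$proportion[eI$regions$region == "CDS"],
            400 / 600)  # far above the cDNA share
  # intron donor sits at relative CDS position (100-ish)/400 -> 5' mass
  lo <- sum(eI$cds_density$density[eI$cds_density$mid < 0.5]) /
    sum(eI$cds_density$density)
  expect_gt(lo, 0.9)

  # simulation mode agrees with the analytic distribution
  es <- expected_region_distribution(annI, "tI", method = "simulation",
                                     n_perm = 2e4, seed = 3)
  expect_equal(es$regions$proportion, eI$regions$proportion, tolerance = 0.02)
})

test_that("region enrichment test detects planted UTR bias and respects the p floor", {
  cfg <- cohort_config(seed = 31L, n_tumors = 30L, n_chromosomes = 6L,
                       genes_per_chrom = 15L,
                       region_weights = c(UTR5 = 3, CDS = 1, UTR3 = 3))
  gen <- simulate_genome(cfg)
  fus <- simulate_fusions(cfg, gen)
  calls <- head(fus$truth, 250)
  r <- region_enrichment_test(calls, gen$annotation, n_perm = 2000, seed = 5)
  expect_lt(r$p_value[r$region == "UTR5"], 0.01)
  expect_lt(r$p_value[r$region == "CDS"], 0.01)   # depletion is two-sided
  expect_gt(r$fold_enrichment[r$region == "UTR5"], 1)
  expect_lt(r$fold_enrichment[r$region == "CDS"], 1)

  # single call: p at or above the add-one floor
  r1 <- region_enrichment_test(calls[1, ], gen$annotation, n_perm = 1000,
                               seed = 1)
  expect_true(all(r1$p_value >= 1 / 1001))
})

test_that("CDS positional KS test matches brute force and flags C-terminal bias", {
  ann <- toy_annotation()
  # strongly C-terminal observed sample vs a uniform-like expectation
  obs <- rep(c(0.9, 0.92, 0.95, 0.97, 0.99), 20)
  exp_samp <- seq(0.001, 0.999, length.out = 1000)
  D_oracle <- brute_force_ks_D(obs, exp_samp)
  k <- suppressWarnings(ks.test(obs, exp_samp))
  expect_equal(unname(k$statistic), D_oracle, tolerance = 1e-12)
  expect_gte(D_oracle, 0.8)
  expect_lt(k$p.value, 1e-10)

  # the full pipeline entry: calls with CDS breakpoints on the toy gene
  tx <- ann$transcripts[ann$transcripts$transcript_id == "tC", ]
  pos <- seq(20150, 20390, by = 16)   # CDS-resident genomic positions
  calls <- tibble::tibble(
    sample = "s", gene5 = "C", gene3 = "C",
    transcript5 = "tC", transcript3 = "tC",
    chrom5 = "chr1", pos5 = pos, strand5 = "+",
    chrom3 = "chr1", pos3 = rev(pos), strand3 = "+"
  )
  res <- cds_positional_test(calls, ann, seed = 7)
  expect_setequal(res$half, c("overall", "N-terminal", "C-terminal"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # uniform-in-CDS observed positions are compatible with the expectation
  expect_gt(res$p_value[res$half == "overall"], 0.01)
  expect_error(cds_positional_test(calls[0, ], ann), "CDS")
})

test_that("region profile comparisons use chi-square homogeneity", {
  pa <- structure(tibble::tibble(end = "5p", region = c("UTR5", "CDS", "UTR3"),
                                 count = c(30, 50, 20), proportion = c(.3, .5, .2)),
                  class = c("region_profile", class(tibble::tibble())))
  r_same <- compare_region_profiles(pa, pa)
  expect_equal(r_same$statistic[r_same$test == "k_sample"], 0)
  expect_equal(r_same$p_value[r_same$test == "k_sample"], 1)

  pb <- pa; pb$count <- c(90, 10, 0)
  pb2 <- pa; pb2$count <- c(10, 90, 0)
  r <- suppressWarnings(compare_region_profiles(pb, pb2, region = "UTR5"))
  expect_lt(r$p_value[r$test == "two_sample"], 1e-15)

  no_counts <- pa[, c("end", "region", "proportion")]
  expect_error(compare_region_profiles(no_counts, pa), "counts")
})

test_that("stronger planted region bias gives smaller enrichment p", {
  ps <- vapply(c(1, 2.5, 6), function(wt) {
    cfg <- cohort_config(seed = 91L, n_tumors = 25L, n_chromosomes = 5L,
                         genes_per_chrom = 12L,
                         region_weights = c(UTR5 = wt, CDS = 1, UTR3 = wt))
    gen <- simulate_genome(cfg)
    fus <- simulate_fusions(cfg, gen)
    r <- region_enrichment_test(head(fus$truth, 200), gen$annotation,
                                n_perm = 1500, seed = 17)
    r$p_value[r$region == "UTR5"]
  }, numeric(1))
  expect_true(ps[3] <= ps[1])
  expect_lt(ps[3], 0.05)
})
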