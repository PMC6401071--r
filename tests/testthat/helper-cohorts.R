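# Shared synthetic cohorts, built once per test run and cached.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .cohort_cache)) {
    assign(name, maker(), envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

# small general-purpose cohort (fast; used by module tests)
small_cohort <- function() {
  cached("small", function() {
    simulate_cohort(cohort_config(
      seed = 42L, n_tumors = 60L, n_chromosomes = 8L, genes_per_chrom = 20L,
      signature_size = 10L
    ))
  })
}

# cohort with planted fusion-upregulated genes and one anchor
planted_cohort <- function() {
  cached("planted", function() {
    simulate_cohort(cohort_config(
      seed = 7L, n_tumors = 100L, n_chromosomes = 10L, genes_per_chrom = 25L,
      signature_size = 10L,
      planted_gene_folds = c(8, 8, 6, 4), planted_gene_carriers = 20L,
      anchor_peak_folds = c(3, 3, 3), anchor_decays = rep(1e6, 3),
      anchor_carriers = 15L
    ))
  })
}

cohort_status <- function(co) {
  fusion_status_matrix(co$truth, names(co$expression)[-1],
                       co$expression$gene)
}
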