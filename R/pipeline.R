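pipeline_defaults <- list(
  probability_threshold = 0.81,
  min_positives = 3,
  window_half_width = 1e6,
  q_threshold = 0.05,
  n_perm = 1e4,
  n_rand = 200,
  ssgsea_n_perm = 1000,
  seed = 1L
)

pipeline_path_keys <- c("calls", "normals", "gtf", "chrom_sizes", "expression",
                        "copy_number", "signatures", "out_dir")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Paths: `calls`, `normals`,
#' `gtf`, `chrom_sizes`, `expression`, `copy_number` (optional), `signatures`
#' (optional), `out_dir`. Thresholds default to the pipeline's standard
#' constants (probability 0.81, window half-width 1e6 bp, minimum 3 positive
#' samples, q 0.05) and the global `seed` is fanned out to every stochastic
#' stage by a counter-based derivation. Unknown keys are rejected; referenced
#' input files must exist.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) abort("Empty config file.")
  }
  if (!is.list(config)) abort("Config must be a file path or a named list.")
  unknown <- setdiff(names(config), c(pipeline_path_keys,
                                      names(pipeline_defaults)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(pipeline_defaults)) {
    config[[k]] <- config[[k]] %||% pipeline_defaults[[k]]
    if (!is.numeric(config[[k]]) || length(config[[k]]) != 1) {
      abort(sprintf("Config key '%s' must be a single number.", k))
    }
  }
  assert_scalar_prob(config$probability_threshold, "probability_threshold")
  assert_scalar_prob(config$q_threshold, "q_threshold")
  required <- c("calls", "normals", "gtf", "chrom_sizes", "expression", "out_dir")
  for (k in required) {
    if (is.null(config[[k]])) abort(sprintf("Config key '%s' is required.", k))
  }
  for (k in setdiff(intersect(pipeline_path_keys, names(config)), "out_dir")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      abort(sprintf("Config path '%s' does not exist: %s", k, config[[k]]))
    }
  }
  class(config) <- "pipeline_config"
  config
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full fusion analysis pipeline
#'
#' Executes filter, breakage-null, expression-association, regional and
#' subtype stages over the configured inputs, writing each stage's tabular
#' outputs plus a top-level `summary.json` (seeds, counts and every
#' enrichment statistic with its permutation count) into `out_dir`. Stage
#' seeds derive from the global seed so each stage is independently
#' reproducible.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  pipeline_log("load", "reading annotation and inputs")
  chrom_table <- read_chrom_sizes(config$chrom_sizes)
  annotation <- load_annotation(config$gtf, chrom_table)
  calls <- read_defuse_table(config$calls)
  normals <- read_defuse_table(config$normals)
  expression <- read_fpkm_matrix(config$expression)

  pipeline_log("filter", "probability >= %.2f + panel of normals",
               config$probability_threshold)
  filtered <- calls |>
    filter_by_probability(config$probability_threshold) |>
    subtract_panel_of_normals(normals)
  write_defuse_table(filtered, file.path(config$out_dir, "filtered_calls.tsv"))
  burden <- burden_summary(filtered)
  classes <- classify_rearrangements(filtered, annotation)
  readr::write_tsv(classes, file.path(config$out_dir, "rearrangement_classes.tsv"),
                   progress = FALSE)

  pipeline_log("breakage-null", "%d permutations", config$n_perm)
  intra <- intrachromosomal_enrichment(filtered, chrom_table,
                                       n_perm = config$n_perm,
                                       seed = derive_seed(seed, 11L))
  regions <- region_enrichment_test(filtered, annotation,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(seed, 12L))
  profile_obs <- region_profile(filtered, annotation)
  readr::write_tsv(profile_obs, file.path(config$out_dir, "region_profile.tsv"),
                   progress = FALSE)
  cds_ks <- tryCatch(
    cds_positional_test(filtered, annotation, seed = derive_seed(seed, 13L)),
    error = function(e) NULL)

  pipeline_log("expr-assoc", "rank-sum tests, min positives %d",
               config$min_positives)
  status <- fusion_status_matrix(filtered, names(expression)[-1],
                                 expression$gene)
  assoc <- fusion_expression_test(expression, status,
                                  min_positives = config$min_positives)
  readr::write_tsv(assoc, file.path(config$out_dir, "fusion_expression.tsv"),
                   progress = FALSE)
  cn_assoc <- NULL
  if (!is.null(config$copy_number)) {
    cn <- read_gistic_matrix(config$copy_number)
    cn_assoc <- copy_number_association(filtered, cn, n_perm = config$n_perm,
                                        seed = derive_seed(seed, 14L))
  }

  pipeline_log("regional", "window +/- %g bp, %d randomizations",
               config$window_half_width, config$n_rand)
  anchors <- unique(c(filtered$gene5, filtered$gene3))
  windows <- build_anchor_windows(annotation, anchors,
                                  half_width = config$window_half_width)
  profile <- aggregate_profile(expression, windows, status,
                               n_rand = config$n_rand,
                               seed = derive_seed(seed, 15L),
                               min_positives = config$min_positives)
  calls_out <- call_dysregulated_genes(profile, q_threshold = config$q_threshold)
  readr::write_tsv(calls_out$pairs, file.path(config$out_dir, "regional_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(profile$curve, file.path(config$out_dir, "regional_profile.tsv"),
                   progress = FALSE)
  readr::write_tsv(calls_out$genes,
                   file.path(config$out_dir, "dysregulated_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(chromosome_fusion_summary(filtered, chrom_table),
                   file.path(config$out_dir, "chromosome_summary.tsv"),
                   progress = FALSE)

  subtypes <- NULL
  if (!is.null(config$signatures)) {
    pipeline_log("subtype", "ssGSEA with %d permutations", config$ssgsea_n_perm)
    sigs <- read_signatures(config$signatures)
    subtypes <- assign_subtypes(expression, sigs,
                                n_perm = config$ssgsea_n_perm,
                                seed = derive_seed(seed, 16L))
    readr::write_tsv(subtypes, file.path(config$out_dir, "subtypes.tsv"),
                     progress = FALSE)
  }

  summary <- list(
    seed = seed,
    n_raw_calls = nrow(calls),
    n_filtered_calls = nrow(filtered),
    burden = list(median = burden$median, q25 = burden$q25, q75 = burden$q75,
                  min = burden$min, max = burden$max),
    intrachromosomal = as.list(intra[1, c("observed", "null_mean",
                                          "fold_enrichment", "p_value",
                                          "n_perm")]),
    region_enrichment = regions,
    cds_ks = cds_ks,
    copy_number = cn_assoc,
    n_association_rows = nrow(assoc),
    n_regional_pairs = nrow(calls_out$pairs),
    n_dysregulated_genes = nrow(calls_out$genes),
    n_dysregulated_anchors = dplyr::n_distinct(calls_out$called_pairs$anchor)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(filtered = filtered, burden = burden, classes = classes,
                 intra = intra, regions = regions, cds_ks = cds_ks,
                 association = assoc, copy_number = cn_assoc,
                 profile = profile, dysregulation = calls_out,
                 subtypes = subtypes, summary = summary))
}
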