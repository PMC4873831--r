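# End-to-end orchestration: simulate (optional) -> detection filter ->
# pattern classification per tissue x generation -> transgenerational
# consistency -> homeolog partitioning -> deterministic TSV reports.

#' Pipeline run configuration
#'
#' @param expression_path,manifest_path,homeolog_path Input TSV paths;
#'   leave `NULL` to run on simulated data (`simulate` config).
#' @param tissues Tissues to analyze; defaults to those found in the
#'   manifest (or the simulation config).
#' @param generations Polyploid generations; same defaulting.
#' @param alpha_expression FDR threshold for expression contrasts
#'   (default 0.05).
#' @param alpha_partitioning Raw p threshold for partitioning and bias
#'   tests (default 0.05).
#' @param detection_threshold Detection threshold on the log2 scale
#'   (default 5); set to `-Inf` to disable filtering.
#' @param mpv_mode `"measured_mix"` (default) or `"computed"`.
#' @param match_mode Transgenerational match mode (default
#'   `"exact_pattern"`).
#' @param test_method `"moderated"` (default) or `"ordinary"`.
#' @param log2_transform Passed to [read_expression()].
#' @param seed Seed used when simulating.
#' @param simulate A [sim_config()] or a list of its arguments; used
#'   when no input paths are given.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(expression_path = NULL, manifest_path = NULL,
                       homeolog_path = NULL, tissues = NULL,
                       generations = NULL, alpha_expression = 0.05,
                       alpha_partitioning = 0.05, detection_threshold = 5,
                       mpv_mode = "measured_mix",
                       match_mode = "exact_pattern",
                       test_method = "moderated", log2_transform = FALSE,
                       seed = 1, simulate = list()) {
  for (a in c(alpha_expression, alpha_partitioning)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop("significance thresholds must lie in (0, 1)")
    }
  }
  if (!mpv_mode %in% c("measured_mix", "computed")) {
    stop("mpv_mode must be measured_mix or computed")
  }
  if (!match_mode %in% c("exact_pattern", "nonadditive_only")) {
    stop("match_mode must be exact_pattern or nonadditive_only")
  }
  if (!test_method %in% c("moderated", "ordinary")) {
    stop("test_method must be moderated or ordinary")
  }
  if (!inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, c(simulate,
                                      if (!"seed" %in% names(simulate))
                                        list(seed = seed)))
  }
  structure(list(expression_path = expression_path,
                 manifest_path = manifest_path,
                 homeolog_path = homeolog_path,
                 tissues = tissues, generations = generations,
                 alpha_expression = alpha_expression,
                 alpha_partitioning = alpha_partitioning,
                 detection_threshold = detection_threshold,
                 mpv_mode = mpv_mode, match_mode = match_mode,
                 test_method = test_method,
                 log2_transform = log2_transform,
                 seed = as.integer(seed), simulate = simulate),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the
#' `simulate:` block holds [sim_config()] arguments. Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$simulate)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(cfg$simulate), sim_known)
    if (length(sim_unknown)) {
      stop("unknown simulate config keys: ",
           paste(sim_unknown, collapse = ", "))
    }
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes: simulate (when no input paths are configured) ->
#' detection filter -> parental classification and the pattern decision
#' tree per tissue x generation -> transgenerational consistency and
#' source decomposition per tissue -> homeolog partitioning calls,
#' comparable-data-point tabulation and subgenome dominance (when
#' allele fractions are available) -> TSV reports plus a YAML run
#' manifest under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and returns results only.
#' @return Invisibly, a list with `dataset`, `truth` (simulated runs
#'   only), `calls`, `category_summary`, `transgen`, `sources`,
#'   `partitioning`, `comparable`, `dominance` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  simulated <- is.null(config$expression_path)
  truth <- NULL
  homeolog <- NULL
  truth_homeolog <- NULL
  if (simulated) {
    sim <- simulate_expression(config$simulate)
    dataset <- sim$dataset
    truth <- sim$truth
    hsim <- simulate_homeolog(config$simulate, truth, dataset)
    homeolog <- hsim$homeolog
    truth_homeolog <- hsim$truth_homeolog
  } else {
    if (is.null(config$manifest_path)) {
      stop("manifest_path is required with expression_path")
    }
    dataset <- read_expression(config$expression_path, config$manifest_path,
                               log2_transform = config$log2_transform)
    if (!is.null(config$homeolog_path)) {
      homeolog <- read_homeolog(config$homeolog_path)
    }
  }
  tissues <- config$tissues
  if (is.null(tissues)) tissues <- unique(dataset$samples$tissue)
  generations <- config$generations
  if (is.null(generations)) {
    generations <- unique(dataset$samples$generation[
      dataset$samples$role == "polyploid"])
  }

  calls_list <- list()
  transgen_list <- list()
  sources_list <- list()
  part_list <- list()
  for (tt in tissues) {
    filt <- detection_filter(dataset, threshold = config$detection_threshold,
                             tissue = tt)
    ds <- filt$dataset
    parental <- classify_parental(ds, tt, alpha = config$alpha_expression,
                                  method = config$test_method)
    tissue_calls <- do.call(rbind, lapply(generations, function(g) {
      classify_pattern(ds, tt, g, parental = parental,
                       alpha = config$alpha_expression,
                       mpv_mode = config$mpv_mode,
                       method = config$test_method)
    }))
    calls_list[[tt]] <- tissue_calls
    tg <- find_consistent(tissue_calls, generations = generations,
                          match_mode = config$match_mode)
    transgen_list[[tt]] <- tg
    if (config$match_mode == "exact_pattern") {
      sources_list[[tt]] <- decompose_sources(tg, tissue_calls)
    }
    if (!is.null(homeolog)) {
      part_list[[tt]] <- call_partitioning(
        homeolog, dataset, tissue_calls, tt,
        alpha = config$alpha_partitioning)
    }
  }
  calls <- do.call(rbind, calls_list)
  rownames(calls) <- NULL
  partitioning <- if (length(part_list)) do.call(rbind, part_list) else NULL
  if (!is.null(partitioning)) rownames(partitioning) <- NULL

  category_summary <- summarize_categories(calls)
  comparable <- if (!is.null(partitioning)) {
    list(additive = tabulate_comparable(partitioning, "additive"),
         nonadditive = tabulate_comparable(partitioning, "nonadditive"))
  }
  dominance <- if (!is.null(homeolog)) {
    do.call(rbind, lapply(tissues, function(tt) {
      d <- summarize_dominance(homeolog, dataset, tissue = tt,
                               alpha = config$alpha_partitioning)
      d$tissue <- tt
      d
    }))
  }

  manifest <- list(
    seed = config$seed,
    simulated = simulated,
    tissues = tissues,
    generations = generations,
    alpha_expression = config$alpha_expression,
    alpha_partitioning = config$alpha_partitioning,
    detection_threshold = config$detection_threshold,
    mpv_mode = config$mpv_mode,
    match_mode = config$match_mode,
    test_method = config$test_method,
    n_genes_input = length(dataset$gene_ids),
    n_calls = nrow(calls),
    n_partitioning = if (is.null(partitioning)) 0L else nrow(partitioning))

  result <- list(dataset = dataset, truth = truth, homeolog = homeolog,
                 truth_homeolog = truth_homeolog, calls = calls,
                 category_summary = category_summary,
                 transgen = transgen_list, sources = sources_list,
                 partitioning = partitioning, comparable = comparable,
                 dominance = dominance, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calls(calls, file.path(out_dir, "category_calls.tsv"))
    write_tsv <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_tsv(category_summary$pattern_counts, "pattern_counts.tsv")
    write_tsv(category_summary$parental_additivity, "parental_additivity.tsv")
    write_tsv(category_summary$propensity_tests, "propensity_tests.tsv")
    tg_df <- do.call(rbind, lapply(names(transgen_list), function(tt) {
      d <- transgen_list[[tt]]$per_generation
      d$tissue <- tt
      d$n_consistent <- transgen_list[[tt]]$n_consistent
      d
    }))
    write_tsv(tg_df, "transgen_summary.tsv")
    if (length(sources_list)) {
      src_df <- do.call(rbind, lapply(names(sources_list), function(tt) {
        d <- sources_list[[tt]]$source_counts
        d$tissue <- tt
        d
      }))
      write_tsv(src_df, "transgen_sources.tsv")
    }
    if (!is.null(partitioning)) {
      write_calls(partitioning, file.path(out_dir, "partitioning_calls.tsv"))
    }
    if (!is.null(dominance)) write_tsv(dominance, "dominance_summary.tsv")
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  invisible(result)
}
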