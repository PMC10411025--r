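# End-to-end orchestration: match -> estimate -> rank/compare -> GLM -> classify.

#' Run the full analysis pipeline on input files
#'
#' Executes the complete analysis: load the lexicon (dropping excluded
#' entries), tally the query log against it and join the case registry,
#' compute search popularity and search-estimated patients, rank diseases
#' annually in both systems, code ranking differences into RDGs, summarise
#' per-year RDG counts, blocked Pearson consistency, adjacent-year
#' intersections and top-k persistence, fit the Gaussian GLM of RDG on year
#' and disease-group factors, and classify diseases into two categories.
#'
#' When `out_dir` is given, writes `counts.csv`, `estimates.csv`,
#' `ranks.csv`, `diffs.csv`, `rdg_counts.csv`, `group_summary.csv`,
#' `intersections.csv`, `topk.csv`, `glm.csv`, `classification.csv` and a
#' `summary.json` run log (row counts, skip counters, parameters). Reruns on
#' identical inputs produce byte-identical outputs.
#'
#' @param lexicon Path to the lexicon JSON, or a `qc_lexicon`.
#' @param log_path Path to the query-log TSV.
#' @param registry Path to the case-registry CSV, or a tibble.
#' @param population Path to the population CSV, or a tibble/named vector.
#' @param years Integer vector of analysis years.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param cutoff RDG interval half-width.
#' @param block_size Diseases per consistency block.
#' @param k Top-k threshold.
#' @param baseline_year Baseline year for the GLM disease grouping (default
#'   earliest).
#' @param policy Classification policy, see [classify_diseases()].
#' @param mode Query matching mode, see [match_query()].
#' @return List of class `qc_pipeline` with elements `counts`, `estimates`,
#'   `ranks`, `diffs`, `rdg_counts`, `consistency`, `intersections`, `topk`,
#'   `glm`, `classification`, and `params`.
#' @export
run_pipeline <- function(lexicon, log_path, registry, population, years,
                         out_dir = NULL, cutoff = 20L, block_size = 20L,
                         k = 10L, baseline_year = NULL,
                         policy = c("majority", "baseline"),
                         mode = c("substring", "exact")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(lexicon)) lexicon <- stage("lexicon", read_lexicon(lexicon))
  if (is.character(population)) {
    population <- stage("population", read_population(population))
  }
  counts <- stage("match",
                  tally_queries(log_path, lexicon, registry, years, mode = mode))
  estimates <- stage("estimate",
                     estimate_patients(compute_popularity(counts), population))
  analysed <- stage("compare",
                    analyse_counts(counts, estimates, cutoff = cutoff,
                                   block_size = block_size, k = k))
  glm_fit <- stage("glm", fit_rdg_glm(build_design(analysed$diffs,
                                                   baseline_year = baseline_year)))
  classification <- stage("classify",
                          classify_diseases(analysed$diffs, policy = policy))
  res <- c(list(counts = counts, estimates = estimates),
           analysed,
           list(glm = glm_fit, classification = classification,
                params = list(years = sort(unique(as.integer(years))),
                              cutoff = as.integer(cutoff),
                              block_size = as.integer(block_size),
                              k = as.integer(k),
                              baseline_year = baseline_year,
                              policy = policy, mode = mode)))
  class(res) <- "qc_pipeline"
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

# The comparison stage shared by run_pipeline and the noise-free oracle path.
analyse_counts <- function(counts, estimates, cutoff = 20L, block_size = 20L,
                           k = 10L) {
  ranks <- build_ranks(estimates, counts)
  diffs <- ranking_difference(ranks, cutoff = cutoff)
  list(
    ranks = ranks,
    diffs = diffs,
    rdg_counts = rdg_year_counts(diffs),
    consistency = grouped_consistency(ranks, block_size = block_size),
    intersections = adjacent_intersections(diffs),
    topk = topk_persistent(ranks, k = k)
  )
}

#' Run the pipeline on the noise-free expected counts of a synthetic truth
#'
#' Feeds the generator's expected (noise-free) query and case counts through
#' the estimation, ranking, RDG and classification stages, bypassing file
#' emission and tallying. Used to check that the analysis reproduces the
#' generator's ground truth exactly in the absence of sampling noise.
#'
#' @param truth A `synthetic_truth`.
#' @inheritParams run_pipeline
#' @return As [run_pipeline()], without the `glm` element when only one
#'   baseline group is populated.
#' @export
run_expected_pipeline <- function(truth, cutoff = NULL, block_size = 20L,
                                  k = 10L, policy = c("majority", "baseline")) {
  policy <- match.arg(policy)
  if (is.null(cutoff)) cutoff <- truth$config$cutoff
  counts <- expected_counts(truth)
  population <- tibble::tibble(year = truth$config$years,
                               population = unname(truth$config$population))
  estimates <- estimate_patients(compute_popularity(counts), population)
  analysed <- analyse_counts(counts, estimates, cutoff = cutoff,
                             block_size = block_size, k = k)
  classification <- classify_diseases(analysed$diffs, policy = policy)
  c(list(counts = counts, estimates = estimates), analysed,
    list(classification = classification))
}

#' Generate a synthetic scenario and run the full pipeline on it
#'
#' Convenience wrapper: generates the ground truth for `config`, emits the
#' lexicon, query log, case registry and population series under
#' `data_dir`, then runs [run_pipeline()] on those files.
#'
#' @param config A `scenario_config` (e.g. [default_scenario()]).
#' @param data_dir Directory for the emitted synthetic inputs (created;
#'   default a session temporary directory).
#' @inheritParams run_pipeline
#' @return The [run_pipeline()] result, with the `synthetic_truth` attached
#'   as element `truth` and the emission summaries as `emission`.
#' @export
run_scenario <- function(config, data_dir = tempfile("qc_scenario"),
                         out_dir = NULL, block_size = 20L, k = 10L,
                         baseline_year = NULL,
                         policy = c("majority", "baseline")) {
  policy <- match.arg(policy)
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth(config)
  lex_path <- file.path(data_dir, "lexicon.json")
  log_path <- file.path(data_dir, "queries.tsv")
  reg_path <- file.path(data_dir, "registry.csv")
  pop_path <- file.path(data_dir, "population.csv")
  emit_lexicon(truth, lex_path)
  log_summary <- emit_search_log(truth, log_path)
  emit_case_registry(truth, reg_path)
  emit_population(truth, pop_path)
  res <- run_pipeline(lex_path, log_path, reg_path, pop_path,
                      years = config$years, out_dir = out_dir,
                      cutoff = config$cutoff, block_size = block_size, k = k,
                      baseline_year = baseline_year, policy = policy)
  res$truth <- truth
  res$emission <- log_summary
  res
}

# Flatten per-year top-k lists and the persistent sets into one table.
topk_table <- function(topk) {
  per_year <- topk$per_year
  per_year$persistent <- paste(per_year$system, per_year$disease_id) %in%
    paste(topk$persistent$system, topk$persistent$disease_id)
  per_year
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  counts_out <- dplyr::left_join(res$counts$counts, res$counts$totals,
                                 by = "year")
  w(counts_out, "counts.csv")
  w(res$estimates, "estimates.csv")
  w(tibble::as_tibble(res$ranks), "ranks.csv")
  w(tibble::as_tibble(res$diffs), "diffs.csv")
  w(res$rdg_counts, "rdg_counts.csv")
  gs <- dplyr::left_join(res$consistency$blocks, res$consistency$pearson,
                         by = "year")
  w(gs, "group_summary.csv")
  inter <- res$intersections
  inter$members <- vapply(inter$members, paste, character(1), collapse = ";")
  w(inter, "intersections.csv")
  w(topk_table(res$topk), "topk.csv")
  w(res$glm$table, "glm.csv")
  w(tibble::as_tibble(res$classification), "classification.csv")
  summary <- list(
    params = res$params,
    n_diseases = length(unique(res$counts$counts$disease_id)),
    years = res$params$years,
    total_queries = stats::setNames(as.list(res$counts$totals$total_queries),
                                    res$counts$totals$year),
    skipped = res$counts$report,
    glm_n_obs = res$glm$n_obs,
    n_category_2 = sum(res$classification$category == 2L),
    package_version = as.character(utils::packageVersion("querycase"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.qc_pipeline <- function(x, ...) {
  cat("<qc_pipeline> ", length(unique(x$counts$counts$disease_id)),
      " diseases, years ", paste(range(x$params$years), collapse = "-"),
      ", cutoff ", x$params$cutoff, "\n", sep = "")
  wide <- tidyr::pivot_wider(x$rdg_counts, names_from = "year",
                             values_from = "n", names_prefix = "y")
  cat("RDG counts per year:\n")
  print(wide)
  cat("category 2 diseases: ", sum(x$classification$category == 2L), " of ",
      nrow(x$classification), "\n", sep = "")
  invisible(x)
}
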