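# Seeded synthetic query logs, case registries, lexicons and ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# heavy-tailed cross-disease prevalence (log-normal), per-disease-year
# publicity spikes inflating query volume, background non-disease queries,
# and per-disease registry under-reporting. Noise-free expectations are
# exposed as a ground-truth oracle.

#' Build and validate a synthetic scenario configuration
#'
#' @param n_diseases Number of active diseases (>= 2).
#' @param years Strictly increasing integer vector of calendar years.
#' @param population Named numeric vector (names = years) of persons per year.
#' @param prevalence_logmu,prevalence_logsigma Log-normal parameters of
#'   per-disease prevalence in cases per person: `log(prevalence)` has mean
#'   `prevalence_logmu` and sd `prevalence_logsigma` (heavy-tailed across
#'   diseases).
#' @param search_rate Expected queries per true patient per year. Values well
#'   below 1 give a desk-scale query stream whose annual rankings match those
#'   of a proportionally larger one.
#' @param publicity_spike_prob Probability per disease-year of a publicity
#'   spike (news coverage, a film) inflating query volume.
#' @param publicity_spike_scale Multiplicative query inflation under a spike
#'   (>= 1; the multiplier is 1 without a spike).
#' @param reporting_alpha,reporting_beta Beta parameters of the per-disease
#'   registry reporting rate (probability a true case is captured).
#' @param reporting_rho Optional point-mass reporting rate in \[0, 1\]
#'   overriding the Beta draw (e.g. `1` for full reporting).
#' @param background_queries Named numeric vector (names = years) of
#'   non-matching noise queries per year.
#' @param cutoff Ranking-difference interval half-width used for the
#'   ground-truth RDG coding.
#' @param n_excluded Extra lexicon entries flagged as excluded (catalog
#'   entries dropped from analysis), appended after the active diseases.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return Validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_diseases, years, population,
                            prevalence_logmu, prevalence_logsigma,
                            search_rate,
                            publicity_spike_prob, publicity_spike_scale,
                            reporting_alpha, reporting_beta,
                            reporting_rho = NULL,
                            background_queries,
                            cutoff = 20L, n_excluded = 0L, seed = 1L) {
  cfg <- list(
    n_diseases = as.integer(n_diseases),
    years = as.integer(years),
    population = population,
    prevalence_logmu = prevalence_logmu,
    prevalence_logsigma = prevalence_logsigma,
    search_rate = search_rate,
    publicity_spike_prob = publicity_spike_prob,
    publicity_spike_scale = publicity_spike_scale,
    reporting_alpha = reporting_alpha,
    reporting_beta = reporting_beta,
    reporting_rho = reporting_rho,
    background_queries = background_queries,
    cutoff = as.integer(cutoff),
    n_excluded = as.integer(n_excluded),
    seed = as.integer(seed)
  )
  fail <- function(field, why) {
    stop("invalid scenario configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (is.na(cfg$n_diseases) || cfg$n_diseases < 2L) fail("n_diseases", "must be >= 2")
  if (length(cfg$years) < 1L || anyNA(cfg$years) ||
      any(diff(cfg$years) <= 0L)) fail("years", "must be strictly increasing")
  for (fld in c("population", "background_queries")) {
    v <- cfg[[fld]]
    if (is.null(names(v)) || !all(as.character(cfg$years) %in% names(v))) {
      fail(fld, "must be a named vector covering every year")
    }
    cfg[[fld]] <- as.numeric(v[as.character(cfg$years)])
    names(cfg[[fld]]) <- as.character(cfg$years)
  }
  if (any(cfg$population <= 0)) fail("population", "values must be > 0")
  if (any(cfg$background_queries < 0)) fail("background_queries", "must be >= 0")
  if (!is.finite(cfg$prevalence_logsigma) || cfg$prevalence_logsigma < 0) {
    fail("prevalence_logsigma", "must be >= 0")
  }
  if (!is.finite(cfg$search_rate) || cfg$search_rate < 0) {
    fail("search_rate", "must be >= 0")
  }
  if (cfg$publicity_spike_prob < 0 || cfg$publicity_spike_prob > 1) {
    fail("publicity_spike_prob", "must be in [0, 1]")
  }
  if (cfg$publicity_spike_scale < 1) {
    fail("publicity_spike_scale", "must be >= 1")
  }
  if (cfg$reporting_alpha <= 0) fail("reporting_alpha", "must be > 0")
  if (cfg$reporting_beta <= 0) fail("reporting_beta", "must be > 0")
  if (!is.null(cfg$reporting_rho) &&
      (cfg$reporting_rho < 0 || cfg$reporting_rho > 1)) {
    fail("reporting_rho", "must be in [0, 1]")
  }
  if (cfg$cutoff < 1L) fail("cutoff", "must be >= 1")
  if (cfg$n_excluded < 0L) fail("n_excluded", "must be >= 0")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  class(cfg) <- "scenario_config"
  cfg
}

#' The shipped default synthetic scenario
#'
#' 120 active diseases (plus one excluded lexicon entry, mirroring a
#' 121-entry national catalog with one stated exclusion) over 2016-2019 with
#' near-census Chinese population figures; log-normal prevalence centred at
#' about 8 cases per 10 million persons with log-sd 1.3 (heavy-tailed);
#' a desk-scale query stream (0.05 queries per patient-year plus 20,000
#' background queries per year); publicity spikes in 15% of disease-years
#' inflating queries eightfold; Beta(2, 2) per-disease
#' reporting rates (mean 0.5, spanning near-complete to poor ascertainment).
#'
#' @param seed Integer RNG seed.
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1L) {
  years <- 2016:2019
  scenario_config(
    n_diseases = 120L,
    years = years,
    population = stats::setNames(c(1.3925e9, 1.4001e9, 1.4054e9, 1.4100e9),
                                 years),
    prevalence_logmu = log(8e-7),
    prevalence_logsigma = 1.3,
    search_rate = 0.05,
    publicity_spike_prob = 0.15,
    publicity_spike_scale = 8,
    reporting_alpha = 2,
    reporting_beta = 2,
    background_queries = stats::setNames(rep(20000, length(years)), years),
    cutoff = 20L,
    n_excluded = 1L,
    seed = seed
  )
}

#' Read / write a scenario configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_scenario` returns a validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("population", "background_queries")) {
    y[[fld]] <- unlist(y[[fld]])
  }
  do.call(scenario_config, y)
}

#' @rdname read_scenario
#' @param config A `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  y <- unclass(config)
  y$population <- as.list(y$population)
  y$background_queries <- as.list(y$background_queries)
  y[vapply(y, is.null, logical(1))] <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

# Independent sub-stream seeds derived once from the config seed, so that
# adding or reordering one generator does not perturb the draws of another.
stream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                  c("lexicon", "prevalence", "publicity", "reporting",
                    "search_log", "registry"))
}

# Collision-free synthetic lexicon: every keyword embeds a fixed-width
# zero-padded disease index plus a terminal marker, so no keyword of one
# disease can occur inside a query built from another's.
synthetic_lexicon_table <- function(n_active, n_excluded) {
  n <- n_active + n_excluded
  idx <- sprintf("%04dq", seq_len(n))
  tibble::tibble(
    disease_id = sprintf("RD%04d", seq_len(n)),
    canonical_name = sprintf("synthetic disease %04d", seq_len(n)),
    keywords = lapply(idx, function(i) {
      c(sprintf("synthetic disease %s", i),
        sprintf("sdz%s syndrome", i),
        sprintf("sd-%s", i))
    }),
    excluded = rep(c(FALSE, TRUE), c(n_active, n_excluded))
  )
}

#' Generate the synthetic ground truth
#'
#' Draws the scenario's latent quantities and derives the noise-free
#' expectations and the ground-truth analysis results:
#' * prevalence per disease (log-normal), giving true patient counts
#'   `T[d, y] = round(prevalence[d] * population[y])`;
#' * a publicity multiplier per disease-year (1, or `publicity_spike_scale`
#'   when a spike is drawn);
#' * a reporting rate per disease (Beta, or the `reporting_rho` point mass);
#' * expected query counts `search_rate * T * publicity` and expected case
#'   counts `reporting_rate * T`;
#' * the ground-truth RDG table obtained by running the ranking-difference
#'   analysis on the expected (noise-free) counts, and the ground-truth
#'   two-category classification obtained by applying the disease
#'   classification rule to that RDG table.
#'
#' Deterministic for a fixed config (all randomness derives from
#' `config$seed` through per-purpose sub-streams).
#'
#' @param config A `scenario_config`.
#' @return Object of class `synthetic_truth`: list with `config`,
#'   `lexicon_table` (all entries incl. excluded), `lexicon` (active
#'   `qc_lexicon`), `prevalence`, `reporting` (per-disease tibbles), `table`
#'   (tibble `disease_id`, `year`, `true_patients`, `publicity`,
#'   `expected_queries`, `expected_cases`, `truth_rdg`), `truth_diffs`
#'   (the noise-free `diff_table`) and `truth_category`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- stream_seeds(config$seed)
  n <- config$n_diseases
  years <- config$years

  lex_tbl <- synthetic_lexicon_table(n, config$n_excluded)
  lexicon <- as_lexicon(lex_tbl)
  ids <- lexicon$disease_id

  set.seed(seeds[["prevalence"]])
  prevalence <- stats::rlnorm(n, config$prevalence_logmu,
                              config$prevalence_logsigma)

  set.seed(seeds[["publicity"]])
  spikes <- matrix(stats::runif(n * length(years)) < config$publicity_spike_prob,
                   nrow = n)
  publicity <- ifelse(spikes, config$publicity_spike_scale, 1)

  set.seed(seeds[["reporting"]])
  rho <- if (!is.null(config$reporting_rho)) {
    rep(config$reporting_rho, n)
  } else {
    stats::rbeta(n, config$reporting_alpha, config$reporting_beta)
  }

  tab <- tidyr::expand_grid(disease_id = ids, year = years)
  di <- match(tab$disease_id, ids)
  yi <- match(tab$year, years)
  tab$true_patients <- round(prevalence[di] * unname(config$population)[yi])
  tab$publicity <- publicity[cbind(di, yi)]
  tab$expected_queries <- config$search_rate * tab$true_patients * tab$publicity
  tab$expected_cases <- rho[di] * tab$true_patients

  search_tbl <- tab[, c("disease_id", "year")]
  search_tbl$value <- tab$expected_queries
  case_tbl <- tab[, c("disease_id", "year")]
  case_tbl$value <- tab$expected_cases
  truth_ranks <- build_ranks(search_tbl, case_tbl,
                             search_col = "value", case_col = "value")
  truth_diffs <- ranking_difference(truth_ranks, cutoff = config$cutoff)
  tab$truth_rdg <- truth_diffs$rdg[match(paste(tab$disease_id, tab$year),
                                         paste(truth_diffs$disease_id,
                                               truth_diffs$year))]
  truth_category <- classify_diseases(truth_diffs, policy = "majority")

  structure(
    list(
      config = config,
      stream_seeds = seeds,
      lexicon_table = lex_tbl,
      lexicon = lexicon,
      prevalence = tibble::tibble(disease_id = ids, prevalence = prevalence),
      reporting = tibble::tibble(disease_id = ids, reporting_rate = rho),
      table = tab,
      truth_diffs = truth_diffs,
      truth_category = truth_category
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$config$n_diseases, " diseases x ",
      length(x$config$years), " years (seed ", x$config$seed, ")\n", sep = "")
  cat("expected queries/year: ",
      paste(round(tapply(x$table$expected_queries, x$table$year, sum)),
            collapse = ", "), "\n", sep = "")
  cat("expected cases/year:   ",
      paste(round(tapply(x$table$expected_cases, x$table$year, sum)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write the synthetic lexicon to JSON
#'
#' Writes all entries, including those flagged as excluded, in the lexicon
#' JSON schema accepted by [read_lexicon()].
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
emit_lexicon <- function(truth, path) {
  tb <- truth$lexicon_table
  entries <- lapply(seq_len(nrow(tb)), function(i) {
    list(disease_id = tb$disease_id[i],
         canonical_name = tb$canonical_name[i],
         keywords = as.list(tb$keywords[[i]]),
         excluded = tb$excluded[i])
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

query_templates <- c("%s", "%s symptoms", "what is %s", "%s treatment",
                     "%s diagnosis")

#' Emit a synthetic query-log TSV
#'
#' For each disease-year, draws the number of matching lines from
#' Poisson(expected queries) and writes one line per query:
#' `year<TAB>query_text`, where the text embeds exactly one keyword of
#' exactly one disease inside a small set of templates ("<kw> symptoms",
#' "what is <kw>", bare "<kw>", ...). Additionally writes the configured
#' number of background lines per year whose text matches no keyword. Lines
#' are shuffled within each year. Deterministic for a fixed truth (seeded
#' sub-stream). Paths ending in `.gz` are gzip-compressed.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output TSV path.
#' @return List with `lines_per_year` (tibble `year`, `matching`,
#'   `background`, `total`) and `drawn` (tibble `disease_id`, `year`,
#'   `n_queries` — the realized per-disease counts, the round-trip oracle for
#'   [tally_queries()]).
#' @export
emit_search_log <- function(truth, path) {
  cfg <- truth$config
  set.seed(truth$stream_seeds[["search_log"]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)

  tab <- truth$table
  kw <- truth$lexicon$keywords
  names(kw) <- truth$lexicon$disease_id
  drawn <- tab[, c("disease_id", "year")]
  drawn$n_queries <- stats::rpois(nrow(tab), tab$expected_queries)

  per_year <- list()
  for (y in cfg$years) {
    rows <- which(drawn$year == y)
    n_match <- sum(drawn$n_queries[rows])
    texts <- character(0)
    if (n_match > 0) {
      id_rep <- rep(drawn$disease_id[rows], drawn$n_queries[rows])
      kws <- vapply(id_rep, function(d) {
        k <- kw[[d]]
        k[sample.int(length(k), 1L)]
      }, character(1))
      tmpl <- sample(query_templates, n_match, replace = TRUE)
      texts <- sprintf(tmpl, kws)
    }
    n_bg <- cfg$background_queries[[as.character(y)]]
    if (n_bg > 0) {
      texts <- c(texts, sprintf("bgq %07d news", sample.int(9999999L, n_bg,
                                                            replace = TRUE)))
    }
    texts <- texts[sample.int(length(texts))]
    if (length(texts)) writeLines(paste(y, texts, sep = "\t"), con)
    per_year[[as.character(y)]] <- tibble::tibble(
      year = y, matching = n_match, background = as.numeric(n_bg),
      total = n_match + n_bg)
  }
  list(lines_per_year = dplyr::bind_rows(per_year), drawn = drawn)
}

#' Emit a synthetic case-registry CSV
#'
#' For each disease-year, draws the reported count from
#' Binomial(true patients, reporting rate) and writes the case-count CSV
#' (`disease_id,year,reported_cases`). Deterministic for a fixed truth.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output CSV path.
#' @return Tibble `disease_id`, `year`, `reported_cases` (also written to
#'   `path`).
#' @export
emit_case_registry <- function(truth, path) {
  set.seed(truth$stream_seeds[["registry"]])
  tab <- truth$table
  rho <- truth$reporting$reporting_rate[match(tab$disease_id,
                                              truth$reporting$disease_id)]
  out <- tibble::tibble(
    disease_id = tab$disease_id,
    year = tab$year,
    reported_cases = stats::rbinom(nrow(tab), size = tab$true_patients,
                                   prob = rho)
  )
  readr::write_csv(out, path)
  out
}

#' Write the scenario population series to CSV
#'
#' @param truth A `synthetic_truth` (or a `scenario_config`).
#' @param path Output CSV path (`year,population`).
#' @return `path`, invisibly.
#' @export
emit_population <- function(truth, path) {
  cfg <- if (inherits(truth, "synthetic_truth")) truth$config else truth
  readr::write_csv(tibble::tibble(year = cfg$years,
                                  population = unname(cfg$population)), path)
  invisible(path)
}

#' Noise-free expected counts as an `annual_counts` object
#'
#' Packages the generator's expected query and case counts in the container
#' produced by [tally_queries()], so the full downstream analysis can be run
#' on noise-free inputs and compared with the ground truth. Total annual
#' query volume is the expected matching volume plus the configured
#' background.
#'
#' @param truth A `synthetic_truth`.
#' @return An `annual_counts` object (real-valued counts).
#' @export
expected_counts <- function(truth) {
  tab <- truth$table
  counts <- tibble::tibble(
    disease_id = tab$disease_id,
    year = tab$year,
    query_count = tab$expected_queries,
    case_count = tab$expected_cases
  )
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$year),
                             total_queries = sum(.data$query_count),
                             .groups = "drop")
  totals$total_queries <- totals$total_queries +
    truth$config$background_queries[as.character(totals$year)]
  structure(
    list(counts = counts, totals = tibble::as_tibble(totals),
         report = list(malformed_lines = 0L, lines_outside_years = 0L,
                       unknown_registry_rows = 0L)),
    class = "annual_counts"
  )
}
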