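# Search popularity and search-estimated patient counts.

#' Read a population series
#'
#' Reads a CSV with columns `year,population`.
#'
#' @param path Path to the CSV.
#' @return Tibble with integer `year` and numeric `population`.
#' @export
read_population <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    population = readr::col_double()
  ))
}

#' Compute search popularity
#'
#' Search popularity is the fraction of all queries in a year that match a
#' disease's keywords: `popularity = query_count / total_queries`. It is a
#' dimensionless ratio in \[0, 1\].
#'
#' @param counts An `annual_counts` object from [tally_queries()].
#' @return Tibble `disease_id`, `year`, `query_count`, `popularity`.
#' @export
compute_popularity <- function(counts) {
  stopifnot(inherits(counts, "annual_counts"))
  zero <- counts$totals$year[counts$totals$total_queries <= 0]
  if (length(zero)) {
    stop("total query volume is zero for year(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(counts$counts, counts$totals, by = "year")
  out$popularity <- out$query_count / out$total_queries
  out[, c("disease_id", "year", "query_count", "popularity")]
}

#' Estimate patient numbers from search popularity
#'
#' Under the assumption that search-engine users are a random sample of the
#' population, the number of patients with a disease is estimated as
#' `est_patients = popularity * population` for each year. Estimates are kept
#' as real numbers internally; round only at report time to avoid
#' order-dependent ranking artifacts.
#'
#' @param popularity Tibble from [compute_popularity()].
#' @param population Tibble `year`, `population` (or a named numeric vector
#'   keyed by year).
#' @return Tibble `disease_id`, `year`, `query_count`, `popularity`,
#'   `est_patients`.
#' @export
estimate_patients <- function(popularity, population) {
  if (!is.data.frame(population)) {
    population <- tibble::tibble(year = as.integer(names(population)),
                                 population = as.numeric(population))
  }
  missing_years <- setdiff(unique(popularity$year), population$year)
  if (length(missing_years)) {
    stop("population series is missing year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(popularity, population, by = "year")
  out$est_patients <- out$popularity * out$population
  out[, c("disease_id", "year", "query_count", "popularity", "est_patients")]
}

#' Per-year totals of search-estimated patients
#'
#' @param estimates Tibble from [estimate_patients()].
#' @return Tibble `year`, `total_est_patients`.
#' @export
estimated_patient_totals <- function(estimates) {
  out <- dplyr::summarise(dplyr::group_by(estimates, .data$year),
                          total_est_patients = sum(.data$est_patients),
                          .groups = "drop")
  tibble::as_tibble(out)
}
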