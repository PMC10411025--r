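# Annual rankings, ranking differences, RDG coding and stability statistics.

#' Rank diseases within each year
#'
#' Ranks are 1-based ordinal positions after sorting a year's values in
#' descending order, so rank 1 is the largest patient count. Ties are broken
#' by ascending `disease_id`, giving a strict permutation of `1..D` in every
#' year (interval coding and fixed-size rank blocks require unique ranks).
#'
#' @param values Tibble with columns `disease_id`, `year`, and the value
#'   column named by `value_col`.
#' @param value_col Name of the column to rank on.
#' @return Tibble `disease_id`, `year`, `rank`.
#' @export
rank_annual <- function(values, value_col) {
  need <- c("disease_id", "year", value_col)
  miss <- setdiff(need, names(values))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  full <- tidyr::expand_grid(disease_id = unique(values$disease_id),
                             year = unique(values$year))
  holes <- dplyr::anti_join(full, values, by = c("disease_id", "year"))
  if (nrow(holes)) {
    stop("missing value cells: ",
         paste(paste0(holes$disease_id, "/", holes$year), collapse = ", "),
         call. = FALSE)
  }
  v <- values[, need]
  names(v)[3] <- ".value"
  out <- dplyr::group_by(v, .data$year)
  out <- dplyr::arrange(out, dplyr::desc(.data$.value), .data$disease_id,
                        .by_group = TRUE)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  out <- dplyr::ungroup(out)
  dplyr::arrange(out[, c("disease_id", "year", "rank")], .data$year,
                 .data$disease_id)
}

#' Build the two-system rank table
#'
#' Computes annual disease rankings separately in the search system (by
#' search-estimated patients) and the registry system (by reported cases).
#'
#' @param estimates Tibble from [estimate_patients()] (or any tibble with
#'   `disease_id`, `year` and the column in `search_col`).
#' @param counts An `annual_counts` object (or a tibble with `disease_id`,
#'   `year` and the column in `case_col`).
#' @param search_col,case_col Value columns ranked in each system.
#' @return Tibble of class `rank_table`: `disease_id`, `year`,
#'   `search_rank`, `case_rank`.
#' @export
build_ranks <- function(estimates, counts,
                        search_col = "est_patients", case_col = "case_count") {
  if (inherits(counts, "annual_counts")) counts <- counts$counts
  rs <- rank_annual(estimates, search_col)
  rc <- rank_annual(counts, case_col)
  names(rs)[3] <- "search_rank"
  names(rc)[3] <- "case_rank"
  out <- dplyr::inner_join(rs, rc, by = c("disease_id", "year"))
  if (nrow(out) != nrow(rs) || nrow(out) != nrow(rc)) {
    stop("search and case tables cover different (disease, year) domains",
         call. = FALSE)
  }
  class(out) <- c("rank_table", class(out))
  out
}

#' Ranking differences and interval codes (RDG)
#'
#' The ranking difference is `diff = search_rank - case_rank`; negative
#' values mean a disease looks relatively bigger in search than in the
#' registry. Differences are coded into three ranking-difference groups by
#' the intervals `(-Inf, -cutoff)`, `[-cutoff, cutoff]`, `(cutoff, +Inf)`,
#' given codes 0, 1 and 2; both boundaries are closed at the central
#' interval. The default cutoff is 20 and can be adjusted to research needs.
#'
#' @param ranks A `rank_table` from [build_ranks()] (or a tibble with
#'   `disease_id`, `year`, `search_rank`, `case_rank`).
#' @param cutoff Positive integer interval half-width.
#' @return Tibble of class `diff_table`: `disease_id`, `year`, `search_rank`,
#'   `case_rank`, `diff`, `rdg`, with the cutoff stored in attribute
#'   `cutoff`.
#' @export
ranking_difference <- function(ranks, cutoff = 20L) {
  stopifnot(cutoff > 0)
  need <- c("disease_id", "year", "search_rank", "case_rank")
  miss <- setdiff(need, names(ranks))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- tibble::as_tibble(ranks[, need])
  out$diff <- out$search_rank - out$case_rank
  out$rdg <- ifelse(out$diff < -cutoff, 0L,
                    ifelse(out$diff > cutoff, 2L, 1L))
  attr(out, "cutoff") <- as.integer(cutoff)
  class(out) <- c("diff_table", class(out))
  out
}

#' Per-year counts of the three ranking-difference groups
#'
#' @param diffs A `diff_table` from [ranking_difference()].
#' @return Tibble `year`, `rdg`, `n`, with every (year, code) pair present
#'   (zero-filled); the three counts in a year sum to the number of diseases.
#' @export
rdg_year_counts <- function(diffs) {
  grid <- tidyr::expand_grid(year = sort(unique(diffs$year)), rdg = 0:2)
  tab <- dplyr::count(diffs, .data$year, .data$rdg)
  out <- dplyr::left_join(grid, tab, by = c("year", "rdg"))
  out$n[is.na(out$n)] <- 0L
  out$n <- as.integer(out$n)
  out
}

#' Blocked rank consistency with Pearson correlation
#'
#' Within each year, diseases are grouped into consecutive blocks of
#' `block_size` by their search rank (ranks 1-20, 21-40, ... for the default
#' block size; a final partial block is retained when the disease count is
#' not a multiple of `block_size`). For each block the mean search rank and
#' mean registry case rank of its members are computed, and the per-year
#' Pearson correlation between the two block-mean vectors measures how
#' consistent the two systems' orderings are.
#'
#' @param ranks A `rank_table`.
#' @param block_size Diseases per search-rank block.
#' @return List with `blocks` (tibble `year`, `block`, `block_label`, `n`,
#'   `mean_search_rank`, `mean_case_rank`) and `pearson` (tibble `year`,
#'   `pearson_r`). With fewer than two blocks the correlation is `NA` with a
#'   warning.
#' @export
grouped_consistency <- function(ranks, block_size = 20L) {
  stopifnot(block_size >= 1)
  d <- tibble::as_tibble(ranks)
  d$block <- (d$search_rank - 1L) %/% as.integer(block_size) + 1L
  blocks <- dplyr::summarise(
    dplyr::group_by(d, .data$year, .data$block),
    n = dplyr::n(),
    mean_search_rank = mean(.data$search_rank),
    mean_case_rank = mean(.data$case_rank),
    .groups = "drop"
  )
  blocks <- dplyr::arrange(blocks, .data$year, .data$block)
  blocks$block_label <- sprintf("%d-%d",
                                (blocks$block - 1L) * as.integer(block_size) + 1L,
                                (blocks$block - 1L) * as.integer(block_size) +
                                  blocks$n)
  blocks <- blocks[, c("year", "block", "block_label", "n",
                       "mean_search_rank", "mean_case_rank")]
  safe_cor <- function(x, y) {
    if (length(x) < 2L) return(NA_real_)
    dx <- x - mean(x); dy <- y - mean(y)
    den <- sqrt(sum(dx^2) * sum(dy^2))
    if (den == 0) return(NA_real_)
    sum(dx * dy) / den
  }
  pearson <- dplyr::summarise(
    dplyr::group_by(blocks, .data$year),
    pearson_r = safe_cor(.data$mean_search_rank, .data$mean_case_rank),
    .groups = "drop"
  )
  if (anyNA(pearson$pearson_r)) {
    warning("Pearson correlation undefined (fewer than two rank blocks, ",
            "or zero variance across block means)", call. = FALSE)
  }
  list(blocks = blocks, pearson = pearson)
}

#' Adjacent-year intersections of RDG membership
#'
#' For each ranking-difference code and each pair of adjacent years, reports
#' the disease sets carrying that code in each year and the size of their
#' intersection. Large intersections relative to set sizes indicate that the
#' relationship between the two systems' rankings is stable over time.
#'
#' @param diffs A `diff_table` covering at least two years.
#' @return Tibble `rdg`, `year_from`, `year_to`, `n_from`, `n_to`,
#'   `n_intersection`, `members` (list column of the intersecting ids).
#' @export
adjacent_intersections <- function(diffs) {
  years <- sort(unique(diffs$year))
  if (length(years) < 2L) {
    stop("adjacent-year intersections need at least two years", call. = FALSE)
  }
  sets <- lapply(0:2, function(g) {
    lapply(years, function(y) {
      sort(diffs$disease_id[diffs$rdg == g & diffs$year == y])
    })
  })
  rows <- list()
  for (gi in 1:3) {
    for (yi in seq_len(length(years) - 1L)) {
      a <- sets[[gi]][[yi]]
      b <- sets[[gi]][[yi + 1L]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rdg = gi - 1L,
        year_from = years[yi],
        year_to = years[yi + 1L],
        n_from = length(a),
        n_to = length(b),
        n_intersection = length(intersect(a, b)),
        members = list(intersect(a, b))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Top-k rankings and cross-year persistence
#'
#' For each system, lists the diseases ranked in the top `k` in each year,
#' and the persistent set of diseases ranked in the top `k` in *every*
#' analysis year.
#'
#' @param ranks A `rank_table`.
#' @param k Rank threshold.
#' @return List with `per_year` (tibble `system`, `year`, `rank`,
#'   `disease_id`) and `persistent` (tibble `system`, `disease_id`).
#' @export
topk_persistent <- function(ranks, k = 10L) {
  d <- tibble::as_tibble(ranks)
  stopifnot(k <= length(unique(d$disease_id)))
  long <- dplyr::bind_rows(
    tibble::tibble(system = "search", year = d$year, rank = d$search_rank,
                   disease_id = d$disease_id),
    tibble::tibble(system = "case", year = d$year, rank = d$case_rank,
                   disease_id = d$disease_id)
  )
  per_year <- dplyr::arrange(long[long$rank <= k, ], .data$system, .data$year,
                             .data$rank)
  n_years <- length(unique(d$year))
  persistent <- dplyr::summarise(
    dplyr::group_by(per_year, .data$system, .data$disease_id),
    .n = dplyr::n(), .groups = "drop"
  )
  persistent <- persistent[persistent$.n == n_years,
                           c("system", "disease_id")]
  list(per_year = per_year,
       persistent = dplyr::arrange(persistent, .data$system, .data$disease_id))
}
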