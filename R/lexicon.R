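# Lexicon loading, query normalization, keyword matching and annual tallying.

#' Normalize query or keyword text
#'
#' Applies the canonical text normalization used throughout the package:
#' Unicode NFKC normalization, lowercasing (a no-op for uncased scripts such
#' as CJK), collapsing of internal whitespace runs to a single space, and
#' stripping of leading/trailing whitespace. Keywords are normalized once at
#' lexicon load; queries are normalized on the fly during matching, so a
#' keyword matches regardless of case, width variants or stray spacing.
#'
#' @param x Character vector of raw query or keyword strings.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_query(c("  Fabry Disease ", "MARFAN  syndrome"))
#' @export
normalize_query <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Read a disease keyword lexicon
#'
#' Reads a lexicon from JSON: an array of objects with fields `disease_id`,
#' `canonical_name`, `keywords` (non-empty string array) and `excluded`
#' (logical). Entries flagged `excluded` are dropped from the active lexicon
#' (mirroring catalog entries removed from analysis because their definition
#' overlaps a common disease); the dropped ids are retained in the
#' `exclusion_report` attribute. Keywords are normalized once at load and
#' de-duplicated within each entry.
#'
#' @param path Path to the lexicon JSON file.
#' @return A tibble of class `qc_lexicon` with columns `disease_id`,
#'   `canonical_name`, `keywords` (list column of normalized keywords) and
#'   one row per active (non-excluded) disease. The attribute
#'   `exclusion_report` holds a tibble of the dropped entries.
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  if (!is.data.frame(raw)) {
    stop("lexicon JSON must be an array of disease objects", call. = FALSE)
  }
  required <- c("disease_id", "canonical_name", "keywords")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("lexicon is missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"excluded" %in% names(raw)) raw$excluded <- FALSE
  raw$excluded[is.na(raw$excluded)] <- FALSE
  lex <- tibble::tibble(
    disease_id = as.character(raw$disease_id),
    canonical_name = as.character(raw$canonical_name),
    keywords = as.list(raw$keywords),
    excluded = as.logical(raw$excluded)
  )
  as_lexicon(lex)
}

#' Construct a lexicon from a data frame
#'
#' Validates and normalizes an in-memory lexicon. Used by [read_lexicon()]
#' and by the synthetic generator.
#'
#' @param x Data frame with columns `disease_id`, `canonical_name`,
#'   `keywords` (list column), and optionally `excluded`.
#' @return A `qc_lexicon` tibble of active entries (see [read_lexicon()]).
#' @export
as_lexicon <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"excluded" %in% names(x)) x$excluded <- FALSE
  dup <- unique(x$disease_id[duplicated(x$disease_id)])
  if (length(dup)) {
    stop("duplicate disease_id in lexicon: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x$keywords <- lapply(x$keywords, function(kw) {
    kw <- unique(normalize_query(as.character(kw)))
    kw[nzchar(kw)]
  })
  bad <- x$disease_id[vapply(x$keywords, length, integer(1)) == 0L]
  if (length(bad)) {
    stop("empty keyword list after normalization for disease_id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  report <- x[x$excluded, c("disease_id", "canonical_name")]
  active <- x[!x$excluded, c("disease_id", "canonical_name", "keywords")]
  attr(active, "exclusion_report") <- report
  class(active) <- c("qc_lexicon", class(active))
  active
}

#' Report of entries excluded at lexicon load
#'
#' @param lexicon A `qc_lexicon` object.
#' @return Tibble of dropped entries (`disease_id`, `canonical_name`).
#' @export
exclusion_report <- function(lexicon) {
  attr(lexicon, "exclusion_report")
}

# Flat keyword table (keyword, disease_id), one row per normalized keyword.
keyword_table <- function(lexicon) {
  n <- vapply(lexicon$keywords, length, integer(1))
  tibble::tibble(
    keyword = unlist(lexicon$keywords, use.names = FALSE),
    disease_id = rep(lexicon$disease_id, n)
  )
}

#' Match a query against the lexicon
#'
#' A disease matches when at least one of its normalized keywords occurs as a
#' contiguous substring of the normalized query (`mode = "substring"`, the
#' default — real queries append terms such as "symptoms" or "treatment") or
#' when a keyword equals the whole normalized query (`mode = "exact"`).
#' Several keyword hits for one disease yield a single membership; a query
#' may match several diseases.
#'
#' @param text Character vector of raw query strings.
#' @param lexicon A `qc_lexicon` object.
#' @param mode `"substring"` (default) or `"exact"`.
#' @return For a single query, a character vector of matching disease ids
#'   (possibly empty); for several queries, a list of such vectors.
#' @export
match_query <- function(text, lexicon, mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  hits <- match_matrix(normalize_query(text), keyword_table(lexicon), mode)
  out <- lapply(hits, function(ids) sort(unique(as.character(ids))))
  if (length(text) == 1L) out[[1L]] else out
}

# Core matcher: for each normalized query, the disease ids matched.
# Vectorized over queries per keyword, so cost is #keywords passes.
match_matrix <- function(queries_norm, kw_tbl, mode) {
  hits <- vector("list", length(queries_norm))
  for (i in seq_len(nrow(kw_tbl))) {
    sel <- if (mode == "substring") {
      stringi::stri_detect_fixed(queries_norm, kw_tbl$keyword[i])
    } else {
      queries_norm == kw_tbl$keyword[i]
    }
    idx <- which(sel)
    if (length(idx)) {
      for (j in idx) hits[[j]] <- c(hits[[j]], kw_tbl$disease_id[i])
    }
  }
  hits
}

#' Read a case registry file
#'
#' Reads the case-count CSV (`disease_id,year,reported_cases`).
#'
#' @param path Path to the registry CSV.
#' @return Tibble with columns `disease_id`, `year`, `reported_cases`.
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(path, col_types = readr::cols(
    disease_id = readr::col_character(),
    year = readr::col_integer(),
    reported_cases = readr::col_double()
  ))
  tibble::as_tibble(reg)
}

#' Tally queries and registry cases per disease-year
#'
#' Streams a query-log TSV (`year<TAB>query_text`, optionally gzipped) in
#' fixed-size chunks, matches each line against the lexicon, and accumulates
#' per-disease per-year query counts `q[d, y]`, the total annual query volume
#' `Q[y]` (every parseable line in the year, matching or not), and the
#' registry case counts `C[d, y]`. A line matching k diseases increments all
#' k disease counts but `Q[y]` once. Repeated identical queries count
#' separately. Memory use is independent of log length.
#'
#' All (disease, year) cells over the active lexicon and the requested years
#' are present in the result, zero-filled where no line or registry row was
#' seen. Malformed lines, lines in years outside `years`, and registry rows
#' for unknown disease ids are skipped and counted in the report.
#'
#' @param log_path Path to the query-log TSV (`.gz` accepted).
#' @param lexicon A `qc_lexicon` object.
#' @param registry Registry tibble from [read_registry()], a path to the
#'   registry CSV, or `NULL` to leave case counts zero.
#' @param years Integer vector of analysis years.
#' @param mode Matching mode, see [match_query()].
#' @param chunk_size Lines per streamed chunk.
#' @return An object of class `annual_counts`: a list with `counts` (tibble
#'   `disease_id`, `year`, `query_count`, `case_count`), `totals` (tibble
#'   `year`, `total_queries`) and `report` (skip counters).
#' @export
tally_queries <- function(log_path, lexicon, registry = NULL, years,
                          mode = c("substring", "exact"),
                          chunk_size = 50000L) {
  mode <- match.arg(mode)
  years <- sort(unique(as.integer(years)))
  ids <- lexicon$disease_id
  kw_tbl <- keyword_table(lexicon)

  q <- matrix(0L, nrow = length(ids), ncol = length(years),
              dimnames = list(ids, as.character(years)))
  totals <- stats::setNames(numeric(length(years)), as.character(years))
  malformed <- 0L
  out_of_range <- 0L

  con <- if (grepl("\\.gz$", log_path)) gzfile(log_path, "r") else file(log_path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    lines <- readLines(con, n = chunk_size, encoding = "UTF-8", warn = FALSE)
    if (!length(lines)) break
    tab <- stringi::stri_locate_first_fixed(lines, "\t")[, 1L]
    ok <- !is.na(tab)
    yr <- suppressWarnings(as.integer(substr(lines[ok], 1L, tab[ok] - 1L)))
    txt <- substr(lines[ok], tab[ok] + 1L, nchar(lines[ok]))
    bad_year <- is.na(yr)
    malformed <- malformed + sum(!ok) + sum(bad_year)
    yr <- yr[!bad_year]
    txt <- txt[!bad_year]
    in_range <- yr %in% years
    out_of_range <- out_of_range + sum(!in_range)
    yr <- yr[in_range]
    txt <- txt[in_range]
    if (!length(yr)) next
    ycol <- match(yr, years)
    tab_y <- tabulate(ycol, nbins = length(years))
    totals <- totals + tab_y
    hits <- match_matrix(normalize_query(txt), kw_tbl, mode)
    for (j in seq_along(hits)) {
      h <- unique(hits[[j]])
      if (length(h)) {
        rows <- match(h, ids)
        q[rows, ycol[j]] <- q[rows, ycol[j]] + 1L
      }
    }
  }

  cmat <- matrix(0, nrow = length(ids), ncol = length(years),
                 dimnames = dimnames(q))
  unknown_registry <- 0L
  if (!is.null(registry)) {
    if (is.character(registry)) registry <- read_registry(registry)
    keep <- registry$disease_id %in% ids & registry$year %in% years
    unknown_registry <- sum(!registry$disease_id %in% ids)
    if (unknown_registry > 0L) {
      warning(unknown_registry, " registry row(s) with unknown disease_id skipped",
              call. = FALSE)
    }
    reg <- registry[keep, ]
    cmat[cbind(match(reg$disease_id, ids), match(reg$year, years))] <-
      reg$reported_cases
  }

  counts <- tidyr::expand_grid(disease_id = ids, year = years)
  counts$query_count <- as.integer(q[cbind(match(counts$disease_id, ids),
                                           match(counts$year, years))])
  counts$case_count <- cmat[cbind(match(counts$disease_id, ids),
                                  match(counts$year, years))]
  structure(
    list(
      counts = counts,
      totals = tibble::tibble(year = years, total_queries = as.numeric(totals)),
      report = list(malformed_lines = malformed,
                    lines_outside_years = out_of_range,
                    unknown_registry_rows = unknown_registry)
    ),
    class = "annual_counts"
  )
}

#' @export
print.annual_counts <- function(x, ...) {
  cat("<annual_counts> ", length(unique(x$counts$disease_id)), " diseases x ",
      nrow(x$totals), " years\n", sep = "")
  cat("total queries per year:\n")
  print(x$totals)
  rep <- x$report
  cat("skipped: ", rep$malformed_lines, " malformed, ",
      rep$lines_outside_years, " outside years, ",
      rep$unknown_registry_rows, " unknown registry rows\n", sep = "")
  invisible(x)
}
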