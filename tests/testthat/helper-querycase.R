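# Shared fixtures and independent oracles for the test suite.

# A small, fast scenario used by most synthetic-data tests.
tiny_scenario <- function(seed = 42L, n_diseases = 12L, ...) {
  years <- 2016:2018
  defaults <- list(
    n_diseases = n_diseases,
    years = years,
    population = stats::setNames(c(1.00e6, 1.01e6, 1.02e6), years),
    prevalence_logmu = log(2e-4),
    prevalence_logsigma = 1,
    search_rate = 0.5,
    publicity_spike_prob = 0.2,
    publicity_spike_scale = 5,
    reporting_alpha = 2,
    reporting_beta = 2,
    background_queries = stats::setNames(rep(200, length(years)), years),
    cutoff = 3L,
    n_excluded = 0L,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# Write a lexicon JSON from parallel vectors; keywords is a list of
# character vectors.
write_lexicon_json <- function(path, disease_id, keywords,
                               canonical_name = disease_id,
                               excluded = rep(FALSE, length(disease_id))) {
  entries <- lapply(seq_along(disease_id), function(i) {
    list(disease_id = disease_id[i],
         canonical_name = canonical_name[i],
         keywords = as.list(keywords[[i]]),
         excluded = excluded[i])
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE)
  path
}

# Independent ranking oracle: a disease's rank is one plus the number of
# diseases that beat it (larger value, or equal value and smaller id).
oracle_rank <- function(value, id) {
  vapply(seq_along(value), function(i) {
    1L + sum(value > value[i] | (value == value[i] & id < id[i]))
  }, integer(1))
}

# Independent RDG coding oracle via interval lookup.
oracle_rdg <- function(delta, cutoff) {
  vapply(delta, function(d) {
    if (d < -cutoff) 0L else if (d > cutoff) 2L else 1L
  }, integer(1))
}

# Independent blocked-consistency oracle: explicit loops and the textbook
# Pearson sum formula.
oracle_blocks <- function(search_rank, case_rank, block_size) {
  ord <- order(search_rank)
  sr <- search_rank[ord]
  cr <- case_rank[ord]
  n_blocks <- ceiling(length(sr) / block_size)
  ms <- mc <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):min(b * block_size, length(sr))
    ms[b] <- sum(sr[idx]) / length(idx)
    mc[b] <- sum(cr[idx]) / length(idx)
  }
  r <- NA_real_
  if (n_blocks >= 2L) {
    x <- ms - mean(ms); y <- mc - mean(mc)
    den <- sqrt(sum(x^2) * sum(y^2))
    if (den > 0) r <- sum(x * y) / den
  }
  list(mean_search = ms, mean_case = mc, pearson_r = r)
}

# Independent least-squares oracle with sum-to-zero coding built by hand:
# returns the full-level coefficient table (every factor level plus the
# intercept) with normal-equation standard errors.
oracle_sum_lm <- function(year, group, y) {
  year <- as.factor(year); group <- as.factor(group)
  yl <- levels(year); gl <- levels(group)
  n <- length(y)
  sum_cols <- function(f, lv) {
    k <- length(lv)
    out <- matrix(0, n, k - 1L)
    for (j in seq_len(k - 1L)) {
      out[, j] <- ifelse(f == lv[j], 1, ifelse(f == lv[k], -1, 0))
    }
    out
  }
  X <- cbind(1, sum_cols(year, yl), if (length(gl) > 1L) sum_cols(group, gl))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - ncol(X))
  V <- sigma2 * solve(XtX)
  # expand to full levels: last level coefficient = -sum(others)
  expand <- function(idx) {
    b <- beta[idx]
    se <- sqrt(diag(V)[idx])
    ones <- rep(1, length(idx))
    b_last <- -sum(b)
    se_last <- sqrt(drop(t(ones) %*% V[idx, idx, drop = FALSE] %*% ones))
    list(coef = c(b, b_last), se = c(se, se_last))
  }
  yi <- 1L + seq_len(length(yl) - 1L)
  out_y <- expand(yi)
  res <- data.frame(term = c(paste0("year=", yl)),
                    coefficient = out_y$coef, std_error = out_y$se)
  if (length(gl) > 1L) {
    gi <- max(yi) + seq_len(length(gl) - 1L)
    out_g <- expand(gi)
    res <- rbind(res, data.frame(term = paste0("disease_", gl),
                                 coefficient = out_g$coef,
                                 std_error = out_g$se))
  }
  rbind(res, data.frame(term = "intercept", coefficient = beta[1L],
                        std_error = sqrt(V[1L, 1L])))
}

# A hand-built regression design with known group assignment, for
# coefficient-recovery tests (bypasses the baseline-RDG grouping).
manual_design <- function(disease_id, year, group, rdg) {
  structure(
    list(data = tibble::tibble(disease_id = disease_id,
                               year = factor(year),
                               group = factor(group),
                               rdg = as.numeric(rdg)),
         baseline_year = min(as.integer(as.character(year))),
         disease_factor = "group",
         n_obs = length(rdg)),
    class = "rdg_design"
  )
}

# Random rank-table instance for property tests.
random_rank_table <- function(n_diseases, years) {
  ids <- sprintf("D%02d", seq_len(n_diseases))
  out <- list()
  for (y in years) {
    out[[as.character(y)]] <- tibble::tibble(
      disease_id = ids, year = y,
      search_rank = sample(n_diseases),
      case_rank = sample(n_diseases)
    )
  }
  tb <- dplyr::bind_rows(out)
  class(tb) <- c("rank_table", class(tb))
  tb
}
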