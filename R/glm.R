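# Year/disease-group GLM on RDG codes and the two-category classification.

#' Build the RDG regression design
#'
#' Observations are disease-years; the response is the numeric
#' ranking-difference code (0, 1 or 2); the explanatory factors are the
#' calendar year and a disease factor. By default the disease factor is the
#' disease's ranking-difference group in a baseline year (the earliest year
#' unless specified), giving three disease-group levels; set
#' `disease_factor = "disease"` for one dummy per disease instead.
#'
#' @param diffs A `diff_table` from [ranking_difference()] covering at least
#'   two years.
#' @param baseline_year Year whose RDG defines each disease's group; default
#'   the earliest year in `diffs`.
#' @param disease_factor `"group"` (baseline-RDG groups, default) or
#'   `"disease"` (per-disease dummies).
#' @return List of class `rdg_design` with `data` (tibble `disease_id`,
#'   `year`, `group`, `rdg`), `baseline_year`, `disease_factor` and `n_obs`.
#'   Disease-group levels with no members are dropped with a warning.
#' @export
build_design <- function(diffs, baseline_year = NULL,
                         disease_factor = c("group", "disease")) {
  disease_factor <- match.arg(disease_factor)
  years <- sort(unique(diffs$year))
  if (length(years) < 2L) {
    stop("RDG design needs at least two years", call. = FALSE)
  }
  if (is.null(baseline_year)) baseline_year <- years[1L]
  if (!baseline_year %in% years) {
    stop("baseline year ", baseline_year, " not present in diffs", call. = FALSE)
  }
  d <- tibble::as_tibble(diffs)[, c("disease_id", "year", "rdg")]
  if (disease_factor == "group") {
    base <- d[d$year == baseline_year, c("disease_id", "rdg")]
    names(base)[2] <- "baseline_rdg"
    present <- sort(unique(base$baseline_rdg))
    empty <- setdiff(0:2, present)
    if (length(empty)) {
      warning("disease-group level(s) with no members dropped: ",
              paste(empty, collapse = ", "), call. = FALSE)
    }
    d <- dplyr::left_join(d, base, by = "disease_id")
    d$group <- factor(paste0("group", d$baseline_rdg),
                      levels = paste0("group", present))
    d$baseline_rdg <- NULL
  } else {
    d$group <- factor(d$disease_id)
  }
  d$year <- factor(d$year, levels = years)
  d$rdg <- as.numeric(d$rdg)
  structure(
    list(data = d[, c("disease_id", "year", "group", "rdg")],
         baseline_year = baseline_year,
         disease_factor = disease_factor,
         n_obs = nrow(d)),
    class = "rdg_design"
  )
}

# Full-level coefficient table for one sum-coded factor: the fitted model
# carries k-1 deviation coefficients; the last level's coefficient is minus
# their sum, with variance 1' V 1 over the factor's coefficient block.
sum_code_levels <- function(fit, prefix, levels) {
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  idx <- grep(paste0("^", prefix), names(cf))
  stopifnot(length(idx) == length(levels) - 1L)
  beta <- c(cf[idx], -sum(cf[idx]))
  ones <- rep(1, length(idx))
  se_last <- sqrt(drop(t(ones) %*% V[idx, idx, drop = FALSE] %*% ones))
  se <- c(sqrt(diag(V)[idx]), se_last)
  tibble::tibble(level = levels, coefficient = unname(beta),
                 std_error = unname(se))
}

#' Fit the Gaussian GLM of RDG on year and disease factors
#'
#' Fits `rdg ~ year + group` with a Gaussian family and identity link
#' (ordinary least squares). With the default sum-to-zero effects coding,
#' every factor level carries a coefficient (a deviation from the grand
#' mean), the omitted level being reconstructed as minus the sum of the
#' others with the matching standard error, and the intercept equals the
#' grand mean RDG on a balanced panel. Treatment (reference-level) coding is
#' available via `coding = "treatment"`. Wald `z = coefficient / std_error`
#' and two-sided normal p-values are reported per term.
#'
#' @param design An `rdg_design` from [build_design()].
#' @param coding `"effects"` (sum-to-zero, default) or `"treatment"`.
#' @return Object of class `rdg_glm_fit`: list with `table` (tibble `term`,
#'   `coefficient`, `std_error`, `z`, `p`), `coding`, `n_obs` and the
#'   underlying `fit`.
#' @export
fit_rdg_glm <- function(design, coding = c("effects", "treatment")) {
  coding <- match.arg(coding)
  stopifnot(inherits(design, "rdg_design"))
  d <- design$data
  contr <- if (coding == "effects") "contr.sum" else "contr.treatment"
  has_group <- nlevels(d$group) > 1L
  form <- if (has_group) rdg ~ year + group else rdg ~ year
  fit <- stats::glm(form, data = d, family = stats::gaussian(),
                    contrasts = stats::setNames(
                      rep(list(contr), 1L + has_group),
                      c("year", if (has_group) "group")))
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (coding == "effects") {
    yr <- sum_code_levels(fit, "year", levels(d$year))
    yr$term <- paste0("year=", yr$level)
    rows <- yr
    if (has_group) {
      gp <- sum_code_levels(fit, "group", levels(d$group))
      gp$term <- paste0("disease_", gp$level)
      rows <- dplyr::bind_rows(yr, gp)
    }
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tab <- dplyr::bind_rows(
      rows[, c("term", "coefficient", "std_error")],
      tibble::tibble(term = "intercept",
                     coefficient = unname(cf["(Intercept)"]),
                     std_error = unname(se["(Intercept)"]))
    )
  } else {
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tab <- tibble::tibble(term = names(cf), coefficient = unname(cf),
                          std_error = unname(se))
  }
  tab$z <- tab$coefficient / tab$std_error
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  structure(
    list(table = tab, coding = coding, n_obs = design$n_obs, fit = fit),
    class = "rdg_glm_fit"
  )
}

#' @export
print.rdg_glm_fit <- function(x, ...) {
  cat("<rdg_glm_fit> Gaussian identity-link GLM, ", x$coding,
      " coding, n = ", x$n_obs, "\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' Classify diseases into two categories
#'
#' Each disease is reduced to a single ranking-difference code by the chosen
#' policy and mapped to a category: code 0 (high search rank position but
#' low registry rank position — publicity inflation and/or under-diagnosis
#' suspected) gives category 2; codes 1 (consistent rankings) and 2 (high in
#' the registry but low in search) give category 1, for which the registry is
#' considered relatively comprehensive.
#'
#' The default policy takes the majority code across the analysis years; on a
#' tie, the tied code observed most recently wins. `policy = "baseline"`
#' instead uses the code in `baseline_year` (default: earliest year).
#'
#' @param diffs A `diff_table` from [ranking_difference()].
#' @param policy `"majority"` (default) or `"baseline"`.
#' @param baseline_year Year used by the baseline policy.
#' @return Tibble `disease_id`, `rdg_code`, `category`, with the cutoff and
#'   policy stored as attributes.
#' @export
classify_diseases <- function(diffs, policy = c("majority", "baseline"),
                              baseline_year = NULL) {
  policy <- match.arg(policy)
  d <- tibble::as_tibble(diffs)[, c("disease_id", "year", "rdg")]
  if (policy == "baseline") {
    years <- sort(unique(d$year))
    if (is.null(baseline_year)) baseline_year <- years[1L]
    if (!baseline_year %in% years) {
      stop("baseline year ", baseline_year, " not present in diffs",
           call. = FALSE)
    }
    per <- d[d$year == baseline_year, c("disease_id", "rdg")]
    names(per)[2] <- "rdg_code"
  } else {
    majority_code <- function(codes, years) {
      tab <- table(codes)
      top <- as.integer(names(tab)[tab == max(tab)])
      if (length(top) == 1L) return(top)
      recent <- codes[order(years, decreasing = TRUE)]
      recent[recent %in% top][1L]
    }
    per <- dplyr::summarise(dplyr::group_by(d, .data$disease_id),
                            rdg_code = majority_code(.data$rdg, .data$year),
                            .groups = "drop")
  }
  per$category <- ifelse(per$rdg_code == 0L, 2L, 1L)
  per <- dplyr::arrange(per, .data$disease_id)
  attr(per, "cutoff") <- attr(diffs, "cutoff")
  attr(per, "policy") <- policy
  per
}
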