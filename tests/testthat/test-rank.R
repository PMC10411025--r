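tbl_values <- function(values_by_year) {
  # values_by_year: named list year -> named numeric vector (ids -> value)
  out <- lapply(names(values_by_year), function(y) {
    v <- values_by_year[[y]]
    tibble::tibble(disease_id = names(v), year = as.integer(y), value = unname(v))
  })
  dplyr::bind_rows(out)
}

test_that("annual ranking sorts descending with id tie-breaks", {
  v <- tbl_values(list(`2016` = c(A = 10, B = 30, C = 20)))
  r <- rank_annual(v, "value")
  expect_equal(r$rank[match(c("B", "C", "A"), r$disease_id)], 1:3)

  vt <- tbl_values(list(`2016` = c(A = 10, B = 10, C = 5)))
  rt <- rank_annual(vt, "value")
  expect_equal(rt$rank[match(c("A", "B", "C"), rt$disease_id)], 1:3)

  two <- dplyr::bind_rows(v, tbl_values(list(`2017` = c(A = 1, B = 2, C = 3))))
  miss <- two[-1, ]   # A has no value in 2016
  expect_error(rank_annual(miss, "value"), "missing value cells")
})

test_that("ranking matches the brute-force oracle on random instances", {
  set.seed(7)
  for (i in 1:8) {
    D <- sample(3:10, 1)
    ids <- sprintf("D%02d", seq_len(D))
    years <- 2016:2018
    v <- dplyr::bind_rows(lapply(years, function(y) {
      tibble::tibble(disease_id = ids, year = y,
                     value = sample(0:5, D, replace = TRUE))  # forces ties
    }))
    r <- rank_annual(v, "value")
    for (y in years) {
      sel <- v$year == y
      expect_equal(r$rank[r$year == y][match(v$disease_id[sel],
                                             r$disease_id[r$year == y])],
                   oracle_rank(v$value[sel], v$disease_id[sel]))
      expect_setequal(r$rank[r$year == y], seq_len(D))  # strict permutation
    }
  }
})

test_that("ranking differences use closed interval boundaries", {
  ranks <- tibble::tibble(
    disease_id = c("A", "B", "C"),
    year = 2016L,
    search_rank = c(5L, 1L, 3L),
    case_rank = c(25L, 30L, 3L)
  )
  d <- ranking_difference(ranks, cutoff = 20)
  expect_equal(d$diff, c(-20L, -29L, 0L))
  expect_equal(d$rdg, c(1L, 0L, 1L))
  expect_equal(attr(d, "cutoff"), 20L)
})

test_that("interval coding maps the boundary deltas exactly", {
  deltas <- c(-21L, -20L, 0L, 20L, 21L)
  ranks <- tibble::tibble(
    disease_id = sprintf("D%d", seq_along(deltas)),
    year = 2016L,
    search_rank = 30L + deltas,
    case_rank = 30L
  )
  d <- ranking_difference(ranks, cutoff = 20)
  expect_equal(d$rdg, c(0L, 1L, 1L, 1L, 2L))
})

test_that("swapping the systems negates delta and swaps codes 0 and 2", {
  set.seed(21)
  for (i in 1:4) {
    rt <- random_rank_table(30L, 2016:2017)
    d1 <- ranking_difference(rt, cutoff = 5)
    swapped <- rt
    names(swapped)[match(c("search_rank", "case_rank"), names(swapped))] <-
      c("case_rank", "search_rank")
    d2 <- ranking_difference(swapped, cutoff = 5)
    expect_equal(d2$diff, -d1$diff)
    expect_equal(d2$rdg, c(2L, 1L, 0L)[d1$rdg + 1L])
  }
})

test_that("raising the cutoff never evicts a disease from the central group", {
  set.seed(33)
  rt <- random_rank_table(40L, 2016:2018)
  for (cuts in list(c(5, 10), c(10, 20), c(3, 30))) {
    lo <- ranking_difference(rt, cutoff = cuts[1])
    hi <- ranking_difference(rt, cutoff = cuts[2])
    expect_true(all(hi$rdg[lo$rdg == 1L] == 1L))
  }
})

test_that("per-year RDG counts partition the diseases", {
  rt <- random_rank_table(25L, 2016:2019)
  d <- ranking_difference(rt, cutoff = 4)
  cnt <- rdg_year_counts(d)
  expect_equal(nrow(cnt), 4L * 3L)  # every (year, code) cell, zero-filled
  sums <- tapply(cnt$n, cnt$year, sum)
  expect_true(all(sums == 25L))
  # each disease-year carries exactly one code
  expect_true(all(d$rdg %in% 0:2))

  same <- tibble::tibble(disease_id = c("A", "B", "C"), year = 2016L,
                         search_rank = 1:3, case_rank = 1:3)
  cnt2 <- rdg_year_counts(ranking_difference(same, cutoff = 20))
  expect_equal(cnt2$n, c(0L, 3L, 0L))
})

test_that("blocked consistency reproduces concordant and reversed rankings", {
  D <- 120L
  ids <- sprintf("D%03d", seq_len(D))
  conc <- tibble::tibble(disease_id = ids, year = 2016L,
                         search_rank = seq_len(D), case_rank = seq_len(D))
  gc <- grouped_consistency(conc, block_size = 20)
  expect_equal(gc$blocks$mean_case_rank, gc$blocks$mean_search_rank)
  expect_equal(gc$pearson$pearson_r, 1)
  expect_equal(gc$blocks$block_label,
               c("1-20", "21-40", "41-60", "61-80", "81-100", "101-120"))

  rev <- conc
  rev$case_rank <- D + 1L - rev$search_rank
  expect_equal(grouped_consistency(rev, block_size = 20)$pearson$pearson_r, -1)
})

test_that("block means average the members' case ranks", {
  D <- 120L
  ids <- sprintf("D%03d", seq_len(D))
  set.seed(5)
  case <- seq_len(D)
  case[1:20] <- sample(case[1:20])   # permute within the first block
  d <- tibble::tibble(disease_id = ids, year = 2016L,
                      search_rank = seq_len(D), case_rank = case)
  gc <- grouped_consistency(d, block_size = 20)
  expect_equal(gc$blocks$mean_case_rank[1], 10.5)
})

test_that("blocked consistency matches the loop oracle, ragged blocks included", {
  set.seed(9)
  for (i in 1:8) {
    D <- sample(5:10, 1)
    bs <- sample(2:4, 1)
    rt <- random_rank_table(D, 2016:2017)
    gc <- suppressWarnings(grouped_consistency(rt, block_size = bs))
    for (y in 2016:2017) {
      sel <- rt$year == y
      orc <- oracle_blocks(rt$search_rank[sel], rt$case_rank[sel], bs)
      b <- gc$blocks[gc$blocks$year == y, ]
      expect_equal(b$mean_search_rank, orc$mean_search)
      expect_equal(b$mean_case_rank, orc$mean_case)
      expect_equal(gc$pearson$pearson_r[gc$pearson$year == y], orc$pearson_r)
    }
  }
})

test_that("fewer than two blocks yields NA correlation with a warning", {
  rt <- random_rank_table(3L, 2016:2016)
  expect_warning(gc <- grouped_consistency(rt, block_size = 10),
                 "fewer than two rank blocks")
  expect_true(is.na(gc$pearson$pearson_r))
})

test_that("pearson r is invariant under common affine transforms", {
  set.seed(13)
  rt <- random_rank_table(40L, 2016:2016)
  gc <- grouped_consistency(rt, block_size = 10)
  b <- gc$blocks
  r0 <- gc$pearson$pearson_r
  x <- 3 * b$mean_search_rank + 7
  y <- 3 * b$mean_case_rank + 7
  expect_equal(stats::cor(x, y), r0)
})

test_that("adjacent-year intersections match a set oracle", {
  d <- dplyr::bind_rows(
    tibble::tibble(disease_id = c("A", "B", "C"), year = 2016L,
                   rdg = c(1L, 1L, 0L)),
    tibble::tibble(disease_id = c("A", "B", "C"), year = 2017L,
                   rdg = c(0L, 1L, 1L))
  )
  it <- adjacent_intersections(d)
  g1 <- it[it$rdg == 1L, ]
  expect_equal(g1$n_intersection, 1L)   # {A,B} vs {B,C}
  expect_equal(g1$members[[1]], "B")

  # identical assignments: intersection equals the set size
  d2 <- d[d$year == 2016L, ]
  d3 <- d2; d3$year <- 2017L
  it2 <- adjacent_intersections(dplyr::bind_rows(d2, d3))
  expect_equal(it2$n_intersection, it2$n_from)

  expect_error(adjacent_intersections(d2), "at least two years")

  set.seed(77)
  for (i in 1:8) {
    D <- sample(4:10, 1)
    years <- 2016:2019
    dd <- dplyr::bind_rows(lapply(years, function(y) {
      tibble::tibble(disease_id = sprintf("D%02d", seq_len(D)), year = y,
                     rdg = sample(0:2, D, replace = TRUE))
    }))
    it <- adjacent_intersections(dd)
    for (r in seq_len(nrow(it))) {
      a <- dd$disease_id[dd$year == it$year_from[r] & dd$rdg == it$rdg[r]]
      b <- dd$disease_id[dd$year == it$year_to[r] & dd$rdg == it$rdg[r]]
      expect_equal(it$n_intersection[r], length(intersect(a, b)))
      expect_equal(it$n_from[r], length(a))
      expect_equal(it$n_to[r], length(b))
    }
  }
})

test_that("top-k persistence requires membership in every year", {
  D <- 15L
  ids <- sprintf("D%02d", seq_len(D))
  const <- dplyr::bind_rows(lapply(2016:2019, function(y) {
    tibble::tibble(disease_id = ids, year = y,
                   search_rank = seq_len(D), case_rank = seq_len(D))
  }))
  tk <- topk_persistent(const, k = 10)
  expect_equal(sum(tk$persistent$system == "search"), 10L)
  expect_equal(sum(tk$persistent$system == "case"), 10L)

  # drop one disease out of the top 10 in a single year
  moved <- const
  sel16 <- moved$year == 2016L
  r <- moved$search_rank[sel16]
  r[match(c("D05", "D11"), moved$disease_id[sel16])] <- c(11L, 5L)
  moved$search_rank[sel16] <- r
  tk2 <- topk_persistent(moved, k = 10)
  pers <- tk2$persistent$disease_id[tk2$persistent$system == "search"]
  expect_false("D05" %in% pers)  # top-10 in 3 of 4 years only
  expect_false("D11" %in% pers)
  expect_equal(length(pers), 9L)
})
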