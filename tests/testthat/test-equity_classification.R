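toy_tracts <- function(values) {
  # six components moving together except income, which opposes them
  n <- length(values)
  tibble::tibble(
    tract_id = seq_len(n),
    crowded_housing = values, poverty = values, unemployment = values,
    low_education = values, dependents = values,
    per_capita_income = 1000 * (max(values) - values)
  )
}

test_that("hardship index is 0/50/100 at the extremes and midpoint", {
  tr <- toy_tracts(c(0, 50, 100))
  idx <- hardship_index(tr)
  expect_equal(idx, c(0, 50, 100))

  # constant component contributes zero, with a warning
  tr$dependents <- 7
  expect_warning(idx2 <- hardship_index(tr), "constant")
  expect_equal(idx2, c(0, 50, 100) * 5 / 6)

  expect_error(hardship_index(tr[, -2]), "missing hardship components")
})

test_that("income moves the index in the opposite direction", {
  tr <- toy_tracts(c(10, 20, 30))
  richer <- tr
  richer$per_capita_income <- richer$per_capita_income + c(0, 0, 1e5)
  expect_lt(hardship_index(richer)[3], hardship_index(tr)[3])
})

test_that("tercile classification splits ranks with the remainder rule", {
  lab <- tercile_classify(1:9)
  expect_equal(as.character(lab), rep(c("low", "medium", "high"), each = 3))

  # n = 10: remainder goes to the lower group first -> sizes 4/3/3
  lab10 <- tercile_classify(10:1)
  expect_equal(unname(table(lab10)), c(4L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(unname(table(tercile_classify(1:11))), c(4L, 4L, 3L),
               ignore_attr = TRUE)

  # all-equal values: stable split by unit id
  tied <- tercile_classify(rep(5, 9), ids = 1:9)
  expect_equal(as.character(tied), rep(c("low", "medium", "high"), each = 3))

  expect_error(tercile_classify(c(1, 2)), "at least 3")
})

test_that("terciles are invariant under strictly monotone transforms", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(3:200, 1)
      v <- stats::rnorm(n)
      base <- tercile_classify(v, ids = seq_len(n))
      expect_identical(tercile_classify(exp(v), ids = seq_len(n)), base)
      expect_identical(tercile_classify(v^3, ids = seq_len(n)), base)
      expect_identical(tercile_classify(2 * v + 10, ids = seq_len(n)), base)
    }
  })
})

test_that("tract aggregation averages blocks, optionally by population", {
  blocks <- tibble::tibble(
    block_id = 1:3, tract_id = c(1L, 1L, 2L),
    population = c(10L, 30L, 5L)
  )
  access <- tibble::tibble(
    block_id = 1:3, program_type = "ALL",
    a_2sfca = c(2, 4, 9), nearest_minutes = c(5, 15, Inf),
    n_within = c(1L, 2L, 0L)
  )
  ta <- aggregate_to_tract(access, blocks)
  expect_equal(ta$mean_a_2sfca, c(3, 9))  # single-block tract = identity
  expect_equal(ta$mean_nearest_minutes, c(10, NA))  # unreachable excluded
  expect_equal(ta$n_unreachable_blocks, c(0L, 1L))

  tw <- aggregate_to_tract(access, blocks, weighting = "population")
  expect_equal(tw$mean_a_2sfca[1], (2 * 10 + 4 * 30) / 40)

  # stacked per-program rows aggregate separately, never pooled
  stacked <- rbind(access, transform(access, program_type = "HIV_STI",
                                     a_2sfca = a_2sfca * 10))
  ts <- aggregate_to_tract(stacked, blocks)
  expect_equal(nrow(ts), 4)
  expect_equal(ts$mean_a_2sfca[ts$program_type == "ALL"],
               ta$mean_a_2sfca)
  expect_equal(ts$mean_a_2sfca[ts$program_type == "HIV_STI"],
               ta$mean_a_2sfca * 10)

  # aggregation sanity: block min <= tract mean <= block max
  city <- simulate_city(small_config())
  tt <- travel_time_matrix(
    city$network, city$blocks$node_id, city$sites$node_id,
    origin_ids = city$blocks$block_id, dest_ids = city$sites$site_id
  )
  alloc <- allocate_contracts(filter_contracts(city$contracts, city$sites),
                              city$sites)
  acc <- block_access(tt, alloc,
                      stats::setNames(city$blocks$population,
                                      city$blocks$block_id))
  ta2 <- aggregate_to_tract(acc, city$blocks)
  rngs <- tapply(acc$a_2sfca, city$blocks$tract_id[match(acc$block_id, city$blocks$block_id)], range)
  for (i in seq_len(nrow(ta2))) {
    r <- rngs[[as.character(ta2$tract_id[i])]]
    expect_gte(ta2$mean_a_2sfca[i], r[1])
    expect_lte(ta2$mean_a_2sfca[i], r[2])
  }
})

test_that("group summaries report per-group means and conserve funding", {
  hardship <- tibble::tibble(
    tract_id = 1:3,
    hardship_tercile = factor(c("low", "medium", "high"),
                              levels = c("low", "medium", "high"))
  )
  ta <- tibble::tibble(
    tract_id = 1:3, program_type = "ALL",
    mean_a_2sfca = c(4, 2, 6), mean_nearest_minutes = c(10, 20, 5),
    mean_n_within = c(1, 0.5, 2), percent_with_access = c(1, 0.5, 1)
  )
  af <- tibble::tibble(area_id = 1:3, dollars = c(100, 50, 150))
  pop <- tibble::tibble(tract_id = 1:3, population = c(10, 10, 30))
  gs <- group_summary(ta, hardship, af, pop)
  expect_equal(gs$mean_a_2sfca, c(4, 2, 6))
  expect_equal(gs$median_a_2sfca, gs$mean_a_2sfca)  # single-tract groups
  expect_equal(sum(gs$funding_share_pct), 100)
  expect_equal(sum(gs$funding_dollars), sum(af$dollars))
  expect_equal(gs$dollars_per_capita, c(10, 5, 5))

  # identical metric everywhere: every group mean = median = v
  ta$mean_a_2sfca <- 7
  gs2 <- group_summary(ta, hardship, af, pop)
  expect_true(all(gs2$mean_a_2sfca == 7) && all(gs2$median_a_2sfca == 7))
})

test_that("cross-classification counts tracts with consistent marginals", {
  hardship <- tibble::tibble(
    tract_id = 1:9,
    hardship_tercile = tercile_classify(1:9)
  )
  aligned <- tibble::tibble(
    tract_id = 1:9, mean_a_2sfca = 1:9,
    spending_tercile = tercile_classify(1:9, labels = c("lower", "medium", "higher"))
  )
  ct <- cross_classify(hardship, aligned)
  expect_equal(sum(ct), 9)
  expect_true(all(diag(ct) == 3) && sum(diag(ct)) == 9)  # perfectly aligned
  expect_equal(unname(rowSums(ct)), c(3, 3, 3), ignore_attr = TRUE)
  expect_equal(unname(colSums(ct)), c(3, 3, 3), ignore_attr = TRUE)

  # independent labels put about 2/3 of the mass off the diagonal
  withr::with_seed(31, {
    n <- 9000
    h <- tibble::tibble(
      tract_id = 1:n,
      hardship_tercile = tercile_classify(stats::rnorm(n))
    )
    s <- tibble::tibble(
      tract_id = 1:n,
      spending_tercile = tercile_classify(stats::rnorm(n),
                                          labels = c("lower", "medium", "higher"))
    )
    ct2 <- cross_classify(h, s)
    off_diag <- 1 - sum(diag(ct2)) / n
    expect_lt(abs(off_diag - 2 / 3), 0.02)
  })
})

test_that("spending terciles classify tracts by mean funded access", {
  ta <- tibble::tibble(tract_id = 1:6, program_type = "ALL",
                       mean_a_2sfca = c(5, 1, 9, 2, 8, 3))
  st <- spending_terciles(ta)
  expect_equal(as.character(st$spending_tercile),
               c("medium", "lower", "higher", "lower", "higher", "medium"))
})
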