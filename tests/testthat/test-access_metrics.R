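test_that("supply ratios divide dollars by reachable population", {
  # single site, one block of 50 people within reach: R = 100 / 50 = 2
  tt <- travel_matrix(matrix(10, 1, 1, dimnames = list("1", "1")))
  r <- supply_ratio(tibble::tibble(site_id = 1L, supply = 100),
                    tt, c(`1` = 50), T_minutes = 30)
  expect_equal(r$R_j, 2)
  expect_false(r$zero_demand)

  # nobody within reach: R = 0 with the zero-demand flag
  far <- travel_matrix(matrix(45, 1, 1, dimnames = list("1", "1")))
  r0 <- supply_ratio(tibble::tibble(site_id = 1L, supply = 100),
                     far, c(`1` = 50), T_minutes = 30)
  expect_equal(r0$R_j, 0)
  expect_true(r0$zero_demand)

  expect_error(
    supply_ratio(tibble::tibble(site_id = 1L, supply = 1), tt, c(`1` = -2), 30),
    "non-negative"
  )
})

test_that("the worked 3-block/2-site instance reproduces R and A exactly", {
  w <- worked_2sfca_instance()
  r <- supply_ratio(w$supply, w$tt, w$populations, T_minutes = 30)
  expect_identical(r$R_j, c(4.0, 1.2))
  expect_identical(r$reachable_population, c(30, 50))
  a <- access_2sfca(r, w$tt, T_minutes = 30)
  expect_identical(a$a_2sfca, c(4.0, 5.2, 1.2))
})

test_that("block access sums only ratios of in-walkshed sites", {
  minutes <- matrix(c(10, 40), 1, 2, dimnames = list("1", c("1", "2")))
  tt <- travel_matrix(minutes)
  ratios <- tibble::tibble(site_id = 1:2, supply = c(1, 1),
                           reachable_population = c(1, 1),
                           R_j = c(2.0, 9.9), zero_demand = FALSE)
  a <- access_2sfca(ratios, tt, 30)
  expect_equal(a$a_2sfca, 2.0)  # only the reachable site contributes

  none <- travel_matrix(matrix(c(50, 40), 1, 2,
                               dimnames = list("1", c("1", "2"))))
  expect_equal(access_2sfca(ratios, none, 30)$a_2sfca, 0)

  expect_error(
    access_2sfca(tibble::tibble(site_id = 9L, R_j = 1), tt, 30),
    "absent"
  )
})

test_that("nearest-time and count metrics follow the walkshed rules", {
  tt <- travel_matrix(matrix(c(12, 45, 7), 1, 3,
                             dimnames = list("1", c("a", "b", "c"))))
  expect_equal(time_to_nearest(tt)$nearest_minutes, 7)

  colocated <- travel_matrix(matrix(c(0, 3), 1, 2,
                                    dimnames = list("1", c("a", "b"))))
  expect_equal(time_to_nearest(colocated)$nearest_minutes, 0)

  isolated <- travel_matrix(matrix(Inf, 1, 2, dimnames = list("1", c("a", "b"))))
  expect_equal(time_to_nearest(isolated)$nearest_minutes, Inf)
  expect_equal(count_within(isolated, 30)$n_within, 0L)

  # strict boundary: 30.0 is out, 29.9 is in
  edge <- travel_matrix(matrix(c(10, 29.9, 30.0), 1, 3,
                               dimnames = list("1", c("a", "b", "c"))))
  expect_equal(count_within(edge, 30)$n_within, 2L)
  expect_equal(count_within(colocated, 30)$n_within, 2L)  # all sites at t < T
})

test_that("population coverage fraction weighs blocks by population", {
  minutes <- matrix(c(40, 10), 2, 1, dimnames = list(c("1", "2"), "s"))
  tt <- travel_matrix(minutes)
  expect_equal(percent_with_access(tt, c(`1` = 10, `2` = 30), 30), 0.75)
  expect_equal(percent_with_access(tt, c(`1` = 10, `2` = 30), 45), 1.0)
  expect_equal(percent_with_access(tt, c(`1` = 10, `2` = 30), 5), 0.0)
  expect_true(is.na(percent_with_access(tt, c(`1` = 0, `2` = 0), 30)))
})

test_that("2SFCA conserves dollars over sites with populated catchments", {
  city <- simulate_city(small_config())
  tt <- travel_time_matrix(
    city$network, city$blocks$node_id, city$sites$node_id,
    origin_ids = city$blocks$block_id, dest_ids = city$sites$site_id
  )
  kept <- filter_contracts(city$contracts, city$sites)
  alloc <- allocate_contracts(kept, city$sites)
  pops <- stats::setNames(city$blocks$population, city$blocks$block_id)
  sup <- site_supply(alloc, site_ids = city$sites$site_id)
  r <- supply_ratio(sup, tt, pops, 30)
  a <- access_2sfca(r, tt, 30)
  lhs <- sum(pops * a$a_2sfca)
  rhs <- sum(r$supply[!r$zero_demand])
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("zero-supply sites never change access", {
  w <- worked_2sfca_instance()
  r <- supply_ratio(w$supply, w$tt, w$populations, 30)
  a <- access_2sfca(r, w$tt, 30)
  # add a zero-dollar site reachable by everyone
  minutes2 <- cbind(w$tt$minutes, `3` = c(1, 1, 1))
  tt2 <- travel_matrix(minutes2)
  sup2 <- rbind(w$supply, tibble::tibble(site_id = 3L, supply = 0))
  r2 <- supply_ratio(sup2, tt2, w$populations, 30)
  a2 <- access_2sfca(r2, tt2, 30)
  expect_equal(a2$a_2sfca, a$a_2sfca)
})

test_that("access on ALL equals the sum of per-program access", {
  city <- simulate_city(small_config())
  tt <- travel_time_matrix(
    city$network, city$blocks$node_id, city$sites$node_id,
    origin_ids = city$blocks$block_id, dest_ids = city$sites$site_id
  )
  kept <- filter_contracts(city$contracts, city$sites)
  alloc <- allocate_contracts(kept, city$sites)
  pops <- stats::setNames(city$blocks$population, city$blocks$block_id)
  all_access <- block_access(tt, alloc, pops, 30)
  per_prog <- lapply(unique(alloc$program_type), function(p) {
    block_access(tt, alloc, pops, 30, program_type = p)$a_2sfca
  })
  expect_equal(Reduce(`+`, per_prog), all_access$a_2sfca)

  # n_within = 0 exactly when no active site is inside the walkshed
  expect_identical(all_access$n_within == 0,
                   !(all_access$nearest_minutes < 30))
})

test_that("with supply ratios held fixed, block access grows with the walkshed", {
  # the indicator-sum step alone is monotone in T; recomputing step 1 at
  # each T is not, because denominators grow with the catchment
  w <- worked_2sfca_instance()
  r30 <- supply_ratio(w$supply, w$tt, w$populations, 30)
  prev <- rep(-Inf, 3)
  for (T_min in c(5, 12, 18, 25, 36, 45)) {
    a <- access_2sfca(r30, w$tt, T_min)$a_2sfca
    expect_true(all(a >= prev))
    prev <- a
  }
})

test_that("access metrics are non-decreasing in the threshold", {
  city <- simulate_city(small_config())
  tt <- travel_time_matrix(
    city$network, city$blocks$node_id, city$sites$node_id,
    origin_ids = city$blocks$block_id, dest_ids = city$sites$site_id
  )
  kept <- filter_contracts(city$contracts, city$sites)
  alloc <- allocate_contracts(kept, city$sites)
  pops <- stats::setNames(city$blocks$population, city$blocks$block_id)
  prev_n <- rep(-Inf, nrow(city$blocks))
  prev_p <- -Inf
  for (T_min in c(5, 15, 30, 60)) {
    n <- count_within(tt, T_min)$n_within
    p <- percent_with_access(tt, pops, T_min)
    expect_true(all(n >= prev_n))
    expect_gte(p, prev_p)
    prev_n <- n
    prev_p <- p
  }
})
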