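# Shared fixtures, built in code at test time.

# The worked 3-block / 2-site 2SFCA instance: travel times in minutes,
# block populations D, site dollars S. With T = 30 the supply ratios are
# R = (4.0, 1.2) and block access A = (4.0, 5.2, 1.2).
worked_2sfca_instance <- function() {
  minutes <- matrix(
    c(
      10, 40,
      20, 20,
      35, 15
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("1", "2", "3"), c("1", "2"))
  )
  list(
    tt = travel_matrix(minutes, origin_ids = 1:3, dest_ids = 1:2),
    populations = c(`1` = 10, `2` = 20, `3` = 30),
    supply = tibble::tibble(site_id = 1:2, supply = c(120, 60))
  )
}

# A small but complete scenario that runs in well under a second.
small_config <- function(...) {
  scenario_config(
    rows = 12L, cols = 12L, edge_length_m = 200, removal_prob = 0.1,
    n_blocks = 240L, blocks_per_tract = 8L,
    n_providers = 20L, seed = 42L,
    ...
  )
}

# Hand-built micro-city: 1x4 line network, 4 blocks, 2 providers
# (provider 1: HQ at node 1 + satellite at node 3; provider 2: HQ at
# node 4), used where every number must be checkable by hand.
micro_city <- function() {
  net <- street_network(
    nodes = tibble::tibble(
      node_id = 1:4, x = c(0, 800, 1600, 2400), y = 0
    ),
    edges = tibble::tibble(from = 1:3, to = 2:4, length_m = 800)
  )
  blocks <- tibble::tibble(
    block_id = 1:4, node_id = 1:4,
    x = net$nodes$x, y = net$nodes$y,
    population = c(10L, 20L, 30L, 40L),
    tract_id = c(1L, 1L, 2L, 2L)
  )
  sites <- tibble::tibble(
    site_id = 1:3, provider_id = c(1L, 1L, 2L),
    node_id = c(1L, 3L, 4L),
    is_headquarter = c(TRUE, FALSE, TRUE)
  )
  providers <- tibble::tibble(
    provider_id = 1:2, name = c("p1", "p2"), hq_site_id = c(1L, 3L)
  )
  contracts <- tibble::tibble(
    contract_id = 1:2, provider_id = 1:2,
    amount = c(30, 100),
    program_type = c("HIV_STI", "MICAH"),
    citywide = FALSE,
    site_shares = list(NULL, NULL)
  )
  list(
    network = net, blocks = blocks, sites = sites,
    providers = providers, contracts = contracts
  )
}
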