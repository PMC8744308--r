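#' Step 1 of 2SFCA: supply-to-reachable-demand ratio per site
#'
#' For each site j, divides its allocated dollars S_j by the population of
#' all blocks that can reach it within the catchment threshold:
#' R_j = S_j / sum_i D_i I(t_ij < T). Sites whose catchment contains no
#' population get R_j = 0 with `zero_demand = TRUE` rather than a division
#' by zero; such sites are inert downstream, which preserves the
#' conservation identity over the remaining sites.
#'
#' @param supply tibble of (`site_id`, `supply`) from [site_supply()].
#' @param tt `travel_time_matrix` whose destinations cover the sites
#'   (column ids are site ids) and whose origins are blocks.
#' @param block_populations numeric vector of populations aligned to the
#'   matrix origins (or named by origin id).
#' @param T_minutes catchment threshold in minutes; default 30.
#' @param inclusive use `<=` in the indicator; default strict `<`.
#' @return tibble of (`site_id`, `supply`, `reachable_population`, `R_j`,
#'   `zero_demand`).
#' @export
supply_ratio <- function(supply, tt, block_populations, T_minutes = 30,
                         inclusive = FALSE) {
  pops <- align_populations(block_populations, tt$origin_ids)
  if (any(pops < 0)) stop("block populations must be non-negative")
  ind <- catchment_indicator(tt, T_minutes, inclusive)
  col_idx <- match(as.character(supply$site_id), colnames(tt$minutes))
  if (anyNA(col_idx)) stop("every site must be a destination of the matrix")
  reach_pop <- as.numeric(crossprod(ind[, col_idx, drop = FALSE], pops))
  s_j <- supply$supply
  tibble::tibble(
    site_id = supply$site_id,
    supply = s_j,
    reachable_population = reach_pop,
    R_j = ifelse(reach_pop > 0, s_j / reach_pop, 0),
    zero_demand = reach_pop == 0
  )
}

#' Step 2 of 2SFCA: funded access per block
#'
#' Sums the supply ratios of all sites within each block's walkshed:
#' A_i = sum_j R_j I(t_ij < T), in dollars per person. Blocks reaching no
#' site get A_i = 0.
#'
#' @param ratios tibble from [supply_ratio()] (same matrix and threshold).
#' @param tt the `travel_time_matrix` the ratios were computed with.
#' @param T_minutes catchment threshold; must match the one used in step 1.
#' @param inclusive must match step 1.
#' @return tibble of (`block_id`, `a_2sfca`).
#' @export
access_2sfca <- function(ratios, tt, T_minutes = 30, inclusive = FALSE) {
  col_idx <- match(as.character(ratios$site_id), colnames(tt$minutes))
  if (anyNA(col_idx)) {
    stop("supply ratios refer to sites absent from the travel-time matrix")
  }
  ind <- catchment_indicator(tt, T_minutes, inclusive)
  a <- as.numeric(ind[, col_idx, drop = FALSE] %*% ratios$R_j)
  tibble::tibble(block_id = tt$origin_ids, a_2sfca = a)
}

#' Minutes to the nearest service site per block
#'
#' Row-wise minimum over reachable sites; blocks that can reach no site at
#' all carry `Inf` (none reachable).
#'
#' @param tt a `travel_time_matrix` (origins = blocks, dests = sites).
#' @return tibble of (`block_id`, `nearest_minutes`).
#' @export
time_to_nearest <- function(tt) {
  nearest <- if (ncol(tt$minutes) == 0) {
    rep(Inf, nrow(tt$minutes))
  } else {
    unname(apply(tt$minutes, 1, min))
  }
  tibble::tibble(block_id = tt$origin_ids, nearest_minutes = nearest)
}

#' Number of service sites within the walkshed per block
#'
#' @param tt a `travel_time_matrix`.
#' @param T_minutes catchment threshold; default 30.
#' @param inclusive use `<=`; default strict `<`.
#' @return tibble of (`block_id`, `n_within`).
#' @export
count_within <- function(tt, T_minutes = 30, inclusive = FALSE) {
  ind <- catchment_indicator(tt, T_minutes, inclusive)
  tibble::tibble(block_id = tt$origin_ids, n_within = as.integer(rowSums(ind)))
}

#' Share of population with at least one site within the walkshed
#'
#' Population-weighted coverage: sum of D_i over blocks with >= 1 site
#' within T, divided by total population. `NA` when total population is 0.
#'
#' @param tt a `travel_time_matrix`.
#' @param block_populations populations aligned to matrix origins (or
#'   named by origin id).
#' @param T_minutes catchment threshold; default 30.
#' @param inclusive use `<=`; default strict `<`.
#' @return fraction in `[0, 1]`, or `NA` if no population.
#' @export
percent_with_access <- function(tt, block_populations, T_minutes = 30,
                                inclusive = FALSE) {
  pops <- align_populations(block_populations, tt$origin_ids)
  if (any(pops < 0)) stop("block populations must be non-negative")
  total <- sum(pops)
  if (total == 0) return(NA_real_)
  covered <- rowSums(catchment_indicator(tt, T_minutes, inclusive)) > 0
  sum(pops[covered]) / total
}

#' Block-level access table (2SFCA, nearest time, count within walkshed)
#'
#' Convenience wrapper running both 2SFCA steps plus the two proximity
#' metrics for one set of allocations. With `program_type` set, supply is
#' restricted to that program's allocations and the proximity metrics to
#' sites carrying a positive supply of that program.
#'
#' @param tt `travel_time_matrix` over blocks x all sites.
#' @param allocations allocation tibble from [allocate_contracts()].
#' @param block_populations populations aligned to matrix origins.
#' @param T_minutes catchment threshold; default 30.
#' @param program_type optional program filter; `NULL` means all programs.
#' @param inclusive catchment boundary rule; default strict `<`.
#' @return tibble of (`block_id`, `program_type`, `a_2sfca`,
#'   `nearest_minutes`, `n_within`).
#' @export
block_access <- function(tt, allocations, block_populations, T_minutes = 30,
                         program_type = NULL, inclusive = FALSE) {
  all_sites <- as.integer(colnames(tt$minutes))
  supply <- site_supply(allocations, site_ids = all_sites,
                        program_type = program_type)
  ratios <- supply_ratio(supply, tt, block_populations, T_minutes, inclusive)
  a <- access_2sfca(ratios, tt, T_minutes, inclusive)

  # proximity metrics count only sites actually offering funded service(s)
  active <- supply$site_id[supply$supply > 0]
  sub <- subset_dests(tt, active)
  nearest <- time_to_nearest(sub)
  counts <- count_within(sub, T_minutes, inclusive)
  tibble::tibble(
    block_id = a$block_id,
    program_type = program_type %||% "ALL",
    a_2sfca = a$a_2sfca,
    nearest_minutes = nearest$nearest_minutes,
    n_within = counts$n_within
  )
}

# restrict a travel-time matrix to a subset of destinations
subset_dests <- function(tt, dest_ids) {
  keep <- colnames(tt$minutes) %in% as.character(dest_ids)
  new_travel_time_matrix(
    tt$minutes[, keep, drop = FALSE],
    tt$origin_ids, tt$dest_ids[keep],
    tt$origin_nodes, tt$dest_nodes[keep]
  )
}

align_populations <- function(pops, origin_ids) {
  if (!is.null(names(pops))) {
    idx <- match(as.character(origin_ids), names(pops))
    if (anyNA(idx)) stop("populations missing for some matrix origins")
    pops <- pops[idx]
  }
  if (length(pops) != length(origin_ids)) {
    stop("block populations must align with the matrix origins")
  }
  as.numeric(pops)
}
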