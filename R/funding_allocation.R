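#' Filter contracts to in-scope, site-specific services
#'
#' Drops citywide contracts and contracts whose provider has no delivery
#' site, mirroring the restriction of the analysis to services offered at
#' specific locations. Every exclusion is recorded with a reason in the
#' `"excluded"` attribute of the result.
#'
#' @param contracts contract tibble (`contract_id`, `provider_id`,
#'   `amount`, `program_type`, `citywide`, `site_shares` list-column).
#' @param sites site tibble (`site_id`, `provider_id`, ...).
#' @return the retained contracts, with attribute `excluded`: a tibble of
#'   (`contract_id`, `reason`).
#' @export
filter_contracts <- function(contracts, sites) {
  has_site <- contracts$provider_id %in% sites$provider_id
  reason <- rep(NA_character_, nrow(contracts))
  reason[contracts$citywide] <- "citywide"
  reason[!contracts$citywide & !has_site] <- "no_delivery_site"
  keep <- is.na(reason)
  out <- contracts[keep, ]
  attr(out, "excluded") <- tibble::tibble(
    contract_id = contracts$contract_id[!keep],
    reason = reason[!keep]
  )
  out
}

#' Allocate one contract's dollars across delivery sites
#'
#' With explicit site shares the amount is split as `amount * share`.
#' Without shares the amount is divided equally among the headquarters and
#' all satellite sites (`hq_delivers = TRUE`, the default), or among
#' satellites only (`hq_delivers = FALSE`, for when services are known not
#' to be delivered at headquarters). Allocations always sum to the
#' contract amount.
#'
#' @param contract a one-row contract tibble.
#' @param sites the provider's sites.
#' @param hq_delivers include the headquarters in the equal split.
#' @return tibble of (`site_id`, `contract_id`, `program_type`, `amount`).
#' @export
allocate_contract <- function(contract, sites, hq_delivers = TRUE) {
  stopifnot(nrow(contract) == 1)
  own <- sites[sites$provider_id == contract$provider_id, ]
  if (nrow(own) == 0) stop("contract has no delivery sites")
  shares <- contract$site_shares[[1]]
  if (!is.null(shares)) {
    if (abs(sum(shares) - 1) > 1e-9) {
      stop(sprintf(
        "site shares for contract %s sum to %.12f, not 1",
        contract$contract_id, sum(shares)
      ))
    }
    sid <- as.integer(names(shares))
    if (!all(sid %in% own$site_id)) {
      stop("site shares reference a site not belonging to the provider")
    }
    alloc <- tibble::tibble(
      site_id = sid,
      amount = contract$amount * as.numeric(shares)
    )
  } else {
    split_sites <- if (hq_delivers) own else own[!own$is_headquarter, ]
    if (nrow(split_sites) == 0) {
      stop("equal split over satellites requested but provider has none")
    }
    alloc <- tibble::tibble(
      site_id = split_sites$site_id,
      amount = contract$amount / nrow(split_sites)
    )
    if (!hq_delivers && any(own$is_headquarter)) {
      alloc <- rbind(
        tibble::tibble(
          site_id = own$site_id[own$is_headquarter],
          amount = 0
        ),
        alloc
      )
    }
  }
  tibble::tibble(
    site_id = alloc$site_id,
    contract_id = contract$contract_id,
    program_type = contract$program_type,
    amount = alloc$amount
  )
}

#' Allocate every in-scope contract
#'
#' @param contracts filtered contracts ([filter_contracts()]).
#' @param sites site tibble.
#' @param hq_delivers passed to [allocate_contract()].
#' @return stacked allocation tibble; for each contract the allocations sum
#'   to the contract amount.
#' @export
allocate_contracts <- function(contracts, sites, hq_delivers = TRUE) {
  if (nrow(contracts) == 0) {
    return(tibble::tibble(
      site_id = integer(), contract_id = integer(),
      program_type = character(), amount = numeric()
    ))
  }
  out <- lapply(seq_len(nrow(contracts)), function(i) {
    allocate_contract(contracts[i, ], sites, hq_delivers)
  })
  do.call(rbind, out)
}

#' Site supply S_j: dollars allocated at each site
#'
#' Sums allocation amounts per site across contracts, optionally restricted
#' to one program type. Sites with no allocation get 0.
#'
#' @param allocations allocation tibble from [allocate_contracts()].
#' @param site_ids site ids the result should cover (defaults to sites
#'   present in the allocations).
#' @param program_type optional program filter (e.g. `"HIV_STI"`).
#' @return tibble of (`site_id`, `supply`).
#' @export
site_supply <- function(allocations, site_ids = NULL, program_type = NULL) {
  if (!is.null(program_type)) {
    allocations <- allocations[allocations$program_type %in% program_type, ]
  }
  site_ids <- site_ids %||% sort(unique(allocations$site_id))
  s <- tapply(allocations$amount, allocations$site_id, sum)
  supply <- rep(0, length(site_ids))
  idx <- match(names(s), as.character(site_ids))
  supply[idx[!is.na(idx)]] <- as.numeric(s)[!is.na(idx)]
  tibble::tibble(site_id = site_ids, supply = supply)
}

#' Container-approach funding per area
#'
#' The container approach sums dollars located inside each area's boundary,
#' ignoring cross-boundary walkable proximity. `mode = "hq_only"` assigns
#' each contract's full amount to the area of its provider's headquarters —
#' the conventional open-data view, in which satellite delivery sites are
#' invisible. `mode = "all_sites"` sums the per-site allocations by the
#' area containing each site. Both modes conserve total dollars (up to
#' sites that map to no area, which are skipped and counted in the
#' `"n_skipped_sites"` attribute).
#'
#' @param contracts filtered contracts.
#' @param allocations allocations for those contracts.
#' @param sites site tibble (used to find headquarters).
#' @param area_membership tibble of (`site_id`, `area_id`).
#' @param mode `"hq_only"` or `"all_sites"`.
#' @param area_ids areas the result should cover (default: those in
#'   `area_membership`); areas receiving nothing get 0.
#' @return tibble of (`area_id`, `dollars`), with attribute
#'   `n_skipped_sites`.
#' @export
container_funding <- function(contracts, allocations, sites, area_membership,
                              mode = c("all_sites", "hq_only"),
                              area_ids = NULL) {
  mode <- match.arg(mode)
  area_ids <- area_ids %||% sort(unique(area_membership$area_id))
  area_of <- stats::setNames(
    area_membership$area_id,
    as.character(area_membership$site_id)
  )
  if (mode == "hq_only") {
    hq <- sites[sites$is_headquarter, c("site_id", "provider_id")]
    hq_site <- hq$site_id[match(contracts$provider_id, hq$provider_id)]
    df <- data.frame(site_id = hq_site, amount = contracts$amount)
  } else {
    df <- data.frame(site_id = allocations$site_id, amount = allocations$amount)
  }
  df$area_id <- area_of[as.character(df$site_id)]
  n_skipped <- length(unique(df$site_id[is.na(df$area_id)]))
  if (n_skipped > 0) {
    warning(sprintf("%d site(s) map to no area; their dollars are skipped",
                    n_skipped))
  }
  df <- df[!is.na(df$area_id), ]
  s <- tapply(df$amount, df$area_id, sum)
  dollars <- rep(0, length(area_ids))
  idx <- match(names(s), as.character(area_ids))
  dollars[idx[!is.na(idx)]] <- as.numeric(s)[!is.na(idx)]
  out <- tibble::tibble(area_id = area_ids, dollars = dollars)
  attr(out, "n_skipped_sites") <- n_skipped
  out
}

#' Per-capita funding by area
#'
#' @param area_funding tibble from [container_funding()].
#' @param area_population tibble of (`area_id`, `population`).
#' @return `area_funding` with `population` and `dollars_per_capita`
#'   columns; zero-population areas get `NA` per-capita (undefined), never
#'   a division by zero.
#' @export
funding_per_capita <- function(area_funding, area_population) {
  pop <- area_population$population[
    match(area_funding$area_id, area_population$area_id)
  ]
  area_funding$population <- pop
  area_funding$dollars_per_capita <- ifelse(
    !is.na(pop) & pop > 0, area_funding$dollars / pop, NA_real_
  )
  area_funding
}

#' Funding share by group, in percent
#'
#' Sums area dollars within each group label and expresses them as
#' percentages of the total (summing to 100 exactly, up to floating
#' rounding).
#'
#' @param area_funding tibble of (`area_id`, `dollars`).
#' @param group_labels vector of group labels aligned to the rows of
#'   `area_funding` (factor or character).
#' @return tibble of (`group`, `dollars`, `percent`).
#' @export
funding_share_by_group <- function(area_funding, group_labels) {
  stopifnot(length(group_labels) == nrow(area_funding))
  lev <- if (is.factor(group_labels)) levels(group_labels) else unique(group_labels)
  d <- tapply(area_funding$dollars, factor(group_labels, levels = lev), sum)
  d[is.na(d)] <- 0
  total <- sum(d)
  tibble::tibble(
    group = lev,
    dollars = as.numeric(d),
    percent = if (total > 0) 100 * as.numeric(d) / total else rep(NA_real_, length(d))
  )
}
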