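hardship_components <- c(
  "crowded_housing", "poverty", "unemployment",
  "low_education", "dependents", "per_capita_income"
)

#' Composite hardship index per tract
#'
#' Combines six socio-economic indicators — crowded housing, poverty,
#' unemployment, low education, dependents (all percent) and per-capita
#' income (dollars) — into a single 0-100 need score: each component is
#' min-max scaled to `[0, 100]` across tracts, income is inverted (higher
#' income means lower hardship), and the six scaled values are averaged.
#' A component constant across all tracts carries no ranking information
#' and contributes 0 after scaling (with a warning).
#'
#' @param tracts tract tibble containing the six component columns.
#' @return numeric hardship index per tract, on a 0-100 scale.
#' @export
hardship_index <- function(tracts) {
  missing_cols <- setdiff(hardship_components, names(tracts))
  if (length(missing_cols) > 0) {
    stop("missing hardship components: ", paste(missing_cols, collapse = ", "))
  }
  scaled <- sapply(hardship_components, function(cmp) {
    v <- tracts[[cmp]]
    if (anyNA(v)) stop("hardship component '", cmp, "' has missing values")
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("component '", cmp, "' is constant across tracts; it contributes 0")
      return(rep(0, length(v)))
    }
    s <- 100 * (v - rng[1]) / diff(rng)
    if (cmp == "per_capita_income") 100 - s else s
  })
  rowMeans(matrix(scaled, nrow = nrow(tracts)))
}

#' Rank-based tercile classification
#'
#' Splits units into three groups of (near-)equal size by increasing value.
#' Group sizes differ by at most one, with remainders assigned to the lower
#' groups first (n = 10 gives sizes 4/3/3); ties are broken by stable unit
#' order, so the classification depends only on ranks and is invariant
#' under strictly monotone transforms of the values.
#'
#' @param values numeric vector (length >= 3).
#' @param ids unit identifiers used for the stable tie order; default input
#'   position.
#' @param labels the three group labels, low to high.
#' @return factor of group labels aligned to the input order.
#' @export
tercile_classify <- function(values, ids = seq_along(values),
                             labels = c("low", "medium", "high")) {
  n <- length(values)
  if (n < 3) stop("tercile classification needs at least 3 units")
  stopifnot(length(ids) == n, length(labels) == 3)
  ord <- order(values, ids)  # stable: ties resolved by unit id
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, FALSE)
  lab <- rep(labels, times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = labels)
}

#' Aggregate block access metrics to tracts
#'
#' Per-tract mean of each block metric, unweighted by default (population
#' weighting available). Blocks that can reach no site are excluded from
#' the nearest-minutes mean; their count per tract is reported so coverage
#' gaps stay visible.
#'
#' @param access block access tibble ([block_access()]).
#' @param blocks block tibble with `block_id`, `tract_id`, `population`.
#' @param weighting `"unweighted"` or `"population"`.
#' @return tibble of (`tract_id`, `program_type`, `mean_a_2sfca`,
#'   `mean_nearest_minutes`, `mean_n_within`, `percent_with_access`,
#'   `n_blocks`, `n_unreachable_blocks`).
#' @export
aggregate_to_tract <- function(access, blocks, weighting = c("unweighted", "population")) {
  weighting <- match.arg(weighting)
  idx <- match(access$block_id, blocks$block_id)
  if (anyNA(idx)) stop("access rows refer to unknown blocks")
  tract <- blocks$tract_id[idx]
  w <- if (weighting == "population") blocks$population[idx] else rep(1, nrow(access))
  pop <- blocks$population[idx]

  wmean <- function(v, w) if (sum(w) > 0) sum(v * w) / sum(w) else mean(v)
  cells <- split(
    seq_len(nrow(access)),
    list(tract = tract, program = access$program_type),
    drop = TRUE
  )
  per_tract <- lapply(cells, function(i) {
    reach <- is.finite(access$nearest_minutes[i])
    covered <- access$n_within[i] > 0
    tibble::tibble(
      tract_id = tract[i][1],
      program_type = access$program_type[i][1],
      mean_a_2sfca = wmean(access$a_2sfca[i], w[i]),
      mean_nearest_minutes = if (any(reach)) {
        wmean(access$nearest_minutes[i][reach], w[i][reach])
      } else {
        NA_real_
      },
      mean_n_within = wmean(access$n_within[i], w[i]),
      percent_with_access = if (sum(pop[i]) > 0) {
        sum(pop[i][covered]) / sum(pop[i])
      } else {
        NA_real_
      },
      n_blocks = length(i),
      n_unreachable_blocks = sum(!reach)
    )
  })
  out <- do.call(rbind, per_tract)
  out <- out[order(out$program_type, out$tract_id), ]
  rownames(out) <- NULL
  out
}

#' Access/hardship summaries per hardship group
#'
#' For each hardship tercile: mean, median and quartiles of each tract-level
#' access metric, plus the group's share of in-scope dollars and dollars
#' per capita. Funding shares sum to 100%.
#'
#' @param tract_access tibble from [aggregate_to_tract()].
#' @param hardship tibble of (`tract_id`, `hardship_tercile`).
#' @param area_funding tibble of (`area_id`, `dollars`) with `area_id` =
#'   tract id ([container_funding()]).
#' @param tract_populations tibble of (`tract_id`, `population`).
#' @return tibble with one row per hardship group (and per program type if
#'   several are present in `tract_access`).
#' @export
group_summary <- function(tract_access, hardship, area_funding,
                          tract_populations) {
  lab <- hardship$hardship_tercile[
    match(tract_access$tract_id, hardship$tract_id)
  ]
  if (anyNA(lab)) stop("every tract needs a hardship tercile")
  fund <- area_funding$dollars[
    match(hardship$tract_id, area_funding$area_id)
  ]
  fund[is.na(fund)] <- 0
  pop <- tract_populations$population[
    match(hardship$tract_id, tract_populations$tract_id)
  ]
  total_fund <- sum(fund)
  groups <- split(
    seq_len(nrow(tract_access)),
    list(group = lab, program_type = tract_access$program_type),
    drop = TRUE
  )
  qs <- function(v) stats::quantile(v, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
  rows <- lapply(groups, function(i) {
    g <- as.character(lab[i][1])
    in_group <- as.character(hardship$hardship_tercile) == g
    gfund <- sum(fund[in_group])
    gpop <- sum(pop[in_group])
    q_a <- qs(tract_access$mean_a_2sfca[i])
    q_t <- qs(tract_access$mean_nearest_minutes[i])
    q_n <- qs(tract_access$mean_n_within[i])
    tibble::tibble(
      group = g,
      program_type = tract_access$program_type[i][1],
      n_tracts = length(i),
      mean_a_2sfca = mean(tract_access$mean_a_2sfca[i]),
      median_a_2sfca = q_a[2], q1_a_2sfca = q_a[1], q3_a_2sfca = q_a[3],
      mean_nearest_minutes = mean(tract_access$mean_nearest_minutes[i], na.rm = TRUE),
      median_nearest_minutes = q_t[2],
      mean_n_within = mean(tract_access$mean_n_within[i]),
      median_n_within = q_n[2],
      mean_percent_with_access = mean(tract_access$percent_with_access[i], na.rm = TRUE),
      funding_dollars = gfund,
      funding_share_pct = if (total_fund > 0) 100 * gfund / total_fund else NA_real_,
      dollars_per_capita = if (isTRUE(gpop > 0)) gfund / gpop else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  lev <- levels(factor(lab))
  out[order(out$program_type, match(out$group, lev)), ]
}

#' Cross-classification of hardship terciles by spending terciles
#'
#' 3x3 contingency table of need (hardship tercile) against funded access
#' (tercile of tract mean 2SFCA access) — the table behind need-vs-access
#' equity maps: diagonal cells are aligned need and access, off-diagonal
#' cells flag high-need/low-access (and the converse) tracts.
#'
#' @param hardship tibble of (`tract_id`, `hardship_tercile`).
#' @param tract_access tibble with `tract_id` and `spending_tercile`
#'   (see [spending_terciles()]).
#' @return a `table`, rows = hardship tercile, cols = spending tercile.
#' @export
cross_classify <- function(hardship, tract_access) {
  idx <- match(hardship$tract_id, tract_access$tract_id)
  if (anyNA(idx)) stop("classifications must cover the same tracts")
  table(
    hardship = hardship$hardship_tercile,
    spending = tract_access$spending_tercile[idx]
  )
}

#' Spending-level terciles from tract mean 2SFCA access
#'
#' @param tract_access tibble from [aggregate_to_tract()] (single program).
#' @param labels tercile labels, low to high.
#' @return `tract_access` with a `spending_tercile` column.
#' @export
spending_terciles <- function(tract_access,
                              labels = c("lower", "medium", "higher")) {
  tract_access$spending_tercile <- tercile_classify(
    tract_access$mean_a_2sfca, tract_access$tract_id, labels
  )
  tract_access
}
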