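#' Assign each service site to the tract containing it
#'
#' In the synthetic city every site sits on a block node, so a site's tract
#' is the tract of a block at the same node; for off-block nodes
#' (externally supplied data) the nearest block by Euclidean distance is
#' used. Sites are the bridge between contract dollars and tract-level
#' container accounting.
#'
#' @param sites site tibble.
#' @param blocks block tibble with `node_id`, `x`, `y`, `tract_id`.
#' @param net the street network (node coordinates).
#' @return tibble of (`site_id`, `area_id`).
#' @export
site_tract_membership <- function(sites, blocks, net) {
  node_idx <- match(sites$node_id, net$nodes$node_id)
  sx <- net$nodes$x[node_idx]
  sy <- net$nodes$y[node_idx]
  area <- vapply(seq_len(nrow(sites)), function(i) {
    same <- which(blocks$node_id == sites$node_id[i])
    if (length(same) > 0) return(blocks$tract_id[same[1]])
    d2 <- (blocks$x - sx[i])^2 + (blocks$y - sy[i])^2
    blocks$tract_id[which.min(d2)]
  }, numeric(1))
  tibble::tibble(site_id = sites$site_id, area_id = as.integer(area))
}

#' Run the full analysis pipeline on a scenario
#'
#' Executes the five stages in order — simulate, travel times, funding
#' allocation, access metrics, equity classification — and returns every
#' stage output plus a run manifest (seed, stage checksums, warning
#' counts). With `out_dir` set, stage outputs are also written as
#' GeoJSON/CSV files as they complete, so a failed stage leaves the
#' completed ones on disk.
#'
#' @param config a [scenario_config()] / [scenario_preset()], or a path to
#'   a YAML config file.
#' @param out_dir optional output directory.
#' @return list with `city`, `tt`, `allocations`, `access`,
#'   `tract_access`, `funding` (hq_only / all_sites + per-capita),
#'   `summary`, `crosstab`, and `manifest`.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config_yaml(config)
  config <- validate_scenario_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  manifest <- list(
    config = unclass(config), seed = config$seed,
    stages = character(0), checksums = list(), warnings = list()
  )
  done <- function(stage, obj) {
    manifest$stages <<- c(manifest$stages, stage)
    manifest$checksums[[stage]] <<- rlang::hash(obj)
  }

  # stage 1: synthetic city
  city <- validate_city(simulate_city(config))
  done("simulate", city)
  emit("network.geojson", function(p) write_network_geojson(city$network, p))
  emit("blocks.geojson", function(p) write_points_geojson(city$blocks, p))
  emit("sites.geojson", function(p) {
    ni <- match(city$sites$node_id, city$network$nodes$node_id)
    s <- city$sites
    s$x <- city$network$nodes$x[ni]
    s$y <- city$network$nodes$y[ni]
    write_points_geojson(s, p)
  })
  emit("tracts.csv", function(p) utils::write.csv(city$tracts, p, row.names = FALSE))
  emit("contracts.csv", function(p) write_contracts_csv(city$contracts, p))

  # stage 2: walking times blocks x sites
  tt <- travel_time_matrix(
    city$network,
    origin_nodes = city$blocks$node_id, dest_nodes = city$sites$node_id,
    walk_speed_mph = config$walk_speed_mph,
    origin_ids = city$blocks$block_id, dest_ids = city$sites$site_id
  )
  manifest$warnings$unreachable_pairs <- sum(!reachable(tt))
  done("travel", tt$minutes)
  emit("travel_times.csv.gz", function(p) write_travel_csv(tt, p))

  # stage 3: contract filtering and allocation
  kept <- filter_contracts(city$contracts, city$sites)
  manifest$warnings$contracts_excluded <- nrow(attr(kept, "excluded"))
  allocations <- allocate_contracts(kept, city$sites, config$hq_delivers)
  done("allocate", allocations)
  emit("allocations.csv", function(p) utils::write.csv(allocations, p, row.names = FALSE))

  # stage 4: block-level access metrics, overall and per program
  programs <- sort(unique(allocations$program_type))
  pops <- stats::setNames(city$blocks$population, city$blocks$block_id)
  access <- do.call(rbind, c(
    list(block_access(tt, allocations, pops, config$T_minutes)),
    lapply(programs, function(pr) {
      block_access(tt, allocations, pops, config$T_minutes, program_type = pr)
    })
  ))
  done("access", access)
  emit("block_access.csv", function(p) utils::write.csv(access, p, row.names = FALSE))

  # stage 5: tract aggregation, hardship/spending classification, summaries
  tract_access <- aggregate_to_tract(access, city$blocks)
  ta_all <- spending_terciles(
    tract_access[tract_access$program_type == "ALL", ]
  )
  hardship <- city$tracts[, c("tract_id", "hardship", "hardship_tercile")]
  membership <- site_tract_membership(city$sites, city$blocks, city$network)
  tract_pop <- tibble::tibble(
    tract_id = city$tracts$tract_id,
    population = as.numeric(tapply(
      city$blocks$population, city$blocks$tract_id, sum
    )[as.character(city$tracts$tract_id)])
  )
  funding <- lapply(c(hq_only = "hq_only", all_sites = "all_sites"), function(m) {
    af <- container_funding(
      kept, allocations, city$sites, membership,
      mode = m, area_ids = city$tracts$tract_id
    )
    funding_per_capita(
      af, stats::setNames(tract_pop, c("area_id", "population"))
    )
  })
  summary_tbl <- group_summary(
    tract_access, hardship, funding$all_sites, tract_pop
  )
  crosstab <- cross_classify(hardship, ta_all)
  classified <- merge(ta_all, hardship, by = "tract_id")
  done("classify", list(summary_tbl, crosstab))
  emit("tract_classification.csv", function(p) utils::write.csv(classified, p, row.names = FALSE))
  emit("group_summary.csv", function(p) utils::write.csv(summary_tbl, p, row.names = FALSE))
  emit("cross_classification.csv", function(p) {
    utils::write.csv(as.data.frame(crosstab), p, row.names = FALSE)
  })

  result <- list(
    city = city, tt = tt, contracts_kept = kept, allocations = allocations,
    access = access, tract_access = tract_access, tract_access_all = ta_all,
    hardship = hardship, membership = membership, tract_pop = tract_pop,
    funding = funding, summary = summary_tbl, crosstab = crosstab,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  result
}

#' Build the report tables from a pipeline run
#'
#' Produces the four headline tables: funding shares by hardship group
#' under headquarters-only vs. all-sites container accounting, per-capita
#' dollars by group under both modes, the per-group access summaries per
#' program, and the 3x3 hardship-by-spending cross-classification. Dollars
#' are rounded to whole dollars and shares to one decimal at render time
#' only; no quantity is recomputed here.
#'
#' @param result output of [run_pipeline()].
#' @return list of data frames: `funding_shares`, `per_capita`,
#'   `group_summaries`, `cross_classification`.
#' @export
build_report <- function(result) {
  needed <- c("funding", "summary", "crosstab", "hardship")
  if (!all(needed %in% names(result))) {
    stop("incomplete pipeline result; missing: ",
         paste(setdiff(needed, names(result)), collapse = ", "))
  }
  lab <- result$hardship$hardship_tercile
  shares <- lapply(names(result$funding), function(m) {
    sh <- funding_share_by_group(result$funding[[m]], lab)
    tibble::tibble(
      mode = m, group = sh$group,
      dollars = round(sh$dollars),
      share_pct = round(sh$percent, 1)
    )
  })
  per_cap <- lapply(names(result$funding), function(m) {
    af <- result$funding[[m]]
    g <- tapply(af$dollars, lab, sum)[levels(lab)]
    p <- tapply(af$population, lab, sum)[levels(lab)]
    tibble::tibble(
      mode = m, group = levels(lab),
      dollars_per_capita = round(as.numeric(g) / as.numeric(p), 2)
    )
  })
  gs <- result$summary
  gs$mean_a_2sfca <- round(gs$mean_a_2sfca, 2)
  gs$median_a_2sfca <- round(gs$median_a_2sfca, 2)
  gs$funding_dollars <- round(gs$funding_dollars)
  gs$funding_share_pct <- round(gs$funding_share_pct, 1)
  gs$dollars_per_capita <- round(gs$dollars_per_capita, 2)
  list(
    funding_shares = do.call(rbind, shares),
    per_capita = do.call(rbind, per_cap),
    group_summaries = gs,
    cross_classification = as.data.frame(result$crosstab)
  )
}
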