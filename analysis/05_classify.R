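#!/usr/bin/env Rscript
# Stage 5 — need versus funded access at the tract level.
#
# Averages the block metrics to tracts, classifies tracts into hardship
# terciles (need) and spending terciles (tercile of tract-mean 2SFCA
# access), summarises every access metric within each hardship group, and
# cross-tabulates need against access — the table behind equity maps that
# flag high-need / low-access neighborhoods.

suppressPackageStartupMessages(library(fundedaccess))

scen <- "results/scenario"
net <- read_network_geojson(file.path(scen, "network.geojson"))
blocks <- read_points_geojson(file.path(scen, "blocks.geojson"))
sites <- read_points_geojson(file.path(scen, "sites.geojson"))
tracts <- read.csv(file.path(scen, "tracts.csv"))
contracts <- read_contracts_csv(file.path(scen, "contracts.csv"))
config <- read_config_yaml(file.path(scen, "scenario.yaml"))
access <- read.csv("results/block_access.csv")
allocations <- read.csv("results/allocations.csv")

tract_access <- aggregate_to_tract(access, blocks)
ta_all <- spending_terciles(tract_access[tract_access$program_type == "ALL", ])
hardship <- data.frame(
  tract_id = tracts$tract_id,
  hardship = tracts$hardship,
  hardship_tercile = factor(tracts$hardship_tercile,
                            levels = c("low", "medium", "high"))
)

kept <- filter_contracts(contracts, sites)
membership <- site_tract_membership(sites, blocks, net)
funding <- container_funding(kept, allocations, sites, membership,
                             mode = "all_sites", area_ids = tracts$tract_id)
tract_pop <- data.frame(
  tract_id = tracts$tract_id,
  population = as.numeric(tapply(blocks$population, blocks$tract_id,
                                 sum)[as.character(tracts$tract_id)])
)

summary_tbl <- group_summary(tract_access, hardship, funding, tract_pop)
write.csv(summary_tbl, "results/group_summary.csv", row.names = FALSE)
crosstab <- cross_classify(hardship, ta_all)
write.csv(as.data.frame(crosstab), "results/cross_classification.csv",
          row.names = FALSE)
merged <- merge(ta_all, hardship, by = "tract_id")
write.csv(merged, "results/tract_classification.csv", row.names = FALSE)

all_sum <- summary_tbl[summary_tbl$program_type == "ALL", ]
cat("funded access by hardship group (ALL programs):\n")
print(data.frame(
  group = all_sum$group,
  mean_2sfca = round(all_sum$mean_a_2sfca, 1),
  median_2sfca = round(all_sum$median_a_2sfca, 1),
  mean_nearest_min = round(all_sum$mean_nearest_minutes, 1),
  mean_n_within = round(all_sum$mean_n_within, 1),
  funding_share_pct = round(all_sum$funding_share_pct, 1),
  dollars_per_capita = round(all_sum$dollars_per_capita, 2)
), row.names = FALSE)

cat("\nhardship tercile x spending tercile (tract counts):\n")
print(crosstab)
n_gap <- crosstab["high", "lower"]
cat(sprintf(
  "\n%d high-hardship tracts sit in the lowest funded-access tercile (potential access gaps)\n",
  n_gap
))
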