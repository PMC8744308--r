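#!/usr/bin/env Rscript
# Stage 1 — build the synthetic city.
#
# Generates the reference "hq_downtown" scenario: a 40x40 street grid,
# ~4,800 housing blocks in ~600 tracts with a west-to-east hardship
# gradient, and 150 contracted providers whose headquarters cluster in
# low-hardship tracts while satellite delivery sites cluster in medium and
# high-hardship tracts. Writes the scenario to results/scenario/ as
# GeoJSON/CSV/YAML for the later stages.

suppressPackageStartupMessages(library(fundedaccess))

out <- "results/scenario"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- scenario_preset("hq_downtown")
city <- validate_city(simulate_city(config))

write_config_yaml(config, file.path(out, "scenario.yaml"))
write_network_geojson(city$network, file.path(out, "network.geojson"))
write_points_geojson(city$blocks, file.path(out, "blocks.geojson"))
ni <- match(city$sites$node_id, city$network$nodes$node_id)
sites_xy <- city$sites
sites_xy$x <- city$network$nodes$x[ni]
sites_xy$y <- city$network$nodes$y[ni]
write_points_geojson(sites_xy, file.path(out, "sites.geojson"))
write.csv(city$tracts, file.path(out, "tracts.csv"), row.names = FALSE)
write_contracts_csv(city$contracts, file.path(out, "contracts.csv"))

hq_n <- sum(city$sites$is_headquarter)
cat(sprintf(
  "city: %d nodes / %d edges; %d blocks (%s residents) in %d tracts\n",
  nrow(city$network$nodes), nrow(city$network$edges),
  nrow(city$blocks), format(sum(city$blocks$population), big.mark = ","),
  nrow(city$tracts)
))
cat(sprintf(
  "providers: %d, sites: %d (%d HQ + %d satellites); contracts: %d totalling $%sM\n",
  nrow(city$providers), nrow(city$sites), hq_n, nrow(city$sites) - hq_n,
  nrow(city$contracts),
  round(sum(city$contracts$amount) / 1e6, 1)
))
cat(sprintf("hardship index range: %.1f to %.1f\n",
            min(city$tracts$hardship), max(city$tracts$hardship)))
cat("scenario written to", out, "\n")
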