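#!/usr/bin/env Rscript
# Stage 2 — walking times from every block to every service site.
#
# Reads the scenario written by 01_simulate.R, computes the block-by-site
# walking-time matrix over the street network at 3 mph (one shortest-path
# sweep per distinct block node), and writes it as long-form CSV for the
# access-metric stage.

suppressPackageStartupMessages(library(fundedaccess))

scen <- "results/scenario"
net <- read_network_geojson(file.path(scen, "network.geojson"))
blocks <- read_points_geojson(file.path(scen, "blocks.geojson"))
sites <- read_points_geojson(file.path(scen, "sites.geojson"))
config <- read_config_yaml(file.path(scen, "scenario.yaml"))

tt <- travel_time_matrix(
  net,
  origin_nodes = blocks$node_id, dest_nodes = sites$node_id,
  walk_speed_mph = config$walk_speed_mph,
  origin_ids = blocks$block_id, dest_ids = sites$site_id
)
write_travel_csv(tt, "results/travel_times.csv.gz")

nearest <- time_to_nearest(tt)$nearest_minutes
cat(sprintf("computed %d x %d walking times at %.0f mph\n",
            nrow(tt$minutes), ncol(tt$minutes), config$walk_speed_mph))
cat(sprintf("unreachable block-site pairs: %d\n", sum(!reachable(tt))))
cat(sprintf(
  "minutes to nearest site: median %.1f, 90th percentile %.1f\n",
  median(nearest), quantile(nearest, 0.9)
))
cat(sprintf(
  "blocks with any site within a %g-minute walk: %.1f%%\n",
  config$T_minutes, 100 * mean(nearest < config$T_minutes)
))
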