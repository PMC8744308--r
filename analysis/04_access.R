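#!/usr/bin/env Rscript
# Stage 4 — block-level spatial access to funded services.
#
# Combines the walking-time matrix (stage 2) with the site allocations
# (stage 3) into the three access measures for every housing block:
# 2SFCA funded access in dollars per person, minutes to the nearest funded
# site, and the number of funded sites within the 30-minute walkshed —
# overall and per program type.

suppressPackageStartupMessages(library(fundedaccess))

scen <- "results/scenario"
blocks <- read_points_geojson(file.path(scen, "blocks.geojson"))
config <- read_config_yaml(file.path(scen, "scenario.yaml"))
tt <- read_travel_csv("results/travel_times.csv.gz")
allocations <- read.csv("results/allocations.csv")

pops <- setNames(blocks$population, blocks$block_id)
programs <- sort(unique(allocations$program_type))
access <- do.call(rbind, c(
  list(block_access(tt, allocations, pops, config$T_minutes)),
  lapply(programs, function(pr) {
    block_access(tt, allocations, pops, config$T_minutes, program_type = pr)
  })
))
write.csv(access, "results/block_access.csv", row.names = FALSE)

all_rows <- access[access$program_type == "ALL", ]
cat(sprintf(
  "funded access (ALL programs): mean $%.1f per person, median $%.1f\n",
  mean(all_rows$a_2sfca), median(all_rows$a_2sfca)
))
cat(sprintf(
  "population within a %g-minute walk of at least one funded site: %.1f%%\n",
  config$T_minutes,
  100 * percent_with_access(tt, pops, config$T_minutes)
))
cat("sites within the walkshed per block (quartiles):",
    paste(quantile(all_rows$n_within, c(.25, .5, .75)), collapse = " / "), "\n")
cat(sprintf("blocks that can reach no funded site at all: %d\n",
            sum(!is.finite(all_rows$nearest_minutes))))
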