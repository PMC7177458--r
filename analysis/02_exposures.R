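#!/usr/bin/env Rscript
## Stage 2: exclusion funnel and per-participant exposures - catchment-buffer
## walkability measures at 1250 m (children) / 1350 m (adolescents) plus
## home-school network distance and PRD.

library(acsroutes)

city_dir <- "results/city"
net <- read_network_geojson(file.path(city_dir, "network.geojson"))
parcels <- read_parcels_geojson(file.path(city_dir, "parcels.geojson"))
schools <- read.csv(file.path(city_dir, "schools.csv"))
roster <- read_participants_csv(file.path(city_dir, "participants.csv"))

coding <- apply_exclusions(roster)
message(sprintf("exclusions: %d missing ACS, %d cyclists, %d ungeocodable",
                coding$counts["missing_acs"], coding$counts["bike"],
                coding$counts["ungeocodable"]))

records <- build_exposure_table(coding$retained, schools, net, parcels)
excl <- rbind(coding$log, attr(records, "exclusions"))
write_exposure_table(records, "results/exposure.csv")
write_exclusion_log(excl, "results/exclusions.csv")
write.csv(attr(records, "buffer_table"), "results/buffer_measures.csv",
          row.names = FALSE)

message(sprintf("analysed n = %d of %d enrolled", nrow(records), nrow(roster)))
message(sprintf("active share: %.1f%% (children %.1f%%, adolescents %.1f%%)",
                100 * mean(records$acs_binary),
                100 * mean(records$acs_binary[records$age_group == "child"]),
                100 * mean(records$acs_binary[records$age_group == "adolescent"])))
message(sprintf("median distance %.2f km, median PRD %.3f; %d records flagged PRD < 1",
                median(records$distance_km), median(records$prd),
                sum(records$flags == "prd_lt_1")))
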