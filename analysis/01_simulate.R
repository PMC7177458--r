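#!/usr/bin/env Rscript
## Stage 1: generate the synthetic study - street network, land-use parcels,
## schools and a participant roster whose commuting behaviour follows a known
## logistic model. Everything downstream reads the files written here.

library(acsroutes)

out <- "results/city"
cfg <- city_config(seed = 1803L)    # study-wide seed; change to re-draw
sim <- simulate_study(cfg)
write_city(sim, out)

net <- sim$city$net
message(sprintf("city: %d nodes, %d edges, %d schools, %d parcels",
                nrow(net$nodes), nrow(net$edges), nrow(sim$city$schools),
                nrow(sim$city$parcels$table)))
message(sprintf("roster: %d participants (%d children, %d adolescents)",
                nrow(sim$participants),
                sum(sim$participants$age_group == "child"),
                sum(sim$participants$age_group == "adolescent")))
message(sprintf("injected defects: %d missing ACS, %d cyclists, %d bad addresses",
                sim$truth$injected$missing_acs, sim$truth$injected$bike,
                sim$truth$injected$bad_coords))
message("ground-truth coefficients recorded in ", file.path(out, "truth.json"))
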