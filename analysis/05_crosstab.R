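#!/usr/bin/env Rscript
## Stage 5: cross-table of commuting status by PRD ranges. Bin edges combine
## the ROC-derived PRD cutoff (1.212) with the conventional 1.5
## direct/indirect boundary.

library(acsroutes)

records <- read.csv("results/exposure.csv")
ct <- build_crosstab(records)
print(ct)

message(sprintf("active commuters on indirect routes (PRD > 1.5): %.1f%%",
                bin_share(ct, "active", ncol(ct$counts))))
message(sprintf("non-active commuters on direct routes (PRD <= 1.5): %.1f%%",
                bin_share(ct, "non_active", 1:(ncol(ct$counts) - 1))))

write_crosstab(ct, "results/crosstab.csv", "results/crosstab.json")
message("wrote results/crosstab.csv and results/crosstab.json")
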