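#!/usr/bin/env Rscript
## Stage 4: ROC/Youden cut-points of the route measures - the PRD threshold
## separating active from non-active commuters (overall and by age group)
## and the distance threshold (overall; active below the cutoff).

library(acsroutes)

records <- read.csv("results/exposure.csv")
report <- threshold_report(records)

for (nm in names(report)) {
  r <- report[[nm]]
  message(sprintf(
    "%-16s AUC = %.3f (95%% CI %.3f-%.3f)  J = %.3f  cutoff = %.3f  [%s]",
    nm, r$auc, r$ci[1], r$ci[2], r$j_max, r$cutoff, r$validity))
}

write_roc_summary(report, "results/roc_summary.json",
                  points_dir = "results/roc_points")
message("wrote results/roc_summary.json and per-analysis curve points")
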