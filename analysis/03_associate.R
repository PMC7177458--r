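#!/usr/bin/env Rscript
## Stage 3: the two-model logistic protocol. Model 1 pools both age groups
## with an age adjustment and feeds the confounding check and collinearity
## diagnostics; predictors that are both non-significant and VIF-flagged are
## dropped; model 2 refits separately for children and adolescents.

library(acsroutes)

records <- read.csv("results/exposure.csv")
seq <- run_model_sequence(records)

m1 <- seq$model1
message(sprintf("model 1 (pooled, age-adjusted): n = %d, accuracy %.1f%% at p = 0.50",
                m1$n, 100 * m1$accuracy))
message(sprintf("confounding check: max OR change %.1f%% (flag at 10%%)",
                max(seq$confounding$change_pct)))
message(sprintf("collinearity: max |r| = %.2f, max VIF = %.2f, max condition index = %.1f",
                seq$collinearity$max_abs_r, max(seq$collinearity$vif),
                max(seq$collinearity$condition_index)))
message("dropped before model 2: ",
        if (length(seq$dropped)) paste(seq$dropped, collapse = ", ") else "none")

for (ag in names(seq$model2)) {
  m <- seq$model2[[ag]]
  message(sprintf("model 2 (%s): n = %d, accuracy %.1f%%", ag, m$n,
                  100 * m$accuracy))
  cf <- m$coefficients[m$coefficients$term != "(Intercept)", ]
  for (i in seq_len(nrow(cf))) {
    message(sprintf("  %-12s OR = %6.3f (%5.3f-%6.3f)  p = %.3g",
                    cf$term[i], cf$OR[i], cf$ci_lo[i], cf$ci_hi[i], cf$p[i]))
  }
}

write_model_report(seq, "results/models.json", "results/models_table.csv")
message("wrote results/models.json and results/models_table.csv")
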