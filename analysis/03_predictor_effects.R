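#!/usr/bin/env Rscript
# Fit the predictor model to the desk-scale dataset and summarize the
# coefficient, the effect scales and the w-vs-predictor scatter. Run
# analysis/01_simulate.R (and optionally 02) first.

suppressPackageStartupMessages(library(phyloweber))
dir.create("results", showWarnings = FALSE)

trials <- read.csv("results/data/trials.csv")
preds <- read.csv("results/data/predictors.csv")
tree <- load_tree(paste(readLines("results/data/tree8.nwk"), collapse = ""))
cov <- tree_to_correlation(tree)

spec <- model_spec(predictor = "x", chains = 4, warmup = 1000, draws = 1000,
                   seed = 31)
ft <- fit(trials, preds, cov, spec)
print(ft)
cat(sprintf("max Rhat %.4f\n", max(rhat(ft))))

cs <- coefficient_summary(ft)
write.csv(cs, "results/coefficient_summary.csv", row.names = FALSE)
cat("\npredictor coefficient (on log w, standardized predictor):\n")
print(cs, digits = 3)

ss <- scale_summary(ft)
write.csv(ss, "results/scale_summary.csv", row.names = FALSE)
cat("\neffect scales (posterior mean, 50% and 90% intervals):\n")
print(ss, digits = 3)

truth <- jsonlite::read_json("results/data/truth.json")
eff <- truth$beta1 * sd(preds$x)
cat(sprintf("\ngenerating coefficient (on the standardized scale): %.3f\n", eff))

# scatter of species w (from the no-predictor posture of the same data)
# against the predictor
spec0 <- model_spec(predictor = NULL, chains = 2, warmup = 500, draws = 500,
                    seed = 32)
ft0 <- fit(trials, NULL, cov, spec0)
st <- weber_scatter_table(ft0, preds, "x")
write.csv(st, "results/weber_vs_predictor.csv", row.names = FALSE)
cat(sprintf("\nscatter table written; rank correlation of w50 with x: %.2f\n",
            cor(st$w50, st$x, method = "spearman")))
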