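#!/usr/bin/env Rscript
# Generate the working datasets for the analysis: a synthetic 33-species
# time tree, a full-scale structural dataset (33 species / 49 studies /
# 672 subjects) for inspection, and the desk-scale dataset (8 species,
# ~2000 trials) that the model-fitting drivers use.

suppressPackageStartupMessages(library(phyloweber))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

# 33-species tree with calibrated robin (3 Myr) and dog/wolf (0.015 Myr) splits
tree33 <- example_timetree()
ape::write.tree(tree33, "results/data/timetree33.nwk")
cat(sprintf("tree: %d tips, depth %.0f Myr, robin MRCA %.3f Myr, dog/wolf %.3f Myr\n",
            length(tree33$tip.label), max(tip_depths(tree33)),
            mrca_age(tree33, c("North_Island_robin", "South_Island_robin")),
            mrca_age(tree33, c("dog", "wolf"))))

# full structural footprint, 2 trials/subject to keep the table small
paper_cfg <- simulation_config(preset = "paper33", trials_per_subject = c(30, 30),
                               seed = 11)
sim33 <- simulate_dataset(simulate_tree(33, seed = 11), paper_cfg)
write.csv(sim33$trials, "results/data/trials_paper33.csv", row.names = FALSE)
cat(sprintf("paper-scale dataset: %d trials, %d species, %d studies, %d subjects\n",
            nrow(sim33$trials), length(unique(sim33$trials$species)),
            length(unique(sim33$trials$study)),
            length(unique(sim33$trials$subject))))

# desk-scale dataset for the fitting drivers, with a real predictor effect
tree8 <- simulate_tree(8, seed = 1)
cfg <- simulation_config(seed = 1, beta1 = -0.3, lambda = 0.8)
sim <- simulate_dataset(tree8, cfg)
ape::write.tree(tree8, "results/data/tree8.nwk")
write.csv(sim$trials, "results/data/trials.csv", row.names = FALSE)
write.csv(sim$predictors, "results/data/predictors.csv", row.names = FALSE)
jsonlite::write_json(sim$truth[c("beta0", "beta1", "lambda", "sigma_species",
                                 "sigma_study", "sigma_subject", "sigma_task")],
                     "results/data/truth.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("desk-scale dataset: %d trials, overall accuracy %.3f\n",
            nrow(sim$trials), mean(sim$trials$correct)))
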