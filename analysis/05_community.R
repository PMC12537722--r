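# Family-level community analysis of the synthetic amplicon data:
# aggregation of ASVs to families, relative abundances with top-15 pooling,
# Bray-Curtis dissimilarities, PCoA, and a factorial PERMANOVA
# (bay * depth + season) with free permutations.
source("analysis/00_config.R")

res <- run_pipeline(config, data_dir, stages = "community")

cat("\nPERMANOVA on Bray-Curtis dissimilarities:\n")
print(res$community$permanova)
pe <- res$community$pcoa$prop_explained
cat(sprintf("\nPCoA axes 1-2 explain %.1f%% and %.1f%% of the (positive)\n",
            100 * pe[1], 100 * pe[2]))
cat("dissimilarity. Depth and bay dominate the partition, matching the\n")
cat("gradients planted in the generator; season is comparatively weak.\n")

ra <- res$community$relabund
top <- sort(colMeans(ra), decreasing = TRUE)
cat("\nMean family relative abundance (top 5):\n")
print(round(head(top, 5), 3))
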