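# Seasonal temperature summaries per bay, a Welch t-test on the bay
# contrast, and methane fold changes between seasons and bays at matched
# depths.
source("analysis/00_config.R")

res <- run_pipeline(config, data_dir, stages = "compare")

cat("\nSeasonal temperature summaries:\n")
print(res$compare$temperature, row.names = FALSE, digits = 3)
cat(sprintf("\nHeated vs control bay: Welch t = %.1f, p = %.3g\n",
            res$compare$welch$t, res$compare$welch$p))

methane <- read.csv(file.path(data_dir, "methane.csv"), comment.char = "#")
for (depth in c(4, 25)) {
  fc <- fold_change_summary(fold_change(methane, "season", depth = depth,
                                        floor = config$detection_floor))
  cat(sprintf("Summer/winter methane fold change at %d cm: max %.3g, mean %.3g (%d of %d floored)\n",
              depth, fc$max_fold, fc$mean_fold, fc$n_floored, fc$n))
}
cat("\nNear the seafloor (4 cm) both seasons sit at the detection floor in\n")
cat("this scenario; the seasonal contrast appears at depth, where summer's\n")
cat("shallower methane transition has already produced measurable CH4.\n")
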