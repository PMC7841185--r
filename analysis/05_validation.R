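#!/usr/bin/env Rscript
# Generalization check: 1000 random 18/3 train/test splits of the stroke
# table; per split, the full stepwise selection is re-run on the training
# rows and the held-out RMSE recorded, yielding an RMSE distribution and
# per-feature selection frequencies.

suppressMessages(library(eegstroke))

seed <- 1
out <- "results/05_validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
features_path <- "results/02_features/features.csv"
uni_path <- "results/04_regression/univariate.csv"
if (!file.exists(features_path) || !file.exists(uni_path)) {
  stop("run analysis/02_features.R and analysis/04_regression.R first")
}
feats <- read_feature_table(features_path)
stroke <- feats[feats$group != "control", ]
uni <- utils::read.csv(uni_path)
candidates <- uni$predictor[uni$p_bonf < 0.05]

ev <- repeated_split_eval(stroke, candidates, n_test = 3, iters = 1000,
                          seed = seed)
utils::write.csv(data.frame(iteration = seq_along(ev$rmse), rmse = ev$rmse),
                 file.path(out, "rmse.csv"), row.names = FALSE)
utils::write.csv(data.frame(predictor = names(ev$frequency),
                            frequency = unname(ev$frequency)),
                 file.path(out, "frequencies.csv"), row.names = FALSE)
print(ev)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(data.frame(rmse = ev$rmse), aes(rmse)) +
    geom_histogram(bins = 40) +
    labs(x = "held-out RMSE (mm^3)", y = "splits",
         title = "Test RMSE over 1000 random 18/3 splits") +
    theme_minimal()
  ggsave(file.path(out, "rmse_hist.png"), p, width = 6, height = 4, dpi = 120)
}
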