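#!/usr/bin/env Rscript
# Lesion-volume regression on the stroke subjects (controls excluded):
# univariate fits with Bonferroni-corrected p values, the all-subsets
# RMSE/AIC/BIC search over the significant predictors, stepwise selection
# with collinearity diagnostics, and the serialized final model.

suppressMessages(library(eegstroke))

out <- "results/04_regression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
features_path <- "results/02_features/features.csv"
if (!file.exists(features_path)) stop("run analysis/02_features.R first")
feats <- read_feature_table(features_path)
stroke <- feats[feats$group != "control", ]
message(nrow(stroke), " stroke subjects enter the regression")

predictors <- c("RP_alpha", "RP_theta", "RP_delta", "DAR", "DTABR",
                "amplitude", "latency")
uni <- univariate_regressions(stroke[predictors], stroke$lesion_volume)
utils::write.csv(uni, file.path(out, "univariate.csv"), row.names = FALSE)
message("univariate fits (B, standardized beta, R^2, Bonferroni p):")
print(uni, digits = 3)

candidates <- uni$predictor[uni$p_bonf < 0.05]
message("Bonferroni-significant candidates: ", paste(candidates, collapse = ", "))

subsets <- all_subsets(stroke[candidates], stroke$lesion_volume)
utils::write.csv(subsets, file.path(out, "subsets.csv"), row.names = FALSE)
message(nrow(subsets), " candidate-subset models fitted; 5 best by training RMSE:")
print(head(subsets, 5), digits = 3)
best_ic <- subsets[order(subsets$bic), ][1, ]
message("lowest-BIC model: ", best_ic$predictors)

trace <- stepwise(stroke[candidates], stroke$lesion_volume)
utils::write.csv(trace$steps, file.path(out, "stepwise_steps.csv"), row.names = FALSE)
utils::write.csv(trace$excluded, file.path(out, "stepwise_excluded.csv"),
                 row.names = FALSE)
print(trace)
write_model(trace$final, file.path(out, "model.json"))
utils::write.csv(collinearity(stroke[trace$selected]),
                 file.path(out, "model_collinearity.csv"), row.names = FALSE)

pred <- predict_volume(trace$final, stroke)
utils::write.csv(data.frame(subject_id = stroke$subject_id,
                            observed = stroke$lesion_volume, predicted = pred),
                 file.path(out, "predictions.csv"), row.names = FALSE)
message(sprintf("final model: R^2 = %.3f, training RMSE = %.3f mm^3",
                trace$final$r2, trace$final$rmse))
sw <- shapiro_wilk(trace$final$residuals)
message(sprintf("Shapiro-Wilk on residuals: W = %.3f, p = %.3f", sw$W, sw$p))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(data.frame(obs = stroke$lesion_volume, pred = pred),
              aes(obs, pred)) +
    geom_abline(linetype = 2) + geom_point() +
    labs(x = "observed lesion volume (mm^3)",
         y = "predicted lesion volume (mm^3)") +
    theme_minimal()
  ggsave(file.path(out, "predicted_vs_observed.png"), p,
         width = 5, height = 5, dpi = 120)
}
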