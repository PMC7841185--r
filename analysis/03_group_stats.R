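#!/usr/bin/env Rscript
# Nonparametric group comparisons: Kruskal-Wallis per feature (Bonferroni-
# corrected across features), with pairwise Mann-Whitney post-hocs for the
# significant ones - separately for the stimulus and silent conditions. The
# key qualitative check: stimulus-condition biomarkers separate the groups,
# silent-condition ones do not.

suppressMessages(library(eegstroke))

out <- "results/03_group_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
features_path <- "results/02_features/features.csv"
if (!file.exists(features_path)) stop("run analysis/02_features.R first")
feats <- read_feature_table(features_path)

stim <- feature_group_tests(
  feats, c("RP_beta", "RP_alpha", "RP_theta", "RP_delta", "DAR", "DTABR",
           "amplitude", "latency"))
silent <- feature_group_tests(
  feats, c("silent_RP_beta", "silent_RP_alpha", "silent_RP_theta",
           "silent_RP_delta", "silent_DAR", "silent_DTABR"))

utils::write.csv(stim, file.path(out, "stats_stim.csv"), row.names = FALSE)
utils::write.csv(silent, file.path(out, "stats_silent.csv"), row.names = FALSE)

message("with auditory stimulation, Bonferroni-significant features:")
message("  ", paste(stim$feature[stim$significant], collapse = ", "))
message("without auditory stimulation, Bonferroni-significant features:")
message("  ", if (any(silent$significant))
  paste(silent$feature[silent$significant], collapse = ", ") else "(none)")

pw <- attr(stim, "pairwise")
for (f in names(pw)) {
  utils::write.csv(pw[[f]], file.path(out, paste0("pairwise_", f, ".csv")),
                   row.names = FALSE)
}
message("pairwise Mann-Whitney tables written for: ",
        paste(names(pw), collapse = ", "))
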