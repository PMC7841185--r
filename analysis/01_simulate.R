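#!/usr/bin/env Rscript
# Simulate the study cohort: 31 subjects (10 control, 7 mild, 7 moderate,
# 7 severe), each with a ground-truth lesion volume, evoked-response
# parameters, and band-fraction profiles for the stimulus and silent
# conditions. Writes the ground-truth table plus one example recording and
# its event schedule so the on-disk formats can be inspected.

suppressMessages(library(eegstroke))

seed <- 1
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config()
cohort <- sample_cohort(cfg, seed = seed)
write_feature_table(cohort, file.path(out, "ground_truth.csv"))

agg <- aggregate(cbind(lesion_volume, aep_amplitude, aep_latency, frac_delta,
                       frac_alpha) ~ group, cohort, median, na.action = NULL)
message("group medians of the generated ground truth:")
print(agg, digits = 3)

# one example subject, serialized both ways
ev <- generate_event_schedule(cfg, seed = derive_seed(seed, "schedule_mild_01"))
write_events(ev, file.path(out, "mild_01_events.tsv"))
rec <- synthesize_recording(cohort[cohort$subject_id == "mild_01", ], ev, cfg,
                            seed = derive_seed(seed, "synth_mild_01"))
write_recording(rec, file.path(out, "mild_01.edf"), format = "edf")
message(sprintf("example recording: %.0f s at %g Hz, written as EDF (%.1f MB)",
                recording_duration(rec), rec$fs,
                file.size(file.path(out, "mild_01.edf")) / 2^20))
message("schedule span: ", schedule_span(ev), " s; events per type:")
print(table(ev$trial_type))
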