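# End-to-end orchestration: simulate -> features -> group stats -> regression
# -> split validation, with per-stage derived seeds, a deterministic artifact
# tree, and a manifest of seeds and checksums.

#' Pipeline configuration
#'
#' Nested configuration for a full run. `cohort` is a [cohort_config()];
#' `regression` carries the stepwise thresholds and the Bonferroni level used
#' to select candidate predictors from the univariate table; `validation`
#' the split-evaluation settings. A YAML or JSON file with the same nesting
#' can be supplied via `file` (fields validated against the defaults;
#' unknown names error).
#'
#' @param ... overrides of default fields.
#' @param file optional YAML/JSON configuration file.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    cohort = unclass(cohort_config()),
    stim_feature_cols = c("RP_beta", "RP_alpha", "RP_theta", "RP_delta",
                          "DAR", "DTABR", "amplitude", "latency"),
    silent_feature_cols = c("silent_RP_beta", "silent_RP_alpha",
                            "silent_RP_theta", "silent_RP_delta",
                            "silent_DAR", "silent_DTABR"),
    regression = list(p_enter = 0.05, p_remove = 0.10, candidate_alpha = 0.05),
    validation = list(iters = 1000, n_test = 3),
    write_recordings = FALSE,
    recording_format = "csv_json",
    seed = 1)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    over <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(file) else
      jsonlite::read_json(file, simplifyVector = TRUE)
    cfg <- modify_config(cfg, over)
  }
  cfg <- modify_config(cfg, list(...))
  cfg$cohort <- do.call(cohort_config, cfg$cohort)
  structure(cfg, class = "pipeline_config")
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: (1) sample the synthetic cohort; (2) synthesize recordings and
#' extract the per-subject feature table; (3) Kruskal-Wallis group
#' comparisons for the stimulus and silent conditions; (4) regression on the
#' stroke subjects only - univariate table, Bonferroni candidate selection,
#' all-subsets RMSE/AIC/BIC ranking, stepwise selection with collinearity
#' diagnostics, and the serialized final model; (5) repeated random-split
#' validation. Writes one artifact per stage plus `manifest.json` (package
#' version, seeds, per-file MD5 checksums); re-running with the same config
#' and seed reproduces every checksum.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must be writable).
#' @param seed master seed (default `config$seed`).
#' @param progress print per-subject progress during synthesis.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = config$seed, progress = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  paths <- list()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    paths[[name]] <<- path
    path
  }

  cohort <- stage_run("simulate", {
    cohort <- sample_cohort(config$cohort, seed = derive_seed(seed, "simulate"))
    put("ground_truth.csv", function(p) write_feature_table(cohort, p))
    cohort
  })

  features <- stage_run("features", {
    rec_dir <- if (config$write_recordings) file.path(out_dir, "recordings") else NULL
    feats <- cohort_features(
      cohort, config$cohort, seed = derive_seed(seed, "features"),
      out_dir = rec_dir, write_recordings = config$write_recordings,
      recording_format = config$recording_format,
      keep_waveforms = TRUE, progress = progress)
    put("features.csv", function(p) write_feature_table(feats, p))
    wf <- attr(feats, "waveforms")
    wt <- attr(feats, "waveform_times")
    put("aep_waveforms.csv", function(p) {
      long <- data.frame(subject_id = rep(rownames(wf), each = ncol(wf)),
                         time_s = rep(wt, times = nrow(wf)),
                         value_uV = as.vector(t(wf)))
      write_table_full(long, p, sep = ",")
    })
    feats
  })

  stage_run("stats", {
    stim <- feature_group_tests(features, config$stim_feature_cols)
    sil <- feature_group_tests(features, config$silent_feature_cols)
    put("stats_stim.csv", function(p) write_table_full(stim, p, sep = ","))
    put("stats_silent.csv", function(p) write_table_full(sil, p, sep = ","))
    NULL
  })

  regress <- stage_run("regress", {
    stroke <- features[features$group != "control", , drop = FALSE]
    predictors <- c("RP_alpha", "RP_theta", "RP_delta", "DAR", "DTABR",
                    "amplitude", "latency")
    uni <- univariate_regressions(stroke[predictors], stroke$lesion_volume)
    put("univariate.csv", function(p) write_table_full(uni, p, sep = ","))
    candidates <- uni$predictor[uni$p_bonf < config$regression$candidate_alpha]
    if (length(candidates) < 2) {
      warning("fewer than 2 Bonferroni-significant predictors; using all")
      candidates <- predictors
    }
    subsets <- all_subsets(stroke[candidates], stroke$lesion_volume)
    put("subsets.csv", function(p) write_table_full(subsets, p, sep = ","))
    trace <- stepwise(stroke[candidates], stroke$lesion_volume,
                      p_enter = config$regression$p_enter,
                      p_remove = config$regression$p_remove)
    put("stepwise_steps.csv", function(p) write_table_full(trace$steps, p, sep = ","))
    put("stepwise_excluded.csv", function(p) write_table_full(trace$excluded, p, sep = ","))
    if (!is.null(trace$final)) {
      put("model.json", function(p) write_model(trace$final, p))
      vif <- collinearity(stroke[trace$selected])
      put("model_collinearity.csv", function(p) write_table_full(vif, p, sep = ","))
    }
    list(stroke = stroke, candidates = candidates, trace = trace)
  })

  stage_run("validate", {
    ev <- repeated_split_eval(
      regress$stroke, regress$candidates,
      n_test = config$validation$n_test, iters = config$validation$iters,
      p_enter = config$regression$p_enter, p_remove = config$regression$p_remove,
      seed = derive_seed(seed, "validate"))
    put("validation_rmse.csv", function(p)
      write_table_full(data.frame(iteration = seq_along(ev$rmse), rmse = ev$rmse),
                       p, sep = ","))
    put("validation_frequencies.csv", function(p)
      write_table_full(data.frame(predictor = names(ev$frequency),
                                  frequency = unname(ev$frequency)),
                       p, sep = ","))
    NULL
  })

  manifest <- list(
    package = "eegstroke",
    version = as.character(utils::packageVersion("eegstroke")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       features = derive_seed(seed, "features"),
                       validate = derive_seed(seed, "validate")),
    n_subjects = nrow(cohort),
    artifacts = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

fmt_med_iqr <- function(m, i) sprintf("%.2f +/- %.2f", m, i)

#' Generate a human-readable report from a pipeline run directory
#'
#' Five sections: group medians +/- IQR per feature (stimulus and silent
#' conditions), the univariate regression table, the all-subsets RMSE
#' ranking, the stepwise trace with collinearity diagnostics, and the
#' split-validation summary. Regeneration is idempotent.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param path output text file (default `report.txt` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  need <- c("features.csv", "stats_stim.csv", "stats_silent.csv",
            "univariate.csv", "subsets.csv", "stepwise_steps.csv",
            "validation_rmse.csv", "validation_frequencies.csv")
  missing_files <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_files) > 0) {
    stop("incomplete run directory; missing artifact(s): ",
         paste(missing_files, collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(run_dir, f), stringsAsFactors = FALSE)
  stats_stim <- rd("stats_stim.csv"); stats_sil <- rd("stats_silent.csv")
  uni <- rd("univariate.csv"); subsets <- rd("subsets.csv")
  steps <- rd("stepwise_steps.csv"); freqs <- rd("validation_frequencies.csv")
  rmse_tab <- rd("validation_rmse.csv")

  lines <- c("EEG biomarker / lesion-volume pipeline report",
             strrep("=", 46), "")
  section <- function(title, df) {
    c(title, strrep("-", nchar(title)),
      utils::capture.output(print(df, row.names = FALSE, digits = 4)), "")
  }
  med_block <- function(stats_df, label) {
    cols <- grep("^median_", names(stats_df), value = TRUE)
    groups <- sub("^median_", "", cols)
    out <- data.frame(feature = stats_df$feature)
    for (g in groups) {
      out[[g]] <- fmt_med_iqr(stats_df[[paste0("median_", g)]],
                              stats_df[[paste0("iqr_", g)]])
    }
    out$chi_sq <- sprintf("%.3f (%d)", stats_df$statistic, stats_df$df)
    out$p_bonf <- signif(stats_df$p_bonf, 3)
    section(label, out)
  }
  lines <- c(lines,
             med_block(stats_stim, "Group medians +/- IQR, with auditory stimulation"),
             med_block(stats_sil, "Group medians +/- IQR, without auditory stimulation"),
             section("Univariate regressions on lesion volume (stroke groups only)", uni),
             section("All-subsets search: 10 best models by training RMSE",
                     utils::head(subsets, 10)),
             section("Stepwise trace", steps),
             section("Split validation: selection frequencies", freqs),
             sprintf("Split validation: median test RMSE %.4f over %d iterations",
                     stats::median(rmse_tab$rmse), nrow(rmse_tab)), "")
  writeLines(lines, path)
  invisible(path)
}
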