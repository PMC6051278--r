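#' Pipeline configuration
#'
#' Single flat list of every tunable in the simulate-to-evaluate chain.
#' Where the method has a stated operating point, the default equals it:
#' fs = 500 Hz, Morlet centre frequency 35 Hz, K = 5 modes, Renyi order 3,
#' embedding m = 2 with tolerance 0.2 x SD, 150 trees. Dataset sizes
#' default to a desk-scale analogue (6+6 training and 4+4 test records of
#' 200 beats) of a full clinical cohort.
#'
#' @param n_negative,n_positive,beats_per_record,separation,train_frac
#'   Synthetic dataset controls, see [generate_dataset()].
#' @param fs,mean_hr,hr_jitter Record generation controls.
#' @param denoise_first Run the db6 denoiser before R detection.
#' @param window_width Post-R window length in samples.
#' @param center_frequency,n_voices,K,gamma_rel,bandwidth,alpha,m,r_factor,n_bands,lambda,max_jump
#'   Feature-chain controls, see [feature_config()].
#' @param n_trees Random-forest size.
#' @param seed Master seed for the whole run.
#' @return A named list.
#' @export
pipeline_config <- function(n_negative = 10, n_positive = 10,
                            beats_per_record = 200, separation = 1,
                            train_frac = 0.6, fs = 500, mean_hr = 60,
                            hr_jitter = 0.05, denoise_first = TRUE,
                            window_width = 120L, center_frequency = 35,
                            n_voices = 32, K = 5, gamma_rel = 1e-4,
                            bandwidth = NULL, alpha = 3, m = 2,
                            r_factor = 0.2, n_bands = 10, lambda = 0.01,
                            max_jump = 10L, n_trees = 150, seed = 1) {
  as.list(environment())
}

#' Run the full detection pipeline
#'
#' simulate -> denoise -> detect R peaks -> segment -> extract features ->
#' train random forest on the training records -> evaluate on the test
#' records. Beat windows come from *detected* R peaks, so detector errors
#' propagate exactly as they would on real data. Reruns with the same
#' config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (features CSV, JSON
#'   report).
#' @param progress Progress messages every N windows (0 = silent).
#' @return List: `metrics` (test-split `metrics_report`), `features_test`,
#'   `features_train`, `feature_report`, `manifest`, `config`, `counts`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         progress = 0) {
  ds <- generate_dataset(n_negative = config$n_negative,
                         n_positive = config$n_positive,
                         beats_per_record = config$beats_per_record,
                         separation = config$separation,
                         seed = config$seed,
                         train_frac = config$train_frac,
                         fs = config$fs, mean_hr = config$mean_hr,
                         hr_jitter = config$hr_jitter)
  fcfg <- feature_config(fs = config$fs,
                         center_frequency = config$center_frequency,
                         n_voices = config$n_voices, K = config$K,
                         gamma_rel = config$gamma_rel,
                         bandwidth = config$bandwidth, alpha = config$alpha,
                         m = config$m, r_factor = config$r_factor,
                         n_bands = config$n_bands, lambda = config$lambda,
                         max_jump = config$max_jump)

  feats <- vector("list", length(ds$records))
  counts <- list(beats = 0L, windows = 0L)
  for (i in seq_along(ds$records)) {
    rec <- ds$records[[i]]
    bw <- preprocess_record(rec, denoise_first = config$denoise_first,
                            width = config$window_width)
    counts$beats <- counts$beats + length(rec$true_r_indices)
    counts$windows <- counts$windows + nrow(bw$windows)
    feats[[i]] <- extract_features_all(bw, fcfg, progress = progress)
    if (progress > 0)
      message(sprintf("record %s done (%d/%d)", rec$record_id, i,
                      length(ds$records)))
  }
  features <- do.call(rbind, feats)
  split_of <- stats::setNames(ds$manifest$split, ds$manifest$record_id)
  features$split <- split_of[features$record_id]
  train <- features[features$split == "train",
                    setdiff(names(features), "split")]
  test <- features[features$split == "test",
                   setdiff(names(features), "split")]

  fit <- train_rf(train, n_trees = config$n_trees, seed = config$seed)
  metrics <- evaluate_model(fit, test)
  freport <- feature_report(fit, train)

  result <- list(metrics = metrics, feature_report = freport,
                 features_train = train, features_test = test,
                 manifest = ds$manifest, config = config, counts = counts,
                 model = fit)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    roc <- roc_curve(metrics$scores, test$label)
    utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    report <- list(
      metrics = list(Se = metrics$Se, Sp = metrics$Sp, Acc = metrics$Acc,
                     MCC = metrics$MCC, AUC = metrics$AUC,
                     confusion = as.list(metrics$confusion)),
      record_votes = metrics$record_votes,
      top_features = utils::head(freport, 10),
      counts = counts,
      config = config[!vapply(config, is.null, TRUE)],
      version = as.character(utils::packageVersion("jwavesst")))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  result
}
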