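# The default synthetic domain-shift benchmark: the desk-scale analogue of
# the dog/horse experiments (6 classes, 300 windows per domain, one fold,
# 30 epochs, several seeds; shift preset `sensor_position` by default).

#' Generate the default benchmark domain pair with folds assigned
#'
#' @param seed Integer seed for generation and fold assignment.
#' @param preset Shift preset name or a [shift_spec()].
#' @param samples_per_class Windows per class and domain (default 50: 300
#'   windows per domain for the six dog-like classes).
#' @param class_models Activity models (default [dog_activity_models()]).
#' @return List with `source` and `target` [domain_dataset()]s (5 folds).
#' @export
benchmark_pair <- function(seed = 1, preset = "sensor_position",
                           samples_per_class = 50,
                           class_models = dog_activity_models()) {
  cfg <- synthetic_config(class_models, samples_per_class = samples_per_class,
                          seed = seed)
  pair <- generate_domain_pair(cfg, preset)
  pair$source <- make_folds(pair$source, seed = seed)
  pair$target <- make_folds(pair$target, seed = seed)
  pair
}

#' Run the synthetic benchmark for a set of methods and seeds
#'
#' For each seed, generates a fresh shifted domain pair and trains every
#' requested method on fold 0 with the desk-scale configuration. Returns
#' per-run reports and a summary table of source-test and target-test
#' macro F1 / accuracy.
#'
#' @param methods Methods to run.
#' @param seeds Integer seeds (a fresh pair per seed).
#' @param preset Shift preset name or [shift_spec()].
#' @param epochs Training epochs per run (default 30).
#' @param samples_per_class Windows per class and domain.
#' @param keep_bundles Keep the trained bundles in the result (needed for
#'   probes and latent analysis).
#' @param verbose Print per-epoch progress.
#' @return List with `runs` (nested by method, then seed) and `summary`
#'   data frame.
#' @export
run_benchmark <- function(methods = c("source_only", "dan", "dann", "drcn"),
                          seeds = 1:5, preset = "sensor_position",
                          epochs = 30, samples_per_class = 50,
                          keep_bundles = FALSE, verbose = FALSE) {
  runs <- list()
  rows <- list()
  for (seed in seeds) {
    pair <- benchmark_pair(seed, preset, samples_per_class)
    for (m in methods) {
      cfg <- benchmark_train_config(epochs = epochs, seed = seed)
      rep <- if (m == "source_only")
        train_source_only(pair, cfg, fold = 0, verbose = verbose)
      else train_uda(pair, m, cfg, fold = 0, verbose = verbose)
      if (!keep_bundles) rep$bundle <- NULL
      runs[[m]][[as.character(seed)]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        method = m, seed = seed,
        source_test_acc = rep$source_test$accuracy,
        source_test_f1 = rep$source_test$macro_f1,
        target_test_acc = rep$accuracy,
        target_test_f1 = rep$macro_f1,
        target_test_f1_unbiased = rep$by_rule$source_val_best$target_test$macro_f1)
    }
  }
  summary <- do.call(rbind, rows)
  list(runs = runs, summary = summary)
}

#' Mean benchmark metrics by method
#'
#' @param bench Result of [run_benchmark()].
#' @return Data frame of per-method means across seeds.
#' @export
benchmark_means <- function(bench) {
  s <- bench$summary
  do.call(rbind, lapply(split(s, s$method), function(d) {
    data.frame(method = d$method[1],
               source_test_f1 = mean(d$source_test_f1),
               target_test_acc = mean(d$target_test_acc),
               target_test_f1 = mean(d$target_test_f1))
  }))
}

# JSON serialization -----------------------------------------------------

report_to_list <- function(report) {
  mx <- function(m) list(accuracy = m$accuracy, macro_f1 = m$macro_f1,
                         weighted_f1 = m$weighted_f1,
                         per_class = m$per_class)
  list(method = report$method, fold = report$fold,
       selection_rule = report$selection_rule,
       class_names = report$class_names,
       target_test = mx(report$target_test),
       source_test = mx(report$source_test),
       selected_epoch = list(
         source_val_best = report$by_rule$source_val_best$selected_epoch,
         target_test_best = report$by_rule$target_test_best$selected_epoch),
       target_test_by_rule = list(
         source_val_best = mx(report$by_rule$source_val_best$target_test),
         target_test_best = mx(report$by_rule$target_test_best$target_test)),
       history = report$history,
       train_cfg = unclass(report$train_cfg))
}

#' Write an evaluation report as JSON
#'
#' Serialization is value-deterministic: identical reports produce
#' byte-identical files.
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}
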